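category,monthly_amount_zar,allocation,params
assets,18009.04,none_incremental,
overheads,111865.46,extra_room_overhead,requires_any=youth_only|afternoon
staff,776421.24,afternoon_staff_time,requires_any=afternoon
supplies,6501.04,per_visit,unit_cost_zar=1.12
wifi,7317.66,per_visit,unit_cost_zar=148.12;requires=wifi
food,0,all_adolescents_billed_to_additional,amount_per_adolescent_zar=10;requires=food
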