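clinic,baseline_adolescents_per_month,baseline_uptake_share_pct,total_monthly_headcount
A,1531,30.60,5000
B,1808,30.60,6000
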