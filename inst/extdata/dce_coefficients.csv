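attribute,level,coefficient,std_error,modifiable
afternoon,Afternoon,0.01,0.03,TRUE
wifi,Wi-Fi,0.03,0.04,TRUE
youth_only,Youth waiting area,0.00,0.03,TRUE
food,Food,0.02,0.03,TRUE
friendly,Friendly,0.19,0.03,FALSE
confidential,Confidential,0.08,0.03,FALSE
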