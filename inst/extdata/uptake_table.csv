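scenario,attributes,coefficient,delta_pp,se,p_value,ci_low_pp,ci_high_pp,total_share_pct
Afternoon,afternoon,0.01,0.82,0.03,0.80,-5.62,7.27,31.42
Wi-Fi,wifi,0.03,2.71,0.04,0.45,-4.25,9.67,33.31
Youth waiting area,youth_only,0.00,0.29,0.03,0.93,-6.17,6.74,30.89
Food,food,0.02,2.25,0.03,0.49,-4.10,8.61,32.85
Friendly,friendly,0.19,18.54,0.03,0.00,13.44,23.63,49.14
Confidential,confidential,0.08,8.35,0.03,0.00,3.09,13.60,38.95
Wi-Fi and food,wifi;food,0.11,10.70,0.05,0.03,10.00,20.00,41.30
Food and youth,food;youth_only,0.08,8.30,0.04,0.06,0.00,16.00,38.90
Youth and Wi-Fi,youth_only;wifi,0.09,9.00,0.04,0.07,0.00,18.00,39.60
Afternoon and Wi-Fi,afternoon;wifi,0.09,9.00,0.04,0.02,1.20,17.00,39.60
Afternoon and youth-only,afternoon;youth_only,0.07,6.90,0.04,0.08,-0.87,14.67,37.50
Food and afternoon,food;afternoon,0.08,8.00,0.03,0.02,1.20,16.40,38.60
"Youth-only, afternoon and Wi-Fi",youth_only;afternoon;wifi,0.17,16.84,0.06,0.01,4.59,29.08,47.44
"Wi-Fi, food and youth",wifi;food;youth_only,0.17,16.70,0.06,0.01,4.50,28.80,47.30
"Wi-Fi, food and afternoon",wifi;food;afternoon,0.17,17.20,0.05,0.00,6.90,27.48,47.80
"Food, afternoon and youth",food;afternoon;youth_only,0.15,14.80,0.05,0.00,5.48,24.24,45.40
"Wi-Fi, food, afternoon and youth",wifi;food;afternoon;youth_only,0.23,23.00,3.65,0.00,10.60,35.00,53.60
"Youth-only, Wi-Fi, afternoon and friendly",youth_only;wifi;afternoon;friendly,0.49,49.42,0.04,0.00,40.86,57.99,80.02
"Youth-only, Wi-Fi, afternoon and friendly (second printed row)",youth_only;wifi;afternoon;friendly,0.38,37.99,0.05,0.00,28.60,47.38,68.59
"Youth-only, Wi-Fi, food, afternoon, friendly and confidentiality",youth_only;wifi;food;afternoon;friendly;confidential,0.55,55.00,0.05,0.00,46.00,65.00,85.60
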