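name,additional,total,pct_change,cost_per_additional_usd,total_cost_usd,printed_icer,printed_label
Wi-Fi,1,1809,-4.3,11.01,11.01,NA,dominated
Food,1,1809,-4.1,31.82,31.82,NA,dominated
Afternoon,1,1809,-5.6,80.07,80.07,NA,dominated
Youth-only,1,1809,-6.2,630.40,630.40,NA,dominated
Wi-Fi and afternoon,22,1830,1.2,1166.11,856.85,NA,dominated
Wi-Fi and youth-only,1,1809,0.0,81.54,1166.11,NA,dominated
Afternoon and youth-only,22,1830,1.2,10.17,1769.81,NA,dominated
Wi-Fi and food,181,1989,10.0,1907.59,1840.26,6.18,frontier
Food and youth-only,1,1809,0.0,27.82,1907.59,NA,dominated
"Wi-Fi, food and youth-only",81,1889,4.5,28.34,2264.65,NA,dominated
"Wi-Fi, afternoon and youth-only",83,1891,4.6,2478.44,2350.82,NA,dominated
Food and afternoon,1,1809,-0.9,34.94,2478.44,NA,dominated
"Food, afternoon and youth-only",99,1907,5.5,32.21,3463.00,NA,dominated
"Wi-Fi, food and afternoon",125,1933,6.9,21.64,4019.66,NA,dominated
"Wi-Fi, food, afternoon and youth-only",192,2000,10.6,571.64,4148.30,212.73,frontier
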