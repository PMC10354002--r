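name,additional,total,pct_change,cost_per_additional_usd,total_cost_usd,printed_icer,printed_label
Wi-Fi,1,1532,-4.3,535.81,535.81,NA,dominated
Youth-only,1,1532,-6.2,929.29,929.29,NA,dominated
Afternoon,1,1532,-5.6,1015.51,1015.51,NA,dominated
Food,1,1532,-4.1,1117.98,1117.98,NA,dominated
Food and youth-only,1,1532,0.0,1198.75,1198.75,NA,dominated
Wi-Fi and youth-only,1,1532,0.0,1497.53,1497.53,NA,dominated
Wi-Fi and afternoon,18,1549,1.2,87.96,1615.62,NA,dominated
Wi-Fi and food,153,1684,10.0,11.52,1763.88,1.10,frontier
Afternoon and youth-only,18,1549,1.2,109.35,2008.40,NA,dominated
"Wi-Fi, food and youth-only",69,1599,4.5,30.88,2126.94,NA,dominated
Food and afternoon,1,1532,-0.9,3252.15,3252.15,NA,dominated
"Wi-Fi, afternoon and youth-only",70,1601,4.6,50.73,3560.49,NA,dominated
"Food, afternoon and youth-only",84,1614,5.5,50.88,4267.50,NA,dominated
"Wi-Fi, food and afternoon",106,1636,6.9,41.29,4361.22,NA,dominated
"Wi-Fi, food, afternoon and youth-only",162,1693,10.6,42.95,6969.09,566.79,frontier
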