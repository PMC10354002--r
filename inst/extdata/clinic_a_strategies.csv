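name,attributes,additional,total,pct_change,cost_per_additional_usd,total_cost_usd,printed_icer,printed_label
Wi-Fi,wifi,41,1572,2.7,12.56,516.65,NA,dominated
Youth-only,youth_only,4,1535,0.3,202.91,811.63,NA,dominated
Afternoon,afternoon,13,1544,0.8,78.47,1020.14,NA,dominated
Food,food,34,1565,2.3,31.54,1072.28,NA,dominated
Wi-Fi and youth-only,wifi;youth_only,138,1669,9.0,10.62,1465.56,9.78,frontier
Wi-Fi and food,wifi;food,168,1699,10.7,10.15,1705.92,NA,weakly_dominated
Food and youth-only,food;youth_only,122,1653,8.3,15.23,1858.50,NA,dominated
Wi-Fi and afternoon,wifi;afternoon,142,1673,9.3,18.33,2603.24,NA,weakly_dominated
"Wi-Fi, food and youth-only",wifi;food;youth_only,260,1791,17.0,10.54,2739.87,10.45,frontier
Afternoon and youth-only,afternoon;youth_only,106,1637,6.9,27.03,2864.78,NA,dominated
"Wi-Fi, afternoon and youth-only",wifi;afternoon;youth_only,230,1761,17.0,13.68,3147.26,NA,dominated
Food and afternoon,food;afternoon,138,1669,9.0,24.94,3441.86,NA,dominated
"Food, afternoon and youth-only",food;afternoon;youth_only,230,1761,15.0,18.09,4160.93,NA,dominated
"Wi-Fi, food and afternoon",wifi;food;afternoon,260,1791,17.0,16.35,4251.24,NA,dominated
"Wi-Fi, food, afternoon and youth-only",wifi;food;afternoon;youth_only,352,1883,23.0,19.20,6757.95,43.67,frontier
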