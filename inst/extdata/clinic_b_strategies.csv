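name,attributes,additional,total,pct_change,cost_per_additional_usd,total_cost_usd,printed_icer,printed_label
Wi-Fi,wifi,49,1857,2.7,10.66,522.69,NA,weakly_dominated
Youth-only,youth_only,5,1813,0.3,116.50,611.08,NA,dominated
Wi-Fi and youth-only,wifi;youth_only,163,1971,9.0,7.01,1141.87,7.01,frontier
Afternoon,afternoon,15,1823,0.8,77.58,1150.59,NA,dominated
Food,food,41,1849,2.3,30.83,1254.73,NA,dominated
Food and youth-only,food;youth_only,145,1953,8.0,11.43,1653.56,NA,dominated
Afternoon and youth-only,afternoon;youth_only,125,1933,6.9,13.79,1720.92,NA,dominated
Wi-Fi and food,wifi;food,199,2007,10.7,8.97,1785.57,NA,weakly_dominated
Wi-Fi and afternoon,wifi;afternoon,168,1976,9.3,7.45,1253.69,NA,dominated
Food and afternoon,food;afternoon,163,1971,9.0,14.83,2413.33,NA,dominated
"Wi-Fi, food and youth-only",wifi;food;youth_only,307,2115,17.0,8.10,2490.46,9.32,frontier
"Wi-Fi, afternoon and youth-only",wifi;afternoon;youth_only,271,2079,15.0,8.45,2293.28,NA,dominated
"Wi-Fi, food and afternoon",wifi;food;afternoon,307,2115,17.0,12.73,3914.33,NA,dominated
"Food, afternoon and youth-only",food;afternoon;youth_only,271,2079,15.0,11.15,3025.94,NA,dominated
"Wi-Fi, food, afternoon and youth-only",wifi;food;afternoon;youth_only,416,2224,23.0,9.76,4059.62,14.45,frontier
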