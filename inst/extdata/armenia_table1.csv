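population,city,year,expert_low,expert_median,expert_high,q5,q25,q50,q75,q95,assessment
FSW,Yerevan,2012,1500,3143,9900,1243,2235,3734,6975,16599,Great
FSW,Yerevan,2014,1500,3143,9900,397,421,445,469,542,Bad
FSW,Yerevan,2016,1500,3143,9900,784,1340,2090,4169,12924,Okay
FSW,Gyumri,2016,165,351,1089,126,152,171,217,340,Okay
FSW,Vanadzor,2016,115,239,759,133,164,205,280,551,Great
MSM,Yerevan,2012,2420,4202,6667,943,1550,2407,4335,14296,Bad
MSM,Yerevan,2014,2420,4202,6667,836,1407,2299,4477,17973,Bad
MSM,Yerevan,2016,2420,4202,6667,871,1121,1550,2264,4870,Bad
MSM,Gyumri,2016,176,306,485,127,176,249,409,974,Okay
MSM,Vanadzor,2016,123,214,339,323,506,666,836,993,Bad
PWID,Yerevan,2012,1667,5842,14473,1196,2041,3236,5823,17117,Good
PWID,Yerevan,2014,1667,5842,14473,1196,2091,3435,3569,19008,Good
PWID,Yerevan,2016,1667,5842,14473,698,947,1245,2091,6072,Bad
PWID,Gyumri,2016,167,584,1446,197,354,596,1141,2960,Great
PWID,Vanadzor,2016,117,409,1013,201,318,477,812,1775,Great
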