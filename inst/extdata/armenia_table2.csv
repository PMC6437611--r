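population,city,year,expert_low,expert_median,expert_high,object_multiplier,service_multiplier,woc,sspse_no_visibility,sspse_visibility
FSW,Yerevan,2012,1500,3143,9900,NA,NA,NA,2041,3734
FSW,Yerevan,2014,1500,3143,9900,NA,NA,NA,469,445
FSW,Yerevan,2016,1500,3143,9900,571,1283,1615,No fit,2090
FSW,Gyumri,2016,165,351,1089,150,92,196,277,171
FSW,Vanadzor,2016,115,239,759,204,156,67,275,205
MSM,Yerevan,2012,2420,4202,6667,NA,NA,NA,No fit,2407
MSM,Yerevan,2014,2420,4202,6667,NA,NA,NA,No fit,2299
MSM,Yerevan,2016,2420,4202,6667,749,8300,11900,1121,1550
MSM,Gyumri,2016,176,306,485,3659,NA,138,168,249
MSM,Vanadzor,2016,123,214,339,150,NA,40,No fit,666
PWID,Yerevan,2012,1667,5842,14473,NA,NA,NA,1245,3236
PWID,Yerevan,2014,1667,5842,14473,NA,NA,NA,1743,3435
PWID,Yerevan,2016,1667,5842,14473,9000,NA,19342,997,1245
PWID,Gyumri,2016,167,584,1446,3000,6800,26,No fit,596
PWID,Vanadzor,2016,117,409,1013,3000,7000,198,No fit,477
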