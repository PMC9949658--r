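condition_group,sex,measure,attributable,total,ci_lo,ci_hi
ow_ob_child,female,events,318855,2053392,153592,503791
ow_ob_child,male,events,455164,2251656,219252,719159
ow_ob_child,female,cost_musd,5.77,29.4,4.2,8.2
ow_ob_child,male,cost_musd,9,36,3.6,15
ow_ob_adult,female,events,169061,9897071,117209,288925
ow_ob_adult,male,events,351702,10212675,243835,601058
ow_ob_adult,female,cost_musd,28.08,619.86,27,49
ow_ob_adult,male,cost_musd,19.2,350,18,34
diabetes,female,events,281984,1406057,126846,417421
diabetes,male,events,356887,1349033,169944,505523
diabetes,female,deaths,563,3388,246,856
diabetes,male,deaths,754,3633,341,1114
diabetes,female,dalys,27007,139603,12291,40445
diabetes,male,dalys,34925,138834,16904,50282
diabetes,female,cost_musd,398.80,1988.55,181,597
diabetes,male,cost_musd,504.74,1908,244,727
cardiac,female,events,18456,437411,8746,28439
cardiac,male,events,35119,588503,16866,53402
cardiac,female,deaths,740,18153,350,1141
cardiac,male,deaths,1061,18844,508,1618
cardiac,female,dalys,7225,159545,3420,11119
cardiac,male,dalys,15664,208848,7528,23834
cardiac,female,cost_musd,32.6,772,15,50
cardiac,male,cost_musd,65.1,1074,31,99
cerebrovascular,female,events,13606,283518,6481,20855
cerebrovascular,male,events,15425,231778,7453,23316
cerebrovascular,female,deaths,482,11235,229,743
cerebrovascular,male,deaths,574,9920,275,873
cerebrovascular,female,dalys,8072,161099,3843,12367
cerebrovascular,male,dalys,10652,153406,5155,16125
cerebrovascular,female,cost_musd,27.90,572.93,13,43
cerebrovascular,male,cost_musd,29.6,435,15,45
ckd,female,events,11920,1087740,7937,19198
ckd,male,events,9508,581952,6254,15250
ckd,female,deaths,37,3645,25,60
ckd,male,deaths,53,3536,35,87
ckd,female,dalys,708,58643,457,1104
ckd,male,dalys,963,52808,604,1473
ckd,female,cost_musd,10.37,945.51,7,16
ckd,male,cost_musd,8.3,506,5,12
asthma,female,events,7878,968062,5223,12395
asthma,male,events,8111,626449,5330,12570
asthma,female,deaths,2,303,2,4
asthma,male,deaths,2,183,1,3
asthma,female,dalys,334,40245,216,513
asthma,male,dalys,341,25749,220,519
asthma,female,cost_musd,6.86,841.44,4,11
asthma,male,cost_musd,7,545,5,11
musculoskeletal,female,events,14652,5313518,9741,23101
musculoskeletal,male,events,19125,4143750,12556,29894
musculoskeletal,female,deaths,0,0,0,0
musculoskeletal,male,deaths,0,0,0,0
musculoskeletal,female,dalys,1011,361979,655,1554
musculoskeletal,male,dalys,1386,294635,892,2125
musculoskeletal,female,cost_musd,0.85,325.86,0.55,1.31
musculoskeletal,male,cost_musd,0.8,195,0.5,1.2
other,female,events,6311,581030,4195,9877
other,male,events,2870,280495,1889,4612
other,female,deaths,81,19838,53,131
other,male,deaths,76,13122,50,128
other,female,dalys,910,191118,590,1389
other,male,dalys,1093,155555,694,1695
other,female,cost_musd,3.26,553.22,2,5
other,male,cost_musd,3.6,489,3,6
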