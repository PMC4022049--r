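"state","component","mean_annual","lcl","ucl"
"asymptomatic","hospital",1470,455,2152
"signs_symptoms","hospital",2887,1974,3885
"recovery","hospital",3055,1708,4858
"splenectomy","hospital",4836,2544,7145
"bone_complication","hospital",4337,1590,9313
"multiple_complications","hospital",2194,1652,2826
"malignancy","hospital",27523,4786,51722
"asymptomatic","out_of_hospital",0,NA,NA
"signs_symptoms","out_of_hospital",121,31,272
"recovery","out_of_hospital",641,229,1097
"splenectomy","out_of_hospital",299,8,589
"bone_complication","out_of_hospital",449,51,939
"multiple_complications","out_of_hospital",245,97,421
"malignancy","out_of_hospital",56,NA,NA
"asymptomatic","production_loss",0,NA,NA
"signs_symptoms","production_loss",0,0,0
"recovery","production_loss",0,0,0
"splenectomy","production_loss",13698,0,27396
"bone_complication","production_loss",10002,0,20004
"multiple_complications","production_loss",10615,0,21230
"malignancy","production_loss",73057,NA,NA
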