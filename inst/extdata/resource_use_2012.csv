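category,code,quantity
appointment,DNA_offHAART,32
appointment,DNA_onHAART,127
appointment,HIV_offHAART,89
appointment,HIV_onHAART,997
appointment,ANC_offHAART,2
appointment,ANC_onHAART,42
appointment,BASE_offHAART,14
appointment,BASE_onHAART,12
test,CD4,1013
test,VL,995
test,FBC,1036
test,BIOCHEM_PROFILE,1042
test,OTHER_TEST,1262
regimen,EFV_FTC_TDF,1515
regimen,FTC_TDF_DRV_RTV,864
regimen,FTC_TDF_ATV_RTV,389
regimen,FTC_TDF_LPV_RTV,99
regimen,FTC_TDF_NVP,75
regimen,AZT_3TC_LPV_RTV,53
regimen,OTHER_REGIMEN,327
antibiotic,AZITHROMYCIN,330
antibiotic,SULFAMETHOXAZOLE_TRIMETHOPRIM,2047
antibiotic,DAPSONE,344
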