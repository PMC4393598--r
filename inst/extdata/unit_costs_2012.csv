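category,code,unit_cost_eur
appointment,DNA_offHAART,12.68
appointment,DNA_onHAART,21.25
appointment,HIV_offHAART,174.89
appointment,HIV_onHAART,194.88
appointment,ANC_offHAART,174.26
appointment,ANC_onHAART,194.25
appointment,BASE_offHAART,244.46
appointment,BASE_onHAART,264.45
test,CD4,47.29
test,VL,92.94
test,FBC,6.79
test,BIOCHEM_PROFILE,18.63
test,OTHER_TEST,28.39
regimen,EFV_FTC_TDF,816.61
regimen,FTC_TDF_DRV_RTV,1097.51
regimen,FTC_TDF_ATV_RTV,1084.84
regimen,FTC_TDF_LPV_RTV,1148.79
regimen,FTC_TDF_NVP,747.98
regimen,AZT_3TC_LPV_RTV,953.16
regimen,OTHER_REGIMEN,923.70
antibiotic,AZITHROMYCIN,0.42
antibiotic,SULFAMETHOXAZOLE_TRIMETHOPRIM,0.15
antibiotic,DAPSONE,0.69
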