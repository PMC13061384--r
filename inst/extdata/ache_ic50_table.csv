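# Day-12 in vivo AChE IC50 (uM) with standard errors for the seven
# organophosphorus pesticides, regenerating vs adult planarians.
# ACE did not inhibit AChE up to 316 uM (censored: ic50 NA, censor_limit).
op,worm_type,ic50_uM,ic50_se_uM,censor_limit_uM
ACE,regenerating,NA,NA,316
ACE,adult,NA,NA,316
CPF,regenerating,0.27,0.041,NA
CPF,adult,0.18,0.043,NA
DDVP,regenerating,0.0050,0.0010,NA
DDVP,adult,0.095,0.012,NA
DZN,regenerating,0.056,0.008,NA
DZN,adult,0.16,0.06,NA
MAL,regenerating,4.9,2.0,NA
MAL,adult,4.7,1.1,NA
PFS,regenerating,0.057,0.016,NA
PFS,adult,0.044,0.012,NA
PT,regenerating,0.21,0.038,NA
PT,adult,0.16,0.02,NA
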