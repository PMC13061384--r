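# In vitro oxon-mixture design parameters as published:
# the constant CPO:MALO mixing ratio used, and the preliminary IC50 values
# it is stated to be based on. The two are stored verbatim and NOT
# reconciled (1/13.6 = 0.074, not 0.007).
parameter,value,units
cpo_malo_ratio,0.007,dimensionless ([CPO]/[MALO])
cpo_preliminary_ic50,1,uM
malo_preliminary_ic50,13.6,uM
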