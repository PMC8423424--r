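phenotype,original_n,original_pct,cdm_n,cdm_pct,unmapped_n,unmapped_pct,incorrect_n,incorrect_pct
af,177954,35.39,177866,35.40,91,0.05,3,0.001
copd,249119,49.55,267925,53.33,13,0.005,18819,7.02
t2dm,119968,23.86,121059,24.09,280,0.23,1371,1.13
ami,102020,20.29,102028,20.31,11,0.01,19,0.02
ht,331011,65.84,330884,65.86,138,0.041,11,0.003
cancer,135047,26.86,137380,27.34,65,0.048,2398,1.74
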