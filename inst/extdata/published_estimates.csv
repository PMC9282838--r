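analysis,outcome,model,estimate,ci_low,ci_high,p_value,printed_days
ds,clock,base,0.3477,0.3097,0.3858,8.03e-61,347.7
ds,clock,full,0.2442,0.1964,0.2920,2.54e-22,244.2
ds,clock,full_excl_high_nrbc,0.1322,0.0958,0.1685,2.35e-12,132.2
ds,clock,full_gata1_wildtype,0.1730,0.1244,0.2216,7.55e-12,173.0
ds,dnamaa,base,0.3497,0.3119,0.3875,4.51e-62,349.7
ds,dnamaa,full,0.2406,0.1933,0.2880,3.91e-22,240.6
ds,dnamaa,full_excl_high_nrbc,0.1282,0.0921,0.1642,6.99e-12,128.2
ds,dnamaa,full_gata1_wildtype,0.1735,0.1251,0.2219,5.34e-12,173.5
gata1_status,clock,adjusted,0.1441,NA,NA,0.015,144
gata1_vaf,clock,adjusted,1.7805,NA,NA,0.004,178
gata1_status,dnamaa,adjusted,0.1447,NA,NA,0.009,NA
gata1_vaf,dnamaa,adjusted,1.5390,NA,NA,0.016,NA
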