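line,fecundity_mean,larval_viability,larva_to_pupa_days,viability_significant
HWE,76.2,0.823,5.9,NA
AeaNosC109,74.8,0.723,6.3,TRUE
AeaZpgC109,75.5,0.831,6.1,FALSE
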