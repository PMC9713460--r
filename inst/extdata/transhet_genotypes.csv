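line,rep,embryos_injected,surviving_larvae,n_ecfp,n_mcherry
AeaNosC109,1,1056,26,14,12
AeaNosC109,2,1017,33,18,15
AeaNosC109,3,1170,24,14,10
AeaZpgC109,1,1007,23,13,10
AeaZpgC109,2,1015,26,12,14
AeaZpgC109,3,1004,46,22,24
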