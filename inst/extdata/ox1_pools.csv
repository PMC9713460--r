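line,parent_sex,pool,marker_rate,n_assessed,gdbi_tested,gdbi_positive
AeaNosT4,M,low,0.459,290,40,0
AeaNosT4,M,high,0.581,136,40,0
AeaNosT4,F,low,0.429,163,40,0
AeaNosT4,F,high,0.513,117,40,0
AeaNosC109,M,low,0.553,228,54,9
AeaNosC109,M,high,0.864,214,27,7
AeaNosC109,F,low,0.615,148,46,7
AeaNosC109,F,high,0.897,136,12,7
AeaZpgC109,M,low,0.565,232,41,0
AeaZpgC109,M,high,0.592,228,51,0
AeaZpgC109,F,low,0.571,98,27,2
AeaZpgC109,F,high,0.737,118,23,1
Aeab2tC109,M,none,0.507,138,10,0
Aeab2tC109,F,none,0.525,40,10,0
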