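line,marker_class,locus,activity_rate
AeaNosC109,eCFP,drive_locus,0.19
AeaNosC109,eCFP,secondary_locus,0.40
AeaZpgC109,eCFP,drive_locus,0.14
AeaZpgC109,eCFP,secondary_locus,0.16
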