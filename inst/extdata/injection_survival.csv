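line,embryos_injected,survivors
Aeab2tT4,1115,72
AeaNosT4,959,154
Aeab2tC109,882,122
AeaNosC109,912,206
AeaZpgC109,568,45
AeaeCFPC109,1142,44
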