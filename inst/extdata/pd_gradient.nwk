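((s1:1,((s2:1,s3:1):1,s4:1):1):1,(s5:1,(s6:1,(s7:1,(s8:1,(s9:1,s10:1):1):1):1):1):1);
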