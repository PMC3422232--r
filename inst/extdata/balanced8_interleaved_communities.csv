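# synthetic example: interleaved communities, one tip per cherry
# (see pbd_example("interleaved_pair"))
site,t1,t2,t3,t4,t5,t6,t7,t8
A,1,0,1,0,1,0,1,0
B,0,1,0,1,0,1,0,1
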