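# synthetic six-community example: nested phylogenetic-diversity gradient
# on a 10-species unit-branch-length tree (see pbd_example("pd_gradient"))
site,s1,s2,s3,s4,s5,s6,s7,s8,s9,s10
A,1,1,1,0,0,0,0,0,0,0
B,0,1,1,1,0,0,0,0,0,0
C,0,1,1,1,0,1,0,0,0,0
D,0,1,1,1,0,0,1,0,0,0
E,0,1,1,1,0,0,0,0,1,0
F,0,1,1,1,0,0,0,0,1,1
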