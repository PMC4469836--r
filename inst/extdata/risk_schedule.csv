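state,safe,risky1,risky2,group
1,150,125,175,eev
2,150,100,200,eev
3,150,50,250,eev
4,140,40,240,uev
5,200,40,240,uev
6,210,40,240,uev
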