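state,image,optimal_action,valence,points,p_points_optimal,p_points_nonoptimal
1,I1,1,reward,25,0.8,0.2
2,I2,2,reward,25,0.8,0.2
3,I3,1,punishment,-25,0.2,0.8
4,I4,2,punishment,-25,0.2,0.8
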