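replicate,passage,fraction_r
1,0,0.8979
1,1,0.8193
1,2,0.6769
1,3,0.4682
1,4,0.2228
1,5,0.063
1,6,0.0115
1,7,0.0021
1,8,2e-04
1,9,0
1,10,0
1,11,0
1,12,0
1,13,0
1,14,0
1,15,0
1,16,0
1,17,0
1,18,0
1,19,0
1,20,0
1,21,0
1,22,0
1,23,0
1,24,0
1,25,0
1,26,0
1,27,0
1,28,0
1,29,0
1,30,0
2,0,0.8978
2,1,0.8244
2,2,0.6781
2,3,0.466
2,4,0.2162
2,5,0.064
2,6,0.0111
2,7,0.0021
2,8,3e-04
2,9,1e-04
2,10,0
2,11,0
2,12,0
2,13,0
2,14,0
2,15,0
2,16,0
2,17,0
2,18,0
2,19,0
2,20,0
2,21,0
2,22,0
2,23,0
2,24,0
2,25,0
2,26,0
2,27,0
2,28,0
2,29,0
2,30,0
3,0,0.8988
3,1,0.8205
3,2,0.6801
3,3,0.4618
3,4,0.2195
3,5,0.0655
3,6,0.01
3,7,0.0019
3,8,3e-04
3,9,0
3,10,0
3,11,0
3,12,0
3,13,0
3,14,0
3,15,0
3,16,0
3,17,0
3,18,0
3,19,0
3,20,0
3,21,0
3,22,0
3,23,0
3,24,0
3,25,0
3,26,0
3,27,0
3,28,0
3,29,0
3,30,0
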