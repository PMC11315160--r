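method,class,tp,fp,fn,tn,precision,sensitivity,f1,mcc
stisebs,Water,268,91,343,694830,0.747,0.439,0.553,0.572
stisebs,Trees,2456,1085,5515,686476,0.694,0.308,0.427,0.458
stisebs,Flooded vegetation,155,41,78,695258,0.791,0.665,0.723,0.725
stisebs,Crops,572,256,669,694035,0.691,0.461,0.553,0.564
stisebs,Built area,679,184,342,694327,0.787,0.665,0.721,0.723
stisebs,Bare ground,3361,1318,5570,685283,0.718,0.376,0.494,0.516
stisebs,Rangeland,672738,12328,2786,7680,0.982,0.996,0.989,0.521
eslic,Water,236,114,375,694807,0.674,0.386,0.491,0.510
eslic,Trees,2589,1174,5389,686380,0.688,0.325,0.441,0.469
eslic,Flooded vegetation,147,101,86,695198,0.593,0.631,0.611,0.611
eslic,Crops,581,266,663,694022,0.686,0.467,0.556,0.565
eslic,Built area,643,207,378,694304,0.756,0.630,0.687,0.690
eslic,Bare ground,2956,1016,5979,685581,0.744,0.331,0.458,0.492
eslic,Rangeland,672828,12674,2682,7348,0.982,0.996,0.989,0.509
lr,Water,175,113,436,694808,0.608,0.286,0.389,0.417
lr,Trees,2050,1085,5921,686476,0.654,0.257,0.369,0.406
lr,Flooded vegetation,105,55,128,695244,0.656,0.451,0.534,0.544
lr,Crops,616,259,625,694032,0.704,0.496,0.582,0.591
lr,Built area,613,155,408,694356,0.798,0.600,0.685,0.692
lr,Bare ground,3408,1234,5523,685367,0.734,0.382,0.502,0.525
lr,Rangeland,672784,12880,2740,7128,0.981,0.996,0.989,0.498
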