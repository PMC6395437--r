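onset_bin,phase,n,lesion_mean,lesion_sd,cnawm_mean,cnawm_sd,contrast_mean,contrast_sd,nihss_mean,nihss_sd
le96h,pre,30,-1.13,1.05,0.43,0.50,-1.56,1.01,6.3,4.2
le96h,post,12,-0.33,0.61,0.46,0.28,-0.79,0.51,3.2,1.6
4_7d,pre,13,-0.75,0.45,0.20,0.26,-0.95,0.46,5.5,3.7
4_7d,post,11,-0.30,0.34,0.19,0.50,-0.49,0.32,3.1,1.4
8_21d,post,12,-0.05,0.69,0.27,0.57,-0.31,0.57,2.4,0.8
ge22d,post,7,0.82,0.79,0.21,0.35,0.61,0.59,1.6,0.6
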