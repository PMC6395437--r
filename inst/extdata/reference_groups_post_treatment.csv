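group,n,lesion_mean,lesion_sd,cnawm_mean,cnawm_sd,contrast_mean,contrast_sd,nihss_mean,nihss_sd
pre,43,-1.01,0.91,0.36,0.45,-1.37,0.87,6.0,3.9
post_le96h,18,-0.45,0.63,0.34,0.42,-0.80,0.68,3.2,1.6
post_4_7d,14,-0.23,0.53,0.19,0.52,-0.42,0.38,3.1,1.4
post_8_21d,3,0.65,0.39,0.51,0.19,0.14,0.27,2.5,0.7
post_ge22d,7,0.82,0.79,0.21,0.35,0.61,0.59,1.4,0.5
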