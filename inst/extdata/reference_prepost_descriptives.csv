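sample,measure,pre_mean,pre_sd,post_mean,post_sd,d_printed
1,spwss_social_anxiety,21.07,5.04,9.41,7.18,1.88
1,self_focused_attention,5.30,1.48,2.52,1.75,1.72
1,scq_composite,1.38,1.22,-0.91,1.36,1.77
1,depressed_mood_bdi,18.32,11.03,7.94,10.07,0.98
2,spin,41.52,12.72,21.71,15.67,1.39
2,self_focused_attention,4.82,1.80,2.92,1.83,1.05
2,scq_composite,1.42,1.29,-0.74,1.34,1.64
2,depressed_mood_phq,11.17,6.85,5.21,6.17,0.91
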