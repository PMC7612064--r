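sample,direction,process_variable,a,b,c_prime,ab_printed,pm_printed
1,forward,self_focused_attention,-0.013,0.821,-0.039,-0.010,21
1,forward,negative_cognitions,-0.011,1.922,-0.029,-0.021,42
1,forward,depressed_mood,-0.035,0.162,-0.044,-0.006,11
1,reversed,self_focused_attention,-0.053,0.096,-0.006,-0.005,46
1,reversed,negative_cognitions,-0.053,0.073,-0.005,-0.004,43
1,reversed,depressed_mood,-0.053,0.159,-0.022,-0.008,28
2,forward,self_focused_attention,-0.016,0.796,-0.128,-0.013,9
2,forward,negative_cognitions,-0.016,3.199,-0.092,-0.050,35
2,forward,depressed_mood,-0.036,0.428,-0.127,-0.015,11
2,reversed,self_focused_attention,-0.158,0.030,-0.010,-0.005,32
2,reversed,negative_cognitions,-0.158,0.040,-0.007,-0.006,47
2,reversed,depressed_mood,-0.159,0.078,-0.021,-0.012,37
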