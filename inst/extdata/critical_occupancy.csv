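L,p_c,seed,reps,iters
256,0.4045118929138,1,48,5
512,0.405714125719455,1,48,5
1024,0.405825066853508,1,48,5
Inf,0.406732626316242,1,48,5
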