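measure,model_mean,model_sd,lit_mean,lit_sd,n
peak,1.97,0.16,1.44,0.21,4
mean,0.79,0.05,0.66,0.02,4
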