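model,AICc,logLik,K
social_gp,3760.59,-1846.30,34
social_prob,3766.97,-1848.79,34
social_landscape,3767.41,-1839.70,44
social_only,3767.55,-1851.77,32
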