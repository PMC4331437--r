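tissue	genic_pct	promoter_pct
cerebellum	49.36	5.36
frontal_cortex	48.62	5.23
SVZ	48.87	5.53
dentate_gyrus	49.69	4.64
myocardium	48.75	4.89
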