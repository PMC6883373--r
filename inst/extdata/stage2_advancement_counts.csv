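management,cohort,n_advanced,n_selected_total
WW,PS,93,157
WW,GS,64,157
WS,PS,66,157
WS,GS,91,157
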