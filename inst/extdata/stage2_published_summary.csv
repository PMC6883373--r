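cohort,management,n_hybrids,mean_all,mean_top15,best_hybrid,checks_mean,best_check
PS,WW,526,7.7,9.4,11.67,7.2,8.4
GS,WW,516,7.5,9.1,10.44,7.2,8.4
PS,WS,526,3.2,4.7,6.19,2.3,3.3
GS,WS,516,3.2,4.8,6.33,2.3,3.3
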