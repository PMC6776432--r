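cohort,group,n_tested,n_detected,printed_percent
Mexico,T790M,316,64,20.25
Mexico,L858R,316,34,10.76
Mexico,DEL19,316,92,29.11
Mexico,DEL19_PLUS_L858R,316,126,39.87
Colombia,T790M,128,15,11.72
Colombia,L858R,128,12,9.38
Colombia,DEL19,128,22,17.19
Colombia,DEL19_PLUS_L858R,128,34,26.56
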