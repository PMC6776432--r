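target,n_positive_tests,false_negatives,n_negative_tests,false_positives,lod_mutant_copies,lod_wt_copies,lod_display
EGFR_DEL19,120,0,112,1,1,14000,0.01%
EGFR_L858R,138,0,112,1,2.8,14000,0.02%
EGFR_T790M,138,0,112,0,1,14000,0.01%
BRAF_V600,135,1,112,0,1,14000,0.01%
KRAS_EX2,136,0,112,0,2.8,14000,0.02%
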