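target,standard,mean_ct,mean_ct_wt
BRAF_V600,A,26.97,26.97
BRAF_V600,B,29.61,29.99
BRAF_V600,C,33.09,32.91
BRAF_V600,D,36.6,35.94
BRAF_V600,F,38.19,38.06
EGFR_DEL19,A,25.29,25.21
EGFR_DEL19,B,28.82,28.15
EGFR_DEL19,C,32.23,31.43
EGFR_DEL19,D,35.34,34.68
EGFR_DEL19,F,36.85,36.23
EGFR_L858R,A,26.15,26.26
EGFR_L858R,B,29.76,29.9
EGFR_L858R,C,33.72,33.44
EGFR_L858R,D,37.5,36.91
EGFR_L858R,F,39.39,38.95
EGFR_T790M,A,26.9,26.95
EGFR_T790M,B,29.94,29.97
EGFR_T790M,C,33.56,32.96
EGFR_T790M,D,36.67,36.65
EGFR_T790M,G,38.69,39.05
KRAS_EX2,A,29.08,29.17
KRAS_EX2,B,31.59,31.86
KRAS_EX2,C,34.92,34.32
KRAS_EX2,D,38.04,36.10
KRAS_EX2,F,39.26,38.14
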