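area,estimate_pct,ci_low_pct,ci_high_pct
AFR LMI,17.7,14.8,21.0
AMR LMI,83.3,72.2,90.5
EMR LMI,68.3,59.2,76.1
EUR LMI,95.7,91.8,97.8
SEAR LMI,69.4,39.5,88.7
WPR LMI,89.6,67.7,97.3
Urban,84.1,75.6,90.1
Rural,61.2,40.7,78.3
LMI,69.5,56.8,79.8
HIC,95.0,89.8,97.7
World,73.5,63.2,81.8
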