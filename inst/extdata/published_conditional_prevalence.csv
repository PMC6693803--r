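area,facility,prevalence,ci_low,ci_high,source
AFR LMI,0,0.071,0.033,0.110,region-specific
AFR LMI,1,0.142,0.056,0.227,region-specific
AMR LMI,0,0.198,0.165,0.231,region-specific
AMR LMI,1,0.394,0.362,0.426,region-specific
EMR LMI,0,0.128,0.040,0.337,pooled-average
EMR LMI,1,0.254,0.078,0.578,pooled-average
EUR LMI,0,0.128,0.040,0.337,pooled-average
EUR LMI,1,0.254,0.078,0.578,pooled-average
SEAR LMI,0,0.163,0.144,0.182,region-specific
SEAR LMI,1,0.325,0.277,0.373,region-specific
WPR LMI,0,0.090,0.074,0.107,region-specific
WPR LMI,1,0.180,0.167,0.193,region-specific
HIC,NA,0.506,0.426,0.585,meta-analysis
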