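timepoint,annual_mean,annual_median,annual_se,lessfreq_mean,lessfreq_median,lessfreq_se,printed_mean_difference
4,0.784,0.7960,0.201,0.784,0.8260,0.2082,0.0004
5,0.779,0.7960,0.211,0.772,0.7950,0.2201,-0.0074
6,0.768,0.7960,0.229,0.765,0.7950,0.2320,-0.0036
7,0.760,0.7950,0.240,0.754,0.7950,0.2470,-0.0061
8,0.739,0.7680,0.263,0.740,0.7680,0.2569,0.0010
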