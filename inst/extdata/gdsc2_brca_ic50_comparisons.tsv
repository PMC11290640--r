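gene	drug	p_t	p_w	p_m	n_mut	n_unmut
FOXA1	paclitaxel	0.011	0.037	0.157	2	937
BAP1	paclitaxel	0.011	0.014	0.068	15	924
NTRK3	tamoxifen	0.025	0.055	0.014	6	932
ERBB2	gemcitabine	0.031	0.032	0.019	15	927
ETV6	tamoxifen	0.053	0.034	0.033	8	930
PIK3CA	5-fluorouracil	0.085	0.049	0.009	94	855
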