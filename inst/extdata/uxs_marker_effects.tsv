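trait	snp	two_a	d	two_a_over_sp	minor_freq	minor_allele	additive_effect
holocellulose	SNP2	1.1154	0.0619	0.1037	0.47	C	-3.5109
holocellulose	SNP22	1.7470	3.2853	0.1624	0.49	T	-1.7705
alpha_cellulose	SNP10	1.3871	0.3247	0.1562	0.49	C	4.8354
fiber_length	SNP27	0.0758	0.0240	0.9028	0.48	A	-0.0288
fiber_length	SNP56	0.0172	0.0095	0.2049	0.44	C	0.0023
fiber_width	SNP6	1.7748	0.9877	0.8954	0.47	T	-0.01120
microfibril_angle	SNP68	1.6288	0.8427	0.3600	0.48	C	-1.2067
diameter_breast_height	SNP6	1.7632	1.0698	0.3146	0.47	T	0.5013
stem_volume	SNP6	0.0715	-0.0228	0.1780	0.47	T	-0.0151
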