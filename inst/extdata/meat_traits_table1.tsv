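trait	unit	mean_1	sd_1	n_1	mean_2	sd_2	n_2	group_1	group_2
live_weight	kg	40.80	4.57	3	41.50	0.95	3	DDH	DHH
carcass_weight	kg	22.00	2.27	3	23.70	0.64	3	DDH	DHH
shear_force	N	83.20	13.60	3	53.30	8.39	3	DDH	DHH
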