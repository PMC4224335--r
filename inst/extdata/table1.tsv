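# mtDNA haplogroup-cluster distribution by disease status in the Ashkenazi
# Jewish T2DM case-control cohort (1,118 patients, 359 controls).
cluster	n_cases	n_controls	proportion_cases
HV	394	145	0.731
UK	431	128	0.771
JT	163	43	0.791
IW	130	43	0.751
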