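trait	unit	mean_control	sd_control	n_control	mean_case	sd_case	n_case
Age	yr	61.14	9.34	220	60.12	7.99	220
BMI	kg/m2	23.79	3.05	220	25.63	2.98	220
HbA1c	percent	5.43	0.46	220	7.62	1.29	220
Glu0	mg/dL	92.23	7.60	220	165.51	54.30	220
Ins0	uU/mL	8.34	3.36	220	16.71	22.00	220
HOMA_IR	dimensionless	1.91	0.81	220	7.49	12.83	220
QUICKI	dimensionless	0.3522	0.02	220	0.3060	0.030	220
WBC	10^3/uL	1.313	2.02	220	1.317	2.02	220
RBC	10^6/uL	5.370	1.50	220	5.347	1.52	220
meth_chr17_55484635	percent	29.46	3.69	220	26.35	3.33	220
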