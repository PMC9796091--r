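subscale	model	sigma2_o	sigma2_m	sigma2_p	sigma_om	sigma_op	sigma_mp	sigma2_e	neg2ll	aic	df	p_printed	best
conduct	differential	0.266	0.059	0.137	-0.114	-0.173	0.090	0.824	27403.48	27421.48	7	NA	FALSE
conduct	combined	0.191	0.071	0.071	-0.083	-0.083	0.071	0.831	27406.86	27418.86	4	.34	TRUE
conduct	no_parental	0.077	NA	NA	NA	NA	NA	0.923	27413.43	27421.43	2	.04	FALSE
conduct	null	NA	NA	NA	NA	NA	NA	1.000	27417.56	27423.56	1	.04	FALSE
inattention	differential	0.238	0.061	0.144	-0.020	-0.107	0.062	0.685	27605.66	27623.66	7	NA	FALSE
inattention	combined	0.240	0.082	0.082	-0.064	-0.064	0.082	0.726	27608.97	27620.97	4	.35	TRUE
inattention	no_parental	0.199	NA	NA	NA	NA	NA	0.801	27614.01	27622.01	2	.08	FALSE
inattention	null	NA	NA	NA	NA	NA	NA	1.000	27641.47	27647.47	1	<.01	FALSE
hyperactivity	differential	0.115	0.054	0.041	0.037	0.025	0.029	0.728	27536.51	27554.51	7	NA	FALSE
hyperactivity	combined	0.116	0.039	0.039	0.030	0.030	0.039	0.746	27536.99	27548.99	4	.92	TRUE
hyperactivity	no_parental	0.221	NA	NA	NA	NA	NA	0.779	27544.64	27552.64	2	.02	FALSE
hyperactivity	null	NA	NA	NA	NA	NA	NA	1.000	27579.26	27585.26	1	<.01	FALSE
oppositional	differential	0.183	0.059	0.038	-0.028	-0.069	0.035	0.818	27538.14	27556.14	7	NA	FALSE
oppositional	combined	0.122	0.000	0.000	0.000	0.000	0.000	0.878	27541.81	27553.81	4	.30	FALSE
oppositional	no_parental	0.122	NA	NA	NA	NA	NA	0.878	27541.81	27549.81	2	1.00	TRUE
oppositional	null	NA	NA	NA	NA	NA	NA	1.000	27551.79	27557.79	1	<.01	FALSE
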