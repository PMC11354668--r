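ligand	k_on	k_dis	k_d	r_squared
poly-A10	NA	NA	NA	NA
poly-A15	NA	NA	NA	NA
poly-A20	NA	NA	NA	NA
poly-A25	NA	NA	NA	NA
poly-A30	NA	NA	NA	NA
poly-C10	NA	NA	NA	NA
poly-C15	4.27e3	5.81e-3	1.36e-6	0.9117
poly-C20	7.42e3	5.65e-3	7.61e-7	0.8997
poly-C25	NA	NA	NA	NA
poly-C30	NA	NA	NA	NA
poly-G10	6.87e3	2.02e-3	2.95e-7	0.9301
poly-G15	8.42e3	2.30e-3	2.73e-7	0.9676
poly-G20	7.85e3	2.45e-3	3.12e-7	0.9583
poly-G25	7.24e3	5.01e-3	6.92e-7	0.8785
poly-G30	4.39e3	2.45e-3	5.57e-7	0.8844
poly-T10	3.79e3	5.66e-3	1.49e-6	0.9438
poly-T15	4.42e3	4.02e-3	9.09e-7	0.9614
poly-T20	4.50e3	3.74e-3	8.30e-7	0.9628
poly-T25	4.18e3	4.20e-3	1.01e-6	0.9661
poly-T30	2.50e3	3.57e-3	1.43e-6	0.9448
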