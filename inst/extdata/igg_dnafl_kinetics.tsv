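ligand	k_on	k_dis	k_d	r_squared
5XRZ	3.76e3	3.17e-3	8.43e-7	0.9402
6GN7	9.52e3	2.29e-3	2.41e-7	0.9294
4GNX	1.81e3	3.80e-3	2.10e-6	0.9622
7JSG	3.11e3	3.48e-3	1.12e-6	0.9692
2C62	1.85e3	6.00e-3	3.24e-6	0.9251
7XHD	6.29e3	3.28e-3	5.21e-7	0.9229
6SKO	4.26e3	4.54e-3	1.07e-6	0.9636
1RDE	2.91e3	3.18e-3	1.09e-6	0.9661
2CCZ	4.42e3	4.02e-3	9.09e-7	0.9614
6CRM	5.14e3	5.70e-3	1.11e-6	0.9257
1PH1-D	6.97e3	6.14e-3	8.81e-7	0.8856
1OTC	8.24e3	3.41e-3	4.14e-7	0.9031
4JS5	3.34e3	5.78e-3	1.73e-6	0.9447
3UGO	5.38e3	4.27e-3	7.93e-7	0.8999
2A0I	6.39e3	5.57e-3	8.72e-7	0.9134
2KN7	5.06e3	6.08e-3	1.20e-6	0.94
4OU6	5.06e3	4.79e-3	9.47e-7	0.9497
7JSI	2.58e3	4.73e-3	1.83e-6	0.9672
5FGP	2.74e3	4.13e-3	1.51e-6	0.9522
6S3M	6.93e3	8.06e-3	1.16e-6	0.9262
SPA-IgG	4.80e4	7.16e-4	1.49e-8	0.959
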