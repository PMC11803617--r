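# Interfacial thermodynamic properties per temperature (kJ/mol).
# The "unlabeled" column is carried through from the source table but is not
# used by any computation.
temp_K	mu_ice	mu_wat	unlabeled	dgamma_N
240	-50.19	-49.32	0.97	-3.48
245	-50.20	-49.48	1.11	-3.16
250	-50.21	-49.66	1.25	-2.86
255	-50.23	-49.85	1.37	-2.56
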