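motif_class	side	dangle_base	closing_pair	temperature_C	buffer	dG_kcal_mol	sd
initiation				25	PBS	1.96	0.10
stack			GC	25	PBS	-2.24	0.05
stack			CG	25	PBS	-2.17	0.05
stack			GG	25	PBS	-1.84	0.05
stack			GA	25	PBS	-1.30	0.05
stack			AT	25	PBS	-0.88	0.05
dangle	5p	T	G	25	PBS	-0.40	0.04
dangle	3p	T	A	25	PBS	-0.10	0.04
dangle	5p	A	G	25	PBS	-0.45	0.04
dangle	3p	A	T	25	PBS	-0.12	0.04
fluorophore	5p	ROX	T	25	PBS	-0.22	0.04
fluorophore	5p	ROX	A	25	PBS	-0.21	0.04
fluorophore	3p	Alexa532	A	25	PBS	-0.05	0.04
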