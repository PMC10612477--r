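family	species	header	regime	is_paralog
fam001	spA	fam001_spA	M0_kappa2	FALSE
fam001	spB	fam001_spB	M0_kappa2	FALSE
fam001	spC	fam001_spC	M0_kappa2	FALSE
fam002	spA	fam002_spA	M0_kappa2	FALSE
fam002	spB	fam002_spB	M0_kappa2	FALSE
fam002	spC	fam002_spC	M0_kappa2	FALSE
fam003	spA	fam003_spA	M0_kappa2	FALSE
fam003	spB	fam003_spB	M0_kappa2	FALSE
fam003	spC	fam003_spC	M0_kappa2	FALSE
fam004	spA	fam004_spA	M0_kappa2	FALSE
fam004	spB	fam004_spB	M0_kappa2	FALSE
fam004	spC	fam004_spC	M0_kappa2	FALSE
fam005	spA	fam005_spA	M2a_kappa2	FALSE
fam005	spB	fam005_spB	M2a_kappa2	FALSE
fam005	spC	fam005_spC	M2a_kappa2	FALSE
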