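cog_id	category	gene_examples	ambiguous_synthesis
COG0370	Fe(II)	feoB	FALSE
COG2822	Fe(II)	efeU	FALSE
COG1629	Fe(III)-OM	fhuA	FALSE
COG4771	Fe(III)-OM	fepA	FALSE
COG0609	Fe(III)-CM	fhuB	FALSE
COG0614	Fe(III)-CM	fhuD	FALSE
COG1121	divalent_cation	sitABC znuC	FALSE
COG0803	divalent_cation	sitA znuA	FALSE
COG4772	dicitrate	fecA	FALSE
COG4558	heme	hemR hmuT	FALSE
COG1528	storage	bfr ftnA	FALSE
COG0783	storage	dps	FALSE
COG0735	regulators	fur irr	FALSE
COG1321	regulators	mntR ideR	FALSE
COG0318	siderophore_synthesis	entE pvdL asbC	TRUE
COG1021	siderophore_synthesis	entE dhbE	FALSE
COG1535	siderophore_synthesis	entB	FALSE
COG1819	siderophore_synthesis	iroB	FALSE
COG3486	siderophore_synthesis	entF pchE irp2	FALSE
COG7001	siderophore_synthesis	alcA	FALSE
COG7002	siderophore_synthesis	mbtA	FALSE
COG7003	siderophore_synthesis	mxcE	FALSE
COG7004	siderophore_synthesis	asbA	FALSE
COG7005	siderophore_synthesis	sfnaB	FALSE
COG7006	siderophore_synthesis	sbnC	FALSE
COG7007	siderophore_synthesis	pchA	FALSE
COG7008	siderophore_synthesis	pvdJ	FALSE
COG7009	siderophore_synthesis	irp1	FALSE
COG7010	siderophore_synthesis	sfnaD sbnE	FALSE
COG7011	siderophore_synthesis	amphA	FALSE
COG7012	siderophore_synthesis	amphB	FALSE
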