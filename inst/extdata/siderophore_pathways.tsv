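pathway_id	gene_id	cog_id	ambiguous
enterobactin	entB	COG1535	FALSE
enterobactin	entE	COG0318	TRUE
enterobactin	entE	COG1021	FALSE
enterobactin	entF	COG3486	FALSE
salmochelin	iroB	COG1819	FALSE
salmochelin	entE	COG0318	TRUE
salmochelin	entE	COG1021	FALSE
salmochelin	iroC	COG3486	FALSE
alcaligin	alcA	COG7001	FALSE
alcaligin	alcB	COG3486	FALSE
mycobactin	mbtA	COG7002	FALSE
mycobactin	mbtB	COG3486	FALSE
myxochelin	mxcE	COG7003	FALSE
myxochelin	mxcF	COG3486	FALSE
petrobactin	asbA	COG7004	FALSE
petrobactin	asbC	COG0318	TRUE
staphyloferrin_A	sfnaB	COG7005	FALSE
staphyloferrin_A	sfnaD	COG7010	FALSE
staphyloferrin_B	sbnC	COG7006	FALSE
staphyloferrin_B	sbnE	COG7010	FALSE
pyochelin	pchA	COG7007	FALSE
pyochelin	pchE	COG3486	FALSE
pyoverdin	pvdL	COG0318	TRUE
pyoverdin	pvdJ	COG7008	FALSE
yersiniabactin	irp1	COG7009	FALSE
yersiniabactin	irp2	COG3486	FALSE
amphibactin	amphA	COG7011	FALSE
amphibactin	amphB	COG7012	FALSE
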