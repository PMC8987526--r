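source	sign	target	mechanism	relationship_number	feedback
oxidative_stress	activates	tissue_injury	other	1	FALSE
tissue_injury	activates	macrophages	other	2	FALSE
tissue_injury	activates	hypoxia	other	3	FALSE
tissue_injury	activates	wnt_ligand	transcription	4	FALSE
macrophages	activates	wnt_signaling	protein_activity	5	FALSE
wnt_ligand	activates	fzd	binding	6	FALSE
wnt_ligand	activates	lrp5_6	binding	7	FALSE
fzd	activates	dvl1	binding	8	FALSE
lrp5_6	activates	dvl1	binding	8	FALSE
dvl1	activates	axin	binding	8	FALSE
fzd	activates	wnt_signaling	protein_activity	NA	FALSE
lrp5_6	activates	wnt_signaling	protein_activity	NA	FALSE
axin	inhibits	destruction_complex	binding	33	FALSE
destruction_complex	inhibits	tcf_lef	degradation	10	FALSE
wnt_signaling	inhibits	gsk3	protein_activity	14	FALSE
gsk3	inhibits	foxm1	protein_activity	15	FALSE
gsk3	inhibits	ccnd1	degradation	34	FALSE
gsk3	inhibits	myc	degradation	35	FALSE
tcf_lef	activates	myc	transcription	12	FALSE
tcf_lef	activates	ccnd1	transcription	13	FALSE
foxm1	activates	myc	transcription	16	FALSE
foxm1	activates	mapk8	transcription	17	FALSE
mapk8	activates	ccnd1	transcription	36	FALSE
myc	activates	cdk4_6	transcription	18	FALSE
cdk4_6	activates	cyclin_cdk	binding	19	FALSE
ccnd1	activates	cyclin_cdk	binding	20	FALSE
cyclin_cdk	inhibits	rb1	protein_activity	21	FALSE
cyclin_cdk	activates	g1s_dysregulation	other	NA	FALSE
rb1	inhibits	g1s_dysregulation	other	22	FALSE
foxm1	inhibits	g1s_dysregulation	other	23	FALSE
psmd10	inhibits	rb1	degradation	35	FALSE
g1s_dysregulation	activates	proliferation	other	23	FALSE
hypoxia	inhibits	hif1an	protein_activity	24	FALSE
hif1an	inhibits	hif1a	protein_activity	25	FALSE
hypoxia	inhibits	vhl	protein_activity	26	FALSE
vhl	inhibits	hif1a	degradation	27	FALSE
hif1a	activates	tcf_lef	transcription	28	FALSE
wspar	activates	tcf_lef	transcription	29	FALSE
tcf_lef	activates	axin	transcription	30	TRUE
tcf_lef	activates	dkk1	transcription	31	TRUE
dkk1	inhibits	lrp5_6	binding	32	TRUE
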