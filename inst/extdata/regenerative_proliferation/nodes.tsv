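id	label	kind	measurable	genes	sufficient	expected_direction
oxidative_stress	Oxidative stress / initiating insult	process	FALSE		FALSE	none
tissue_injury	Liver tissue injury	process	FALSE		FALSE	none
macrophages	Macrophage activation and wound repair	process	FALSE		FALSE	none
hypoxia	Hypoxia	process	FALSE		FALSE	none
wnt_ligand	Wnt ligand family	ligand_family	TRUE	Wnt1;Wnt2;Wnt4;Wnt6;Wnt11;Wnt16	FALSE	none
wnt_signaling	Wnt signaling activity	process	FALSE		FALSE	none
fzd	Frizzled co-receptors	protein	TRUE	Fzd1;Fzd2	FALSE	none
lrp5_6	Lrp5/6 co-receptors	protein	TRUE	Lrp5;Lrp6	FALSE	none
dvl1	Dishevelled	protein	TRUE	Dvl1	FALSE	none
axin	Axin scaffold	protein	TRUE	Axin1;Axin2	FALSE	none
destruction_complex	Beta-catenin destruction complex	complex	TRUE	Apc	FALSE	none
gsk3	Gsk3 kinase activity	protein	TRUE	Gsk3a;Gsk3b	FALSE	none
tcf_lef	Tcf/Lef:beta-catenin transcription complex	complex	TRUE	Ctnnb1;Ctcf	FALSE	none
wspar	lncRNA WSPAR	gene	FALSE		FALSE	none
dkk1	Dkk1 Wnt signaling inhibitor	protein	FALSE		FALSE	none
hif1an	Hif1an oxygen sensor	protein	FALSE		FALSE	none
hif1a	Hif1a transcription factor	protein	FALSE		FALSE	none
vhl	Von Hippel-Lindau tumor suppressor	protein	TRUE	Vhl	FALSE	none
myc	Myc proto-oncogene	gene	TRUE	Myc	FALSE	none
foxm1	Foxm1 transcription factor	gene	TRUE	Foxm1	FALSE	none
mapk8	Mapk8 (Jnk1)	gene	FALSE		FALSE	none
ccnd1	Cyclin D1	gene	TRUE	Ccnd1	TRUE	up
cdk4_6	Cdk4/6 cyclin-dependent kinases	protein	TRUE	Cdk4;Cdk6	TRUE	up
cyclin_cdk	Cyclin D1:Cdk4/6 complex	complex	FALSE		FALSE	none
rb1	Rb1 transcriptional corepressor	protein	TRUE	Rb1	TRUE	down
psmd10	Psmd10 (gankyrin)	protein	TRUE	Psmd10	TRUE	up
g1s_dysregulation	Dysregulated G1/S transition	process	FALSE		FALSE	none
proliferation	Regenerative/cell proliferation	process	FALSE		FALSE	none
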