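rule_id	label	delta_formula	delta_mass	delta_n	phase
ox	oxidation	+O	15.994915	0	I
diox	di-oxidation	+O2	31.989829	0	I
triox	tri-oxidation	+O3	47.984744	0	I
red	reduction	+H2	2.015650	0	I
dehyd	dehydrogenation	-H2	-2.015650	0	I
hydr	hydration	+H2O	18.010565	0	I
dehydr	dehydration	-H2O	-18.010565	0	loss
demet	demethylation	-CH2	-14.015650	0	I
met	methylation	+CH2	14.015650	0	II
deglyhex	deglycosylation (hexose)	-C6H10O5	-162.052824	0	loss
deglypen	deglycosylation (pentose)	-C5H8O4	-132.042259	0	loss
deglydeoxy	deglycosylation (deoxyhexose)	-C6H10O4	-146.057909	0	loss
degluc	deglucuronidation	-C6H8O6	-176.032088	0	loss
gluc	glucuronidation	+C6H8O6	176.032088	0	II
glyco	glucosylation	+C6H10O5	162.052824	0	II
sulf	sulfation	+SO3	79.956815	0	II
acet	acetylation	+C2H2O	42.010565	0	II
glyc	glycine conjugation	+C2H3NO	57.021464	1	II
taur	taurine conjugation	+C2H5NO2S	107.004099	1	II
cys	cysteine conjugation	+C3H7NO2S	121.019749	1	II
gsh	glutathione conjugation	+C10H15N3O6S	305.068156	3	II
decarb	decarboxylation	-CO2	-43.989829	0	loss
deco	loss of carbon monoxide	-CO	-27.994915	0	loss
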