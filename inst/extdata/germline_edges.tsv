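Source	Regulates	Target	Definite	Module
DTC	act	APX1	definite	notch
DTC	act	LAG2	definite	notch
LAG2	act	GLP1	definite	notch
APX1	act	GLP1	definite	notch
GLP1	act	GLP1ICD	definite	notch
GLP1ICD	act	SEL8	definite	notch
GLP1ICD	act	LAG1	definite	notch
SEL8	act	LAG1	definite	notch
GLP1	act	HOP1	definite	notch
HOP1	act	GLP1ICD	definite	notch
GLP1	act	SEL12	definite	notch
SEL12	act	GLP1ICD	definite	notch
SEL10	rep	GLP1ICD	definite	notch
SEL10	rep	SEL12	definite	notch
LAG1	act	LST1	definite	effectors
LAG1	act	SYGL1	definite	effectors
LST1	rep	GLD1	definite	gld1-accumulation
LST1	act	FBF1B	definite	fbf1-two-state
LST1	rep	FBF1U	definite	fbf1-two-state
SYGL1	act	FBF1B	definite	fbf1-two-state
SYGL1	rep	FBF1U	definite	fbf1-two-state
FBF1B	rep	GLD1	definite	gld1-accumulation
LAG1	act	FBF2	definite	effectors
FBF2	rep	GLD1	definite	gld1-accumulation
FBF1U	act	GLD3	definite	gld2-pathway
FBF1B	rep	GLD3	definite	gld2-pathway
FBF2	rep	GLD3	definite	gld2-pathway
GLD3	act	GLD2	definite	gld2-pathway
NOS3	act	GLD1	optional	gld1-accumulation
GLD2	act	GLD1	optional	gld1-accumulation
FBF1B	rep	SCF_PROM1	optional	scf-prom1
FBF1B	rep	AXIS_SC	optional	axis-sc
FBF2	rep	AXIS_SC	optional	axis-sc
SCF_PROM1	rep	CYE1_CDK2	definite	scf-prom1
GLD1	act	MeioticDev	optional	fate-readout
GLD2	act	MeioticDev	definite	fate-readout
SCF_PROM1	act	MeioticDev	optional	fate-readout
AXIS_SC	act	MeioticDev	optional	fate-readout
CYE1_CDK2	act	StemcellFate	definite	fate-readout
MeioticDev	rep	StemcellFate	definite	fate-readout
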