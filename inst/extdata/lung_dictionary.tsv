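surface	concept_type	normalized	gap
ajcc 8th edition	AjccEdition	8	0
ajcc 7th edition	AjccEdition	7	0
invasive malignant behavior	BehaviorCode	3	0
in situ behavior	BehaviorCode	2	0
other staging group not applicable	ClinicalOtherStagingGroup	88	0
other staging group unknown	ClinicalOtherStagingGroup	99	0
no special clinical stage descriptor	ClinicalStageDescriptor	0	0
post-therapy clinical staging	ClinicalStageDescriptor	Y	0
Malignancy microscopically confirmed on this specimen	MicroConfirmation	EVENT	0
Status post surgical resection of the lung lesion	SurgicalProcedure	EVENT	0
Findings establish the initial diagnosis of lung cancer	InitialDiagnosis	EVENT	0
Specimen from surgical staging procedure received	StagingProcedure	EVENT	0
positive histology confirmation	DiagnosticConfirmation	1	0
positive cytology confirmation	DiagnosticConfirmation	2	0
positive imaging confirmation	DiagnosticConfirmation	4	0
clinically well differentiated	GradeClinical	1	0
clinically moderately differentiated	GradeClinical	2	0
clinically poorly differentiated	GradeClinical	3	0
clinically undifferentiated	GradeClinical	4	0
well differentiated grade i	GradePathological	1	0
moderately differentiated grade ii	GradePathological	2	0
poorly differentiated grade iii	GradePathological	3	0
undifferentiated grade iv	GradePathological	4	0
adenocarcinoma	Histology	8140	0
squamous cell carcinoma	Histology	8070	0
small cell carcinoma	Histology	8041	0
non-small cell carcinoma	Histology	8046	0
right lung	Laterality	1	0
left lung	Laterality	2	0
bilateral lungs	Laterality	3	0
no lymphovascular invasion	LymphovascularInvasion	0	0
lymphovascular invasion present	LymphovascularInvasion	1	0
ajcc staging system used	OtherStagingSystem	0	0
alternative staging system used	OtherStagingSystem	9	0
pm0 no distant metastasis	PathologicM	0	0
pm1 distant metastasis present	PathologicM	1	0
pn0 nodal status	PathologicN	0	0
pn1 nodal status	PathologicN	1	0
pn2 nodal status	PathologicN	2	0
pn3 nodal status	PathologicN	3	0
no special pathologic stage descriptor	PathStageDescriptor	0	0
post-therapy pathologic staging	PathStageDescriptor	Y	0
pt1a primary tumor	PathologicT	1a	0
pt1b primary tumor	PathologicT	1b	0
pt2a primary tumor	PathologicT	2a	0
pt2b primary tumor	PathologicT	2b	0
pt3 primary tumor	PathologicT	3	0
pt4 primary tumor	PathologicT	4	0
no perineural invasion	PerineuralInvasion	0	0
perineural invasion present	PerineuralInvasion	1	0
upper lobe	PrimarySite	C341	0
middle lobe	PrimarySite	C342	0
lower lobe	PrimarySite	C343	0
main bronchus	PrimarySite	C340	0
lung, nos	PrimarySite	C349	0
no regional lymph node surgery	NodeSurgeryScope	0	0
regional lymph node dissection performed	NodeSurgeryScope	4	0
lymph node surgery extent unknown	NodeSurgeryScope	9	0
no visceral pleural invasion	SSF2	000	0
visceral pleural invasion identified	SSF2	010	0
mediastinal nodes not sampled	SSF5	000	0
mediastinal node dissection performed	SSF5	010	0
egfr mutation detected	SSF6	010	0
egfr wild type	SSF6	020	0
egfr testing not performed	SSF6	988	0
alk translocation positive	SSF7	010	0
alk translocation negative	SSF7	020	0
surgical margins free of tumor	SurgicalMargins	0	0
surgical margins involved by tumor	SurgicalMargins	1	0
lung, left upper lobe	PrimarySiteLaterality	C1261076	0
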