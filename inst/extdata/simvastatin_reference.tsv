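section	term	frequency	p_adjusted	ddi_gold
fda_drug	Cyclosporine	35	0	Y
fda_drug	Warfarin	23	0	Y
fda_drug	Diltiazem	19	0	Y
fda_drug	Ticlopidine	18	0	N
fda_drug	Clopidogrel	18	0	N
fda_drug	Clarithromycin	17	0	Y
fda_drug	Amiodarone	17	0	Y
fda_drug	Itraconazole	15	0	Y
fda_drug	Aspirin	15	0.023	Y
fda_drug	Verapamil	12	0	Y
fda_drug	Rifampin	11	0	Y
fda_drug	Ketoconazole	11	0	Y
fda_drug	Amlodipine	9	0	Y
fda_drug	pitavastatin	9	0.0083	Y
fda_drug	Ritonavir	7	0	Y
fda_drug	Digoxin	7	0	Y
fda_drug	Midazolam	7	0	N
fda_drug	Erythromycin	6	0	Y
fda_drug	Imatinib Mesylate	5	0	Y
fda_drug	Colchicine	5	0	Y
fda_drug	Tacrolimus	5	0	Y
fda_drug	Nifedipine	5	0.000083	Y
fda_drug	Sirolimus	5	0.0016	Y
fda_drug	Lisinopril	5	0.0032	N
fda_drug	Atenolol	5	0.0053	N
fda_drug	Ramipril	5	0.026	N
fda_drug	Nelfinavir	4	0	Y
fda_drug	nefazodone	4	0	Y
fda_drug	Ranolazine	4	0	Y
fda_drug	Troglitazone	4	0	Y
fda_drug	Carbamazepine	4	0	Y
fda_drug	Fluconazole	4	0	Y
fda_drug	Sitagliptin Phosphate	4	0.0000052	N
protein	Cytochrome P-450 CYP3A	93	0	
protein	CYP3A4 protein, human	57	0	
protein	CYP3A protein, human	34	0	
protein	Mixed Function Oxygenases	16	0	
protein	Aryl Hydrocarbon Hydroxylases	16	0.0024	
protein	Oxidoreductases, N-Demethylating	4	0.0018	
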