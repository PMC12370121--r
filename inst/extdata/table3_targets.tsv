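protein	type	inference_score	situation	novelty	pmids
RASGRP1	Risk Protein	0.93	Potential target	Novel	34199962, 34777472
NFATC1	Interaction Partner	0.93	Potential target	Novel	31972421, 34681582
RELA	Interaction Partner	0.92	Potential target	Novel	34750358, 37457726
ETS1	Interaction Partner	0.92	Potential target	Novel	38821936, 34199962
LCK	Interaction Partner	0.90	Potential target	Novel	36910149, 38473928
PIK3R1	Interaction Partner	0.90	Potential target	Novel	36992829
BATF	Risk Protein	0.90	Potential target	Novel	38821936
TNFRSF1A	Risk Protein	0.93	Identified target	Previously studied	37396624
IL1R1	Interaction Partner	0.92	Identified target	Previously studied	DrugBank
IL6ST	Interaction Partner	0.91	Identified target	Previously studied	35140805
CD40	Risk Protein	0.90	Identified biomarker	Previously studied	Biomarker Database
TGFB1	Risk Protein	0.90	Identified target	Previously studied	25967237
PRKCB	Risk Protein	0.89	Potential target	Novel	33667569
RUNX1	Risk Protein	0.89	Potential target	Previously studied	36625319, 34737275
IRAK1	Risk Protein	0.89	Identified target	Previously studied	Biomarker
FYN	Interaction Partner	0.88	Potential target	Novel	33714238, 36740671, 36693907
SH2B3	Risk Protein	0.88	Identified target	Previously studied	32879140, 33067605
CRP	Risk Protein	0.88	Identified biomarker	Previously studied	34880861, 35379209
AIM2	Risk Protein	0.88	Identified target	Previously studied	37426634, 33976384
FLT3	Risk Protein	0.88	Potential target	Previously studied	33003568, 38238321
IL2RA	Interaction Partner	0.87	Potential target	Previously studied	31253980
IRF8	Risk Protein	0.87	Identified target	Previously studied	37066336, 33673123
PTPN2	Risk Protein	0.87	Identified biomarker	Previously studied	Biomarker
PTPN11	Risk Protein	0.86	Identified target	Previously studied	35265082
PTPN22	Risk Protein	0.86	Identified biomarker	Previously studied	35637605
AIRE	Risk Protein	0.85	Identified biomarker	Previously studied	Biomarker Database, 34199962, 32849810
MED1	Risk Protein	0.85	Identified target	Previously studied	31092410, 34777472
CDK2	Risk Protein	0.85	Potential target	Previously studied	38818077
PLD4	Risk Protein	0.84	Identified target	Previously studied	34199962, 32849810
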