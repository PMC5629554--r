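drug	cancer_abbreviation	n_trials
Abarelix	BRCA	0
Ado-trastuzumab emtansine	GCA	3
Ado-trastuzumab emtansine	Lung cancer	6
Afatinib	CRC	4
Afatinib	GCA	5
Afatinib	HNC	17
Afatinib	PACA	3
Afatinib	THC	0
Aldesleukin	Lymphoma	44
Alitretinoin	Lymphoma	0
Axitinib	CRC	5
Axitinib	GCA	2
Axitinib	KNC	39
Axitinib	Liver cancer	6
Axitinib	PACA	2
Axitinib	Sarcoma	2
Axitinib	THC	4
Bevacizumab	THC	3
Bexarotene	KS	1
Bicalutamide	BRCA	9
Bosutinib	GCA	0
Cabozantinib	CRC	1
Cabozantinib	GCA	1
Cabozantinib	KNC	6
Cabozantinib	Liver cancer	2
Cabozantinib	Lung cancer	8
Cabozantinib	PACA	3
Cabozantinib	Sarcoma	3
Carfilzomib	Lymphoma	20
Cetuximab	BRCA	14
Cetuximab	Lung cancer	77
Cetuximab	PACA	31
Cetuximab	THC	1
Crizotinib	THC	1
Dabrafenib	CRC	1
Dabrafenib	GCA	0
Dabrafenib	KNC	1
Dabrafenib	Liver cancer	1
Dabrafenib	THC	3
Dasatinib	GCA	0
Degarelix	BRCA	1
Denileukin diftitox	KNC	2
Denileukin diftitox	Melanoma	9
Enzalutamide	BRCA	9
Erlotinib hydrochloride	BRCA	25
Erlotinib hydrochloride	CRC	31
Erlotinib hydrochloride	HNC	62
Erlotinib hydrochloride	THC	1
Estramustine	BRCA	2
Fluoxymesterone	PCa	0
Flutamide	BRCA	0
Fulvestrant	PCa	3
Gefitinib	BRCA	12
Gefitinib	CRC	12
Gefitinib	HNC	43
Gefitinib	PACA	4
Gefitinib	THC	2
Ibritumomab tiuxetan	Leukemia	9
Lapatinib ditosylate	CRC	7
Lapatinib ditosylate	GCA	13
Lapatinib ditosylate	HNC	20
Lapatinib ditosylate	Lung cancer	7
Lapatinib ditosylate	PACA	5
Lapatinib ditosylate	THC	1
Leuprolide acetate	BRCA	12
Methyltestosterone	PCa	0
Nilotinib	GCA	0
Nilutamide	BRCA	0
Obinutuzumab	Lymphoma	44
Ofatumumab	Lymphoma	64
Panitumumab	BRCA	5
Panitumumab	HNC	31
Panitumumab	Lung cancer	16
Panitumumab	PACA	7
Panitumumab	THC	0
Pazopanib hydrochloride	CRC	4
Pazopanib hydrochloride	GCA	4
Pazopanib hydrochloride	Liver cancer	5
Pazopanib hydrochloride	PACA	6
Pazopanib hydrochloride	THC	6
Peginterferon Alfa-2b	Leukemia	14
Peginterferon Alfa-2b	Lymphoma	5
Peginterferon Alfa-2b	Sarcoma	1
Pertuzumab	GCA	4
Pertuzumab	Lung cancer	3
Pomalidomide	Lymphoma	5
Ponatinib hydrochloride	GCA	0
Ramucirumab	CRC	6
Ramucirumab	KNC	5
Ramucirumab	Liver cancer	7
Ramucirumab	PACA	1
Ramucirumab	Sarcoma	1
Ramucirumab	THC	0
Regorafenib	KNC	4
Regorafenib	Liver cancer	8
Regorafenib	Melanoma	4
Regorafenib	PACA	4
Regorafenib	Sarcoma	5
Regorafenib	THC	1
Sorafenib tosylate	CRC	23
Sorafenib tosylate	GCA	10
Sorafenib tosylate	Melanoma	30
Sorafenib tosylate	PACA	25
Sorafenib tosylate	Sarcoma	16
Sunitinib malate	CRC	14
Sunitinib malate	Liver cancer	16
Sunitinib malate	Sarcoma	17
Sunitinib malate	THC	6
Tamoxifen citrate	PCa	4
Temsirolimus	BRCA	129
Temsirolimus	BrainC	40
Temsirolimus	PACA	50
Thalidomide	Lymphoma	174
Toremifene	PCa	5
Tositumomab and Iodine I 131 Tositumomab	Leukemia	4
Trastuzumab	Lung cancer	22
Vandetanib	BRCA	11
Vandetanib	BrainC	7
Vandetanib	CRC	7
Vandetanib	GCA	2
Vandetanib	HNC	22
Vandetanib	KNC	4
Vandetanib	Lung cancer	29
Vandetanib	PACA	3
Vemurafenib	CRC	5
Vemurafenib	GCA	0
Vemurafenib	KNC	0
Vemurafenib	Liver cancer	0
Vemurafenib	THC	4
Ziv-aflibercept	BrainC	3
Ziv-aflibercept	KNC	4
Ziv-aflibercept	Lung cancer	5
Ziv-aflibercept	THC	1
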