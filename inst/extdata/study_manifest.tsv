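series_id	species	ischemic_period_min	reperfusion_period_h	n_mcao	n_sham	platform
E-MEXP-2547	mouse	30	24, 240	5	5	Affymetrix GeneChip Mouse Gene 1.0 ST Array
GSE23160	mouse	120	2, 8, 24	24	8	Illumina MouseRef-8 v2.0 expression beadchip
GSE30655	mouse	60	24	7	3	Affymetrix Mouse Genome 430 2.0 Array
GSE58720	mouse	90	24	3	3	Agilent-028005 SurePrint G3 Mouse GE 8 x 60 K Microarray
E-MEXP-2222	rat	90	6, 24	12	3	Affymetrix Rat Genome 230 2.0 Array
GSE33725	rat	NA	2, 6	6	6	Agilent-014879 Whole Rat Genome Microarray 4 x 44 K G4131F
GSE52001	rat	120	144	3	3	Agilent-028282 Whole Rat Genome Microarray 4 x 44 K v3
GSE61616	rat	120	168	5	5	Affymetrix Rat Genome 230 2.0 Array
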