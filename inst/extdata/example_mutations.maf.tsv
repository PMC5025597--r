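Tumor_Sample_Barcode	Chromosome	Start_Position	Reference_Allele	Tumor_Seq_Allele2
T01	chr1	101	C	T
T01	chr1	250	G	A
T01	chr2	77	C	G
T02	chr1	15	A	G
T02	chr2	3021	T	C
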