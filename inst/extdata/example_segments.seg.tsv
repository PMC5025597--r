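sample	chrom	start	end	value
T01	chr1	1	5000	2
T01	chr1	5001	9000	4
T01	chr2	1	7000	2
T02	chr1	1	4000	3
T02	chr1	4001	8000	1
T02	chr2	1	6000	2
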