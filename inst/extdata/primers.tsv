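region	forward_name	forward	reverse_name	reverse
V1-V3	A17F	GTTTGATCCTGGCTCAG	515R	TTACCGCGGCMGCSGGCA
V2-V3	16S_BV2f	AGTGGCGGACGGGTGAGTAA	HDA-2	GTATTACCGCGGCTGCTGGCAC
V3	v3_579F	THTTSSRCAATGGRSGVA	v3_779R	GKNSCRAGCSTTRHYCGG
V3-V4	V3F	CCTACGGGAGGCAGCAG	V4R	GGACTACHVGGGTWTCTAAT
V4	F515	GTGCCAGCMGCCGCGGTAA	R806	CCTGATGHVCCCAWAGATTA
V4-V6	519F	GTGCCAGCTGCCGCGGTAATA	1114R	GGGGTTGCGCTCGTTGC
V6	v6_1183F	CCGCCTGGGGASTACGVH	v6_1410R	AGTCCCRYAACGAGCGCA
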