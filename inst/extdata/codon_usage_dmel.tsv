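codon	per_mille
TTT	12.7
TTC	21.8
TTA	4.4
TTG	13.5
CTT	8.7
CTC	14.5
CTA	8.1
CTG	38.6
ATT	16.4
ATC	22.5
ATA	9.6
ATG	23.1
GTT	10.9
GTC	14.6
GTA	5.7
GTG	26.9
TCT	7.4
TCC	16.8
TCA	9.5
TCG	17.4
CCT	7.6
CCC	17.1
CCA	12.8
CCG	14.9
ACT	8.7
ACC	22.2
ACA	11.0
ACG	11.9
GCT	13.9
GCC	33.6
GCA	10.9
GCG	9.8
TAT	11.4
TAC	17.3
TAA	0.7
TAG	0.5
CAT	10.7
CAC	13.6
CAA	15.9
CAG	28.6
AAT	21.0
AAC	25.8
AAA	17.0
AAG	39.9
GAT	26.5
GAC	25.9
GAA	19.7
GAG	41.4
TGT	5.9
TGC	11.5
TGA	0.4
TGG	10.0
CGT	8.9
CGC	17.8
CGA	8.6
CGG	10.1
AGT	11.2
AGC	25.2
AGA	4.9
AGG	6.3
GGT	13.0
GGC	25.2
GGA	17.5
GGG	3.9
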