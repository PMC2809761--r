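codon	per_1000
AAA	15.24
AAC	8.33
AAG	16.74
AAT	16.95
ACA	30.63
ACC	3.84
ACG	4.3
ACT	7.91
AGA	33.28
AGC	6.19
AGG	2.86
AGT	20.89
ATA	24.51
ATC	10.36
ATG	11.79
ATT	5.78
CAA	76.48
CAC	13.58
CAG	19.74
CAT	5.85
CCA	4.44
CCC	27.37
CCG	13.41
CCT	34.34
CGA	14.25
CGC	13.66
CGG	21.19
CGT	10.64
CTA	13.81
CTC	14.7
CTG	10.65
CTT	12.51
GAA	7.81
GAC	19.16
GAG	20.38
GAT	9.2
GCA	16.81
GCC	9.55
GCG	8.25
GCT	21.65
GGA	3.9
GGC	21.32
GGG	25.78
GGT	26.62
GTA	28.84
GTC	12.76
GTG	3.12
GTT	18.99
TAA	13.06
TAC	14.47
TAG	8.28
TAT	18.62
TCA	7.08
TCC	13.64
TCG	32.32
TCT	14.18
TGA	23
TGC	4.94
TGG	13.46
TGT	12.8
TTA	4.21
TTC	10.77
TTG	7.43
TTT	21.37
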