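species	members	proteome	percent_printed
A. thaliana	105	25498	0.41
O. sativa	175	35825	0.49
Z. mays	71	39591	0.18
P. patens	54	35398	0.15
E. siliculosus	339	16256	2.08
G. max	162	55897	0.29
S. lycopersicum	130	33952	0.38
C. baccatum	87	35874	0.24
C. annuum	85	35884	0.24
C. chinense	96	35009	0.27
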