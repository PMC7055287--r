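name	pattern
WBOXATNPR1	TTGAC
ASF1MOTIFCAMV	TGACG
GCCCORE	GCCGCC
SEBFCONSSTPR10A	YTGTCWC
IBOX	GATAAG
-10PEHVPSBD	TATTCT
TBOXATGAPB	ACTTTG
INRNTPSADB	YTCANTYY
GT1CONSENSUS	GRWAAW
MYBCORE	CNGTTR
MYCATERD1	CATGTG
MYCATRD22	CACATG
MYBATRD22	CTAACCA
MYB2AT	TAACTG
MYB1AT	WAACCA
CAATBOX1	CAAT
TATABOX5	TTATTT
ARR1AT	NGATT
WRKY71OS	TGAC
GATABOX	GATA
DOFCOREZM	AAAG
CACTFTPPCA1	YACT
EBOXBNNAPA	CANNTG
ACGTATERD1	ACGT
ABRELATERD1	ACGTG
ROOTMOTIFTAPOX1	ATATT
POLLEN1LELAT52	AGAAA
GTGANTG10	GTGA
CBFHV	RYCGAC
LTRECOREATCOR15	CCGAC
PREATPRODH	ACTCAT
SURECOREATSULTR11	GAGAC
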