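# Regulatory elements of the 50-kb Pou5f1 locus, chr17:35,484,600-35,534,600 (mm10).
# Enhancer groups E1/E2 as annotated intervals; promoters P1 (Pou5f1) and P2
# (Tcf19) as 600-bp windows centered on the annotated positions.
chr17	35485600	35486100	E1
chr17	35502100	35502700	E2
chr17	35505700	35506300	P1
chr17	35516500	35517100	P2
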