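# Regulatory elements of the 120-kb Sox2 locus, chr3:34,645,000-34,765,000 (mm10).
# Promoter as a 600-bp window centered on the annotated position; the distal
# strong enhancer as its annotated interval.
chr3	34650100	34650700	promoter
chr3	34756500	34761500	enhancer
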