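# micro-RNA transcription-factor interaction model (9 species, 11 reactions)
r1: miR_gene + TF1 -> miR_gene_TF1
r2: miR_gene_TF1 -> miR_gene + TF1
r3: miR_gene + TF2 -> miR_gene_TF2
r4: miR_gene_TF2 -> miR_gene + TF2
r5: miR_gene_TF2 -> miR_gene_TF2 + miR
r6: miR -> Sink
r7: Signal -> Signal + TF1_mRNA
r8: TF1_mRNA -> Sink
r9: TF1_mRNA + miR -> miR
r10: TF1_mRNA -> TF1_mRNA + TF1
r11: TF1 -> Sink
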