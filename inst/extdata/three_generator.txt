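# artificial 3-generator model (7 species, 9 reactions)
R1: A1 -> A1 + B1
R2: A2 -> A2 + B2
R3: A3 -> A3 + B3
R4: A2 + B3 -> B3
R5: B1 + A2 -> 0
R6: B1 + B3 -> 2 B2
R7: A1 + A2 -> 0
R8: A1 + A2 + A3 -> D1
R9: D1 + B1 -> 2 B1 + A2
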