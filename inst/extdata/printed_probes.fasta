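>sc1 sc1 wt (standard)
GCUGCGGUGUGGAAGGAGUGGUCGGGUUGCGCAGCG
>sc1_g4m sc1 g4m (standard)
GCUGCAAUGUGGAAAAAGUGGUCGGGUUGCGCAGCG
>mll1_probe MLL1 wt (binding_probe) 220-258
CGGCGGGAAGCAGCGGGGCUGGGGUUCCAGGGGGAGCGG
>mll1_probe_g4m MLL1 g4m (binding_probe)
CGGCAAAAAGCAGCGGGGCUAAAAUUCCAGGGGGAGCGG
>mll4_probe MLL4 wt (binding_probe) 267-310
CCAGCGGGGCCGGGGACGGGGUCGGGGCCGGGGCUGGGGCCCGA
>mll4_probe_g4m MLL4 g4m (binding_probe)
CCAGCAAAACCGGGGACGGGGUCAAAACCGGGGCUGGGGCCCGA
>mll1_inline MLL1 wt (probing)
GGCCGCGGCGGCGGCGGCGGGAAGCAGCGGGGCUGGGGUUCCAGGGGGAGCGGCCGCCGCCUC
>mll1_inline_g4m MLL1 g4m (probing)
GGCCGCGGCGGCGGCGGCGAGAAGCAGCGAAGCUGAAGUUCCAGAAAGAGCGGCCGCCGCCUC
>mll4_inline MLL4 wt (probing)
GGCCCGCGGGUCCAGCGGGGCCGGGGACGGGGUCGGGGCCGGGGCUGGGGCCCGAGUCGAGGCUG
>mll4_inline_g4m MLL4 g4m (probing)
GGCCCGCGGGUCCAGCGAAGCCGAAGACGAAGUCGAAGCCGAAGCUGAAGCCCGAGUCGAGGCUG
>pgl3_mll4_insert MLL4 wt (reporter) 262-318
CGGGUCCAGCGGGGCCGGGGACGGGGUCGGGGCCGGGGCUGGGGCCCGAGUCGAGGC
>pgl3_mll4_mutant MLL4 g4m (reporter)
CGCGUCCAGCGCGCCCGCGCCCGCGCCCGCGCCCGCGCCUGGGCCCCGAGUCGAGGC
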