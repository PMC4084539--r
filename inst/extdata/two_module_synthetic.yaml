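# Two-module orofacial-neurocranial grouping of the same synthetic landmark
# ids: facial block (anterior oral-nasal, molar-palate, orbit,
# zygomatic-pterygoid) versus neurocranial block (vault, basicranium).
orofacial: [lm1, lm2, lm3, lm4, lm5, lm6, lm7, lm8, lm9, lm10,
            lm11, lm12, lm13, lm14, lm15, lm16, lm17, lm18,
            lm19, lm20, lm21, lm22, lm23, lm24, lm25,
            lm26, lm27, lm28, lm29, lm30, lm31, lm32, lm33]
neurocranial: [lm34, lm35, lm36, lm37, lm38, lm39,
               lm40, lm41, lm42, lm43, lm44, lm45, lm46, lm47, lm48, lm49]
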