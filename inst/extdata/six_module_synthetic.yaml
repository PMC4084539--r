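# Six-module cranial partition over generic landmark ids lm1..lm49
# (module sizes 10/8/7/8/6/10: anterior oral-nasal, molar-palate, orbit,
# zygomatic-pterygoid, cranial vault, basicranium). Landmark identities are
# synthetic placeholders: real datasets should supply their own mapping.
AON: [lm1, lm2, lm3, lm4, lm5, lm6, lm7, lm8, lm9, lm10]
MOL: [lm11, lm12, lm13, lm14, lm15, lm16, lm17, lm18]
ORB: [lm19, lm20, lm21, lm22, lm23, lm24, lm25]
ZP: [lm26, lm27, lm28, lm29, lm30, lm31, lm32, lm33]
CV: [lm34, lm35, lm36, lm37, lm38, lm39]
BC: [lm40, lm41, lm42, lm43, lm44, lm45, lm46, lm47, lm48, lm49]
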