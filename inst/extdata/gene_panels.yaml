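autoimmune:
  category: autoimmune diabetes
  genes: [AIRE, FOXP3, IL2RA, ITCH, LRBA, SKAP2, STAT1, STAT3]
mody_neonatal:
  category: MODY and neonatal diabetes
  genes: [GCK, HNF1A, HNF4A, HNF1B, ABCC8, KCNJ11, INS]
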