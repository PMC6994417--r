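# Reference cohort profile: encodes the published cohort structure the
# synthetic generator emulates. Counts are cohort-level quantities; the
# burden list is synthetic subject to the published median (135) and range
# (6-204) only, since per-patient counts are not reported individually.
cohort:
  n_discovery: 21
  n_extension: 50
  n_matched_discovery: 4
  n_matched_extension: 8
  n_pon: 20
  n_hyperplastic: 8
  n_rna: 18
exome_mb: 54.0
titv:
  ti: 1676
  tv: 857
gc_bias: 0.6
n_background_genes: 200
genes:
  wes:
    # recurrently mutated genes with published mutated-tumor counts
    - FAT1
    - KMT2C
    - TET2
    - KMT2D
    - NOTCH1
    - NOTCH2
    - CREBBP
    - ATM
    - TP63
    - KMT2A
    - SETD2
    - DNMT3A
    - ASXL3
    - CHD1
    - MBD4
    - JAK3
    - TP53
    - STK3
    - LATS1
    - STAT6
    # additional exome-screen genes recurrent in two tumors each
    - SPEN
    - BCOR
    - ZRSR2
    - SF3B1
    - U2AF1
    - SRSF2
    - PHF6
    - CTCF
    - SMC1A
    - SMC3
    - RAD21
    - STAG2
    - ATRX
    - DDX3X
    - KDM5C
    - CHD2
    - CHD3
    - NCOR1
    - NCOR2
    - TRRAP
    - HUWE1
    - UBR5
    - FBXW7
    - MGA
    - MED12
    - TET3
    - IDH1
    - MSH2
    - MSH6
    - POLE
    - POLQ
    - BRCA2
    # exome-screen singletons (one mutated tumor each)
    - TTN
    - MUC16
    - OBSCN
    - SYNE1
    - NEB
    - CSMD1
    - CSMD3
    - LRP1B
    - FAT2
    - FAT3
    - FAT4
    - DST
    - PCLO
    - RYR1
    - RYR2
    - RYR3
    - ANK2
    - ANK3
    - DNAH5
    - DNAH9
    - DNAH11
    - USH2A
    - FLG
    - HMCN1
    - ADGRV1
    - PKHD1
    - COL6A3
    - COL11A1
    - LAMA1
    - LAMA2
    - XIRP2
    - APOB
    - SPTA1
    - PLEC
    - AHNAK
    - AHNAK2
    - MACF1
    - DMD
    - CNTNAP2
    - ZFHX4
  literature:
    # lymphoma genes added to the panel, not recorded in the discovery set
    - RHOA
    - IDH2
    - CD28
    - TNFAIP3
    - APC
    - CHD8
    - ZAP70
    - NF1
    - TNFRSF14
    - TRAF3
    - FOXO1
    - BCORL1
    - KDM6A
    - STAT3
    - STAT5B
    - JAK1
    - JAK2
    - PLCG1
    - CARD11
    - VAV1
    - CD58
    - FYN
    - LCK
    - ITK
    - PDGFRA
    - PIK3CA
    - PTEN
    - RB1
    - CDKN2A
    - EZH2
    - EP300
    - ARID1A
    - ARID2
    - SMARCA4
    - BCL11B
    - GATA3
    - TBX21
    - RUNX1
    - IKZF1
    - ETV6
    - WT1
    - MYC
    - BRAF
    - KRAS
    - NRAS
gene_freqs:
  FAT1: 28
  KMT2C: 23
  TET2: 16
  KMT2D: 16
  NOTCH1: 16
  NOTCH2: 14
  CREBBP: 11
  ATM: 11
  TP63: 9
  KMT2A: 8
  SETD2: 7
  DNMT3A: 6
  ASXL3: 6
  CHD1: 5
  MBD4: 5
  JAK3: 5
  TP53: 5
  STK3: 4
  LATS1: 3
  STAT6: 2
  SPEN: 2
  BCOR: 2
  ZRSR2: 2
  SF3B1: 2
  U2AF1: 2
  SRSF2: 2
  PHF6: 2
  CTCF: 2
  SMC1A: 2
  SMC3: 2
  RAD21: 2
  STAG2: 2
  ATRX: 2
  DDX3X: 2
  KDM5C: 2
  CHD2: 2
  CHD3: 2
  NCOR1: 2
  NCOR2: 2
  TRRAP: 2
  HUWE1: 2
  UBR5: 2
  FBXW7: 2
  MGA: 2
  MED12: 2
  TET3: 2
  IDH1: 2
  MSH2: 2
  MSH6: 2
  POLE: 2
  POLQ: 2
  BRCA2: 2
  TTN: 1
  MUC16: 1
  OBSCN: 1
  SYNE1: 1
  NEB: 1
  CSMD1: 1
  CSMD3: 1
  LRP1B: 1
  FAT2: 1
  FAT3: 1
  FAT4: 1
  DST: 1
  PCLO: 1
  RYR1: 1
  RYR2: 1
  RYR3: 1
  ANK2: 1
  ANK3: 1
  DNAH5: 1
  DNAH9: 1
  DNAH11: 1
  USH2A: 1
  FLG: 1
  HMCN1: 1
  ADGRV1: 1
  PKHD1: 1
  COL6A3: 1
  COL11A1: 1
  LAMA1: 1
  LAMA2: 1
  XIRP2: 1
  APOB: 1
  SPTA1: 1
  PLEC: 1
  AHNAK: 1
  AHNAK2: 1
  MACF1: 1
  DMD: 1
  CNTNAP2: 1
  ZFHX4: 1
per_sample_burden:
  - 6
  - 18
  - 30
  - 45
  - 60
  - 75
  - 88
  - 100
  - 115
  - 128
  - 135
  - 142
  - 150
  - 158
  - 165
  - 172
  - 180
  - 186
  - 192
  - 198
  - 204
contamination:
  germline_per_tumor: 50
  artifact_per_tumor: 20
  germline_pool: 300
  artifact_pool: 100
  artifact_dup: 10
survival:
  n_clinical: 61
  gene: FAT1
  median_mutated: 11.0
  median_wildtype: 26.0
  survival_at_36m: 0.24
  followup_range:
    - 1.0
    - 78.0
seed: 42
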