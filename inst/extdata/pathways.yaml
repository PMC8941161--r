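# Default pathway rule set for trophic classification of sponge-symbiont MAGs.
#
# Each pathway lists gene symbols mapped to the accessions (KO, COG or HMM
# model names) accepted as evidence for that gene.  A gene counts as matched
# when ANY of its accessions is present in the MAG's merged annotation index;
# the pathway rule (all_of / any_of / k_of_n) then decides presence.
#
# class: fixation   -> complete pathway promotes the MAG to autotroph
#        energy     -> complete pathway supports a lithoheterotrophic call
#        flag_only  -> never changes the lifestyle label, only sets its flag
#
# The accession lists are provisional defaults drawn from standard KEGG/COG
# usage for each marker; override this file for production analyses.
pathways:
  CBB:
    class: fixation
    rule: all_of
    flag: ~
    genes:
      rbcL: [K01601]
      prkB: [K00855]
  rTCA:
    class: fixation
    rule: all_of
    flag: ~
    genes:
      aclAB: [K15230, K15231, K15232, K15233]
      porA: [K00169, K00170, K00171, K00172, K03737]
  HP4HB:
    class: fixation
    rule: all_of
    flag: ~
    genes:
      accC: [K01964, K15036, K15037]
      abfD: [K14534]
  WL_NiCODH:
    class: fixation
    rule: all_of
    flag: ~
    genes:
      cooS: [K00198, COG1151, NiCODH]
      acsB: [K14138]
  Mo_CODH:
    class: energy
    rule: all_of
    flag: CO_oxidation
    genes:
      coxS: [K03518]
      coxM: [K03519]
      coxL: [K03520, coxL_form1]
      coxG: [K03521, coxG]
  Sox:
    class: energy
    rule: all_of
    flag: thiosulfate_oxidation
    genes:
      soxB: [K17224]
      soxC: [K17225]
  Hyd3b:
    class: energy
    rule: any_of
    flag: H2_oxidation
    genes:
      hyhL: [K18016, Hyd_3b]
  AoxAB:
    class: energy
    rule: all_of
    flag: arsenite_oxidation
    genes:
      aoxA: [K08354]
      aoxB: [K08355]
  AmoPmo:
    class: energy
    rule: all_of
    flag: ammonia_oxidation
    genes:
      amoA: [K10944]
      amoB: [K10945]
      amoC: [K10946]
  NxrAB:
    class: energy
    rule: all_of
    flag: nitrite_oxidation
    genes:
      nxrA: [K00370]
      nxrB: [K00371]
  anaplerotic:
    class: flag_only
    rule: any_of
    flag: anaplerotic
    genes:
      pyc: [K01958]
      ppc: [K01595]
      pckA: [K01610]
      mez: [K00029]
  PFOR_fermentation:
    class: flag_only
    rule: all_of
    flag: PFOR_fermentation
    genes:
      porA: [K00169, K00170, K00171, K00172, K03737]
      acdA: [COG1042]
# Taxon-specific substrate resolution for the amoABC/pmoABC complex: the same
# subunits can oxidise ammonia or methane depending on lineage.
amo_substrate_overrides:
  Thaumarchaeota: ammonia_oxidation
  Desulfobacterota: methane_oxidation
amo_substrate_default: ammonia_oxidation
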