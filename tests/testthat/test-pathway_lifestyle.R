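rules <- read_pathway_rules()

test_that("pathway scoring follows the presence rule exactly", {
  cbb <- rules$pathways$CBB
  # rbcL + phosphoribulokinase satisfy the all_of CBB rule
  idx <- index_from_accessions("magA", c("K01601", "K00855"))
  sc <- score_pathway(idx, cbb)
  expect_true(sc$present)
  expect_equal(sc$completeness, 1.0)
  expect_setequal(sc$matched_genes[[1]], c("rbcL", "prkB"))

  # empty MAG: absent, completeness 0 (MAG exists only through metadata)
  mags <- mags_fixture("magEmpty", "Bacteroidota")
  idx0 <- merge_annotations(ko = ann_row("g1", "magEmpty", ko_id = "K99999"),
                            mags = mags)
  sc0 <- score_pathway(idx0, cbb)
  expect_false(sc0$present)
  expect_equal(sc0$completeness, 0)

  # 2 of 3 genes under all_of: absent with completeness 2/3
  def3 <- list(name = "toy", class = "energy", rule = "all_of",
               k = NA_integer_, flag = "toy",
               genes = list(a = "K1", b = "K2", c = "K3"))
  idx2 <- index_from_accessions("magA", c("K1", "K2"))
  sc2 <- score_pathway(idx2, def3)
  expect_false(sc2$present)
  expect_equal(sc2$completeness, 2 / 3)
})

test_that("Mo-CODH genomic criterion requires all four cox subunits", {
  full <- index_from_accessions("magA",
                                c("K03518", "K03519", "K03520", "K03521"))
  expect_true(detect_mo_codh(full, rules)$present)

  # coxS+coxM+coxL without coxG fails the strict genomic criterion
  partial <- index_from_accessions("magA", c("K03518", "K03519", "K03520"))
  got <- detect_mo_codh(partial, rules)
  expect_false(got$present)
  expect_setequal(got$subunits[[1]], c("coxS", "coxM", "coxL"))

  none <- index_from_accessions("magA", "K99999")
  expect_false(detect_mo_codh(none, rules)$present)
})

test_that("nickel-CODH screen flags only passing evidence", {
  clean <- index_from_accessions("magA", c("K03520", "K99999"))
  expect_identical(nrow(check_wl_absence(clean, rules)), 0L)

  planted <- index_from_accessions("magB", "K00198")
  expect_identical(check_wl_absence(planted, rules)$mag_id, "magB")

  # a Ni-CODH HMM hit below its score threshold never reaches the index
  thr <- structure(c(NiCODH = 200), class = "hmm_thresholds")
  tab <- ann_row("g1", "magC", hmm_model = "NiCODH", hmm_score = 150)
  got <- read_annotation_table(write_tsv_tmp(tab), thresholds = thr)
  idx <- merge_annotations(hmm = got,
                           mags = mags_fixture("magC", "Chloroflexi"))
  expect_identical(nrow(check_wl_absence(idx, rules)), 0L)
})

test_that("lifestyle precedence is fixation > inorganic energy > default", {
  # CBB + Mo-CODH: autotroph_CBB, CO_oxidation kept as a flag
  both <- index_from_accessions(
    "magA", c("K01601", "K00855", "K03518", "K03519", "K03520", "K03521"))
  call <- classify_lifestyle(score_pathways(both, rules))
  expect_identical(as.character(call$lifestyle), "autotroph_CBB")
  expect_true("CO_oxidation" %in% call$flags[[1]])

  # Mo-CODH alone: lithoheterotroph
  codh <- index_from_accessions(
    "magA", c("K03518", "K03519", "K03520", "K03521"))
  expect_identical(
    as.character(classify_lifestyle(score_pathways(codh, rules))$lifestyle),
    "lithoheterotroph")

  # nothing present: organoheterotroph
  bare <- index_from_accessions("magA", "K99999")
  expect_identical(
    as.character(classify_lifestyle(score_pathways(bare, rules))$lifestyle),
    "organoheterotroph")

  # non-CBB fixation: other chemoautotroph
  rtca <- index_from_accessions("magA", c("K15230", "K00169"))
  expect_identical(
    as.character(classify_lifestyle(score_pathways(rtca, rules))$lifestyle),
    "chemoautotroph_other")
})

test_that("PFOR alone neither implies rTCA nor sets the fermentation flag", {
  pfor_only <- index_from_accessions("magA", "K00169")
  call <- classify_lifestyle(score_pathways(pfor_only, rules))
  expect_identical(as.character(call$lifestyle), "organoheterotroph")
  expect_false("PFOR_fermentation" %in% call$flags[[1]])

  # with acetyl-CoA synthetase the fermentation flag is set, label unchanged
  with_acd <- merge_annotations(
    ko = ann_row("g1", "magA", ko_id = "K00169"),
    cog = ann_row("g2", "magA", cog_id = "COG1042"))
  call2 <- classify_lifestyle(score_pathways(with_acd, rules))
  expect_identical(as.character(call2$lifestyle), "organoheterotroph")
  expect_true("PFOR_fermentation" %in% call2$flags[[1]])
})

test_that("amo/pmo substrate flag resolves by phylum override", {
  amo <- c("K10944", "K10945", "K10946")
  for (case in list(c("Thaumarchaeota", "ammonia_oxidation"),
                    c("Desulfobacterota", "methane_oxidation"),
                    c("Chloroflexi", "ammonia_oxidation"))) {
    mags <- mags_fixture("magA", case[1])
    idx <- index_from_accessions("magA", amo, mags = mags)
    call <- classify_lifestyle(score_pathways(idx, rules), mags)
    expect_true(case[2] %in% call$flags[[1]])
  }
})

test_that("the classifier is a pure function of the scores", {
  sim <- gen_mag_annotations(sim_config(seed = 11, n_mags = 20))
  idx <- merge_annotations(sim$ko, sim$cog, sim$hmm, mags = sim$mags)
  sc <- score_pathways(idx, rules)
  base <- classify_lifestyle(sc, sim$mags)
  for (perm_seed in 1:3) {
    set.seed(perm_seed)
    shuffled <- sc[sample(nrow(sc)), ]
    attr(shuffled, "rules") <- attr(sc, "rules")
    class(shuffled) <- class(sc)
    expect_identical(classify_lifestyle(shuffled, sim$mags), base)
  }
})

test_that("lifestyle matrix percentages and counts are consistent", {
  mags <- mags_fixture(sprintf("m%d", 1:4), "Chloroflexi")
  calls <- structure(data.frame(
    mag_id = sprintf("m%d", 1:4),
    lifestyle = factor(c("lithoheterotroph", "lithoheterotroph",
                         "autotroph_CBB", "organoheterotroph"),
                       levels = levels(classify_lifestyle(
                         score_pathways(index_from_accessions("x", "K1"),
                                        rules))$lifestyle))),
    class = c("lifestyle_calls", "data.frame"))
  lm <- lifestyle_matrix(calls, mags)
  expect_equal(unname(lm$percent["Chloroflexi",
                                 c("lithoheterotroph", "autotroph_CBB",
                                   "organoheterotroph")]),
               c(50, 25, 25))
  expect_equal(sum(lm$count), 4)

  single <- lifestyle_matrix(calls[3, ], mags_fixture("m3", "Cyanobacteria"))
  expect_equal(unname(single$percent[1, "autotroph_CBB"]), 100)

  empty <- lifestyle_matrix(calls[0, ], mags)
  expect_identical(nrow(empty$count), 0L)

  expect_error(lifestyle_matrix(calls, mags, rank = "kingdom"))
})
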