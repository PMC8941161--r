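# Synthetic-data generators with planted ground truth for every input
# family: MAG annotation tables, CoxL protein families, transcript hit
# tables and radiotracer measurements. All generators are pure functions of
# (config, seed); one global seed is split deterministically per generator
# so any single fixture is reproducible in isolation.

.sub_seed <- function(seed, k) {
  (as.integer(seed) + k * 1000003L) %% .Machine$integer.max
}

#' Simulation configuration
#'
#' Bundles and validates the parameters of all synthetic generators. The
#' defaults mirror the scales of the study system the package targets: a
#' collection of a few dozen MAGs of mixed trophic lifestyles with
#' incompleteness emulated as i.i.d. gene dropout, 39 transcriptome samples,
#' CoxL-like families with lengths around 682 +/- 207 aa (truncated to
#' [35, 1250]), and 2-h radiotracer incubations with three 2-mm sections,
#' light/dark conditions and formalin kill controls.
#'
#' @param seed Integer master seed; all generators derive their streams
#'   from it.
#' @param n_mags Number of MAGs to simulate.
#' @param lifestyle_proportions Named fractions over the four lifestyles;
#'   must sum to 1.
#' @param gene_dropout Probability in [0, 1] that each planted pathway gene
#'   is lost (emulating MAG incompleteness).
#' @param n_samples Number of metatranscriptome samples.
#' @param prevalence Named vector of planted expression prevalence per
#'   (function) row.
#' @param coxl List: `n_families`, `family_size`, `within_identity`,
#'   `between_identity` (percent; within must exceed between),
#'   `annotated_fraction`, `length_mean`, `length_sd`.
#' @param tracer List: per-section planted fixation (`planted_light`,
#'   `planted_dark`, ug C per g), `noise_frac` (counting-noise SD as a
#'   fraction of the expected DPM), `kill_background` (DPM),
#'   `tdpm`, `total_ci` (ug), `sampled_fraction`, `wet_weight` (g),
#'   `n_live`, `incubation` (h), `discrimination`.
#' @return Validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_mags = 50L,
                       lifestyle_proportions = c(organoheterotroph = 0.40,
                                                 lithoheterotroph = 0.35,
                                                 autotroph_CBB = 0.15,
                                                 chemoautotroph_other = 0.10),
                       gene_dropout = 0,
                       n_samples = 39L,
                       prevalence = c(pckA = 0.95, coxL = 0.9,
                                      rbcL = 0.75, mez = 0.5),
                       coxl = list(),
                       tracer = list()) {
  if (abs(sum(lifestyle_proportions) - 1) > 1e-8) {
    stop("lifestyle_proportions must sum to 1")
  }
  if (!all(names(lifestyle_proportions) %in% .lifestyles)) {
    stop("unknown lifestyle in proportions: ",
         paste(setdiff(names(lifestyle_proportions), .lifestyles),
               collapse = ", "))
  }
  if (gene_dropout < 0 || gene_dropout > 1) stop("gene_dropout not in [0,1]")
  if (any(prevalence < 0 | prevalence > 1)) stop("prevalence not in [0,1]")
  coxl_defaults <- list(n_families = 5L, family_size = 8L,
                        within_identity = 85, between_identity = 30,
                        annotated_fraction = 0.8,
                        length_mean = 682, length_sd = 207)
  coxl <- utils::modifyList(coxl_defaults, coxl)
  if (coxl$within_identity <= coxl$between_identity) {
    stop("coxl within_identity must exceed between_identity")
  }
  tracer_defaults <- list(planted_light = c(100, 20, 5),
                          planted_dark = c(3, 2, 1),
                          noise_frac = 0.05, kill_background = 100,
                          tdpm = 1e6, total_ci = 25000,
                          sampled_fraction = 0.2, wet_weight = 0.5,
                          n_live = 3L, incubation = 2, discrimination = 1.05)
  tracer <- utils::modifyList(tracer_defaults, tracer)
  structure(list(seed = as.integer(seed), n_mags = as.integer(n_mags),
                 lifestyle_proportions = lifestyle_proportions,
                 gene_dropout = gene_dropout,
                 n_samples = as.integer(n_samples),
                 prevalence = prevalence, coxl = coxl, tracer = tracer),
            class = "sim_config")
}

# phylum pools per planted lifestyle (flavour only; classification never
# reads taxonomy except for the amo/pmo substrate override)
.sim_phyla <- list(
  organoheterotroph = c("Bacteroidota", "Poribacteria", "Verrucomicrobia"),
  lithoheterotroph = c("Actinobacteria", "Chloroflexi", "Proteobacteota"),
  autotroph_CBB = "Cyanobacteria",
  chemoautotroph_other = c("Nitrospirota", "Thaumarchaeota", "Tectomicrobia"))

# accessions planted per lifestyle, drawn from the active rule set
.sim_complement <- function(lifestyle, rules, energy_pathway) {
  defs <- rules$pathways
  grab <- function(nm) vapply(defs[[nm]]$genes, `[[`, character(1), 1L)
  switch(lifestyle,
         organoheterotroph = character(0),
         lithoheterotroph = grab(energy_pathway),
         autotroph_CBB = c(grab("CBB"), grab(energy_pathway)),
         chemoautotroph_other = c(grab(sample(c("rTCA", "HP4HB"), 1L)),
                                  grab(energy_pathway)))
}

#' Generate MAG annotation tables with planted lifestyles
#'
#' Each simulated MAG receives the full marker-gene complement of its
#' planted lifestyle (accessions taken from the active rule set: fixation
#' markers for autotrophs, one inorganic-energy pathway for litho- and
#' autotrophs), every planted gene is then dropped i.i.d. with probability
#' `gene_dropout`, and background KO ids disjoint from every rule accession
#' are added. With zero dropout, [classify_lifestyle()] recovers the planted
#' labels exactly; with dropout, misclassification can only lose evidence.
#'
#' @param config A [sim_config()].
#' @param rules Pathway rule set the complements are drawn from.
#' @return List with `ko`, `cog`, `hmm` annotation data.frames, `mags`
#'   metadata and `truth` (`mag_id`, `lifestyle`, `energy_pathway`).
#' @export
gen_mag_annotations <- function(config, rules = read_pathway_rules()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.sub_seed(config$seed, 1L))
  n <- config$n_mags
  props <- config$lifestyle_proportions
  planted <- sample(names(props), n, replace = TRUE, prob = props)
  mag_id <- sprintf("mag%03d", seq_len(n))

  energy_pool <- names(Filter(function(d) d$class == "energy",
                              rules$pathways))
  # Mo-CODH is the dominant lithoheterotrophic energy source in this system
  energy_w <- ifelse(energy_pool == "Mo_CODH", 4, 1)
  energy <- sample(energy_pool, n, replace = TRUE, prob = energy_w)
  energy[planted == "organoheterotroph"] <- NA

  rule_acc <- unique(unlist(lapply(rules$pathways, function(d) d$genes)))
  background_pool <- setdiff(sprintf("K9%04d", 1:400), rule_acc)

  rows <- list()
  for (i in seq_len(n)) {
    planted_acc <- if (is.na(energy[i])) character(0) else
      .sim_complement(planted[i], rules, energy[i])
    keep <- stats::runif(length(planted_acc)) >= config$gene_dropout
    planted_acc <- planted_acc[keep]
    bg <- sample(background_pool, sample(5:15, 1L))
    acc <- c(planted_acc, bg)
    if (!length(acc)) next
    rows[[i]] <- data.frame(
      gene_id = sprintf("%s_g%03d", mag_id[i], seq_along(acc)),
      mag_id = mag_id[i], accession = acc, stringsAsFactors = FALSE)
  }
  ann <- do.call(rbind, rows)
  is_ko <- grepl("^K\\d", ann$accession)
  is_cog <- grepl("^COG", ann$accession)
  mk <- function(rws, col) {
    m <- nrow(rws)
    out <- data.frame(gene_id = rws$gene_id, mag_id = rws$mag_id,
                      ko_id = rep(NA_character_, m),
                      cog_id = rep(NA_character_, m),
                      hmm_model = rep(NA_character_, m),
                      hmm_score = rep(NA_real_, m),
                      stringsAsFactors = FALSE)
    out[[col]] <- rws$accession
    out
  }
  ko <- mk(ann[is_ko, ], "ko_id")
  cog <- mk(ann[is_cog, ], "cog_id")
  hmm <- mk(ann[!is_ko & !is_cog, ], "hmm_model")
  hmm$hmm_score <- if (nrow(hmm)) 1000 else numeric(0)

  phylum <- vapply(planted, function(l) sample(.sim_phyla[[l]], 1L),
                   character(1))
  completeness <- pmin(100, pmax(62,
    100 * (1 - config$gene_dropout) + stats::rnorm(n, 0, 2)))
  mags <- as_mag_metadata(data.frame(
    mag_id = mag_id,
    taxonomy = paste("Bacteria", phylum, sep = ";"),
    completeness = round(completeness, 1),
    contamination = round(stats::runif(n, 0, 5.5), 1),
    host = "P_ficiformis_sim", source_study = "synthetic",
    stringsAsFactors = FALSE))
  truth <- data.frame(mag_id = mag_id, lifestyle = planted,
                      energy_pathway = energy, stringsAsFactors = FALSE)
  list(ko = ko, cog = cog, hmm = hmm, mags = mags, truth = truth)
}

# truncated normal by rejection; bounds are the observed length range
.rtnorm <- function(n, mean, sd, lower, upper) {
  out <- numeric(0)
  while (length(out) < n) {
    draw <- stats::rnorm(n, mean, sd)
    out <- c(out, draw[draw >= lower & draw <= upper])
  }
  out[seq_len(n)]
}

#' Generate CoxL-like protein families with planted cluster structure
#'
#' Families are planted with within-family identity far above, and
#' between-family identity far below, the clustering threshold, so
#' [cluster_proteins()] must recover the planted partition exactly. Each
#' family carries a planted majority substrate KO (one family is left
#' entirely unassigned, as observed for the largest real COG1529 group);
#' members are annotated with it with probability `annotated_fraction`.
#' Protein lengths are drawn from a truncated normal (defaults 682 +/- 207,
#' bounds 35 and 1250 amino acids).
#'
#' @param config A [sim_config()].
#' @return List with `proteins`, `identities` (all within-family pairs plus
#'   between-family pairs), `mags` metadata and `truth` (protein -> planted
#'   family).
#' @export
gen_coxl_families <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.sub_seed(config$seed, 2L))
  cx <- config$coxl
  nf <- cx$n_families
  sizes <- rep(cx$family_size, nf)
  fam <- rep(seq_len(nf), sizes)
  n <- length(fam)
  protein_id <- sprintf("cox%04d", seq_len(n))

  fam_ko <- sample(.coxl_ko_vocab, nf, replace = nf > length(.coxl_ko_vocab))
  fam_ko[1L] <- NA  # an entirely unassigned family
  annotated <- stats::runif(n) < cx$annotated_fraction
  ko <- ifelse(annotated, fam_ko[fam], NA)

  fam_phylum <- sample(c("Actinobacteria", "Chloroflexi", "Proteobacteota",
                         "Gemmatimonadetes", "Tectomicrobia"),
                       nf, replace = nf > 5L)
  mag_of_fam <- sprintf("coxmag%02d", fam)
  proteins <- data.frame(
    protein_id = protein_id, mag_id = mag_of_fam,
    length = round(.rtnorm(n, cx$length_mean, cx$length_sd, 35, 1250)),
    ko_id = ko, stringsAsFactors = FALSE)

  within <- do.call(rbind, lapply(seq_len(nf), function(f) {
    ids <- protein_id[fam == f]
    if (length(ids) < 2L) return(NULL)
    pr <- t(utils::combn(ids, 2L))
    data.frame(id1 = pr[, 1L], id2 = pr[, 2L],
               percent = pmin(100, cx$within_identity +
                                stats::runif(nrow(pr), -3, 3)),
               stringsAsFactors = FALSE)
  }))
  # a sample of between-family pairs, all safely below threshold
  between <- do.call(rbind, lapply(seq_len(nf - 1L), function(f) {
    a <- sample(protein_id[fam == f], min(3L, sizes[f]))
    b <- sample(protein_id[fam > f], min(3L, sum(sizes) - sum(sizes[1:f])))
    pr <- expand.grid(id1 = a, id2 = b, stringsAsFactors = FALSE)
    pr$percent <- pmax(0, cx$between_identity + stats::runif(nrow(pr), -5, 5))
    pr
  }))
  identities <- rbind(within, between)
  rownames(identities) <- NULL

  fam_mags <- unique(data.frame(mag_id = mag_of_fam,
                                phylum = fam_phylum[fam],
                                stringsAsFactors = FALSE))
  mags <- as_mag_metadata(data.frame(
    mag_id = fam_mags$mag_id,
    taxonomy = paste("Bacteria", fam_mags$phylum, sep = ";"),
    completeness = 90, contamination = 1,
    host = "synthetic", source_study = "synthetic",
    stringsAsFactors = FALSE))
  truth <- data.frame(protein_id = protein_id, family = fam,
                      planted_ko = fam_ko[fam], stringsAsFactors = FALSE)
  list(proteins = proteins, identities = identities, mags = mags,
       truth = truth)
}

#' Generate transcript hit tables with planted expression prevalence
#'
#' For each planted (function, MAG) row and sample, a hit passing the
#' E-value and identity thresholds is emitted with probability equal to the
#' planted prevalence; decoy hits failing one threshold or the other are
#' added in every sample. Read support is emitted for every passing hit
#' (counts >= 5) so read confirmation keeps planted signals.
#'
#' @param config A [sim_config()]; `config$prevalence` names the planted
#'   functions.
#' @param mag_id MAG the planted functions are affiliated to.
#' @return List with `hits`, `read_support`, `samples` and `truth`
#'   (function, planted prevalence).
#' @export
gen_transcript_hits <- function(config, mag_id = "Acido_2") {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.sub_seed(config$seed, 3L))
  samples <- sprintf("s%03d", seq_len(config$n_samples))
  prev <- config$prevalence

  rows <- list()
  support <- list()
  k <- 0L
  for (fn in names(prev)) {
    expressed <- stats::runif(length(samples)) < prev[[fn]]
    for (j in which(expressed)) {
      k <- k + 1L
      rows[[k]] <- data.frame(
        transcript_id = sprintf("t_%s_%s", fn, samples[j]),
        sample_id = samples[j],
        protein_id = sprintf("%s_%s", mag_id, fn), mag_id = mag_id,
        bit_score = round(stats::runif(1, 150, 600), 1),
        e_value = 10^stats::runif(1, -60, -15),
        identity = round(stats::runif(1, 60, 95), 1),
        function_id = fn, stringsAsFactors = FALSE)
      support[[k]] <- data.frame(
        function_id = fn, mag_id = mag_id, sample_id = samples[j],
        count = 5L + stats::rpois(1, 20), stringsAsFactors = FALSE)
    }
  }
  hits <- do.call(rbind, rows)
  # decoys: fail E-value in odd samples, identity in even samples
  decoys <- do.call(rbind, lapply(seq_along(samples), function(j) {
    data.frame(transcript_id = sprintf("decoy_%s", samples[j]),
               sample_id = samples[j],
               protein_id = "off_target", mag_id = "magX",
               bit_score = 80,
               e_value = if (j %% 2L == 1L) 1e-9 else 1e-30,
               identity = if (j %% 2L == 1L) 80 else 50,
               function_id = "decoy", stringsAsFactors = FALSE)
  }))
  hits <- rbind(hits, decoys)
  hits <- hits[order(hits$sample_id, hits$transcript_id, method = "radix"), ]
  rownames(hits) <- NULL
  list(hits = hits,
       read_support = do.call(rbind, support),
       samples = samples,
       truth = data.frame(function_id = names(prev), mag_id = mag_id,
                          prevalence = unname(prev),
                          stringsAsFactors = FALSE))
}

#' Generate radiotracer measurement tables with planted fixation
#'
#' Inverts the fixed-carbon equation: live-cylinder DPM is the kill
#' background plus the planted per-section fixed carbon back-converted
#' through the specific activity, total inorganic carbon, counted fraction,
#' wet weight and discrimination factor, plus Gaussian counting noise
#' proportional to the expected count. Kill rows sit at the background.
#' With `noise_frac = 0`, [compute_fixed_carbon()] returns the planted
#' values exactly.
#'
#' @param config A [sim_config()]; see `tracer` element.
#' @param experiment_id Experiment label.
#' @return List with `measurements`, `medium` and `truth` (condition,
#'   section, planted fixed carbon in ug C per g).
#' @export
gen_tracer <- function(config, experiment_id = "exp1") {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.sub_seed(config$seed, 4L))
  tr <- config$tracer
  planted <- rbind(
    data.frame(condition = "light",
               section_index = seq_along(tr$planted_light),
               fixed_c = tr$planted_light, stringsAsFactors = FALSE),
    data.frame(condition = "dark",
               section_index = seq_along(tr$planted_dark),
               fixed_c = tr$planted_dark, stringsAsFactors = FALSE))

  dpm_for <- function(fixed_c) {
    tr$kill_background +
      fixed_c * tr$wet_weight * tr$sampled_fraction * tr$tdpm /
        (tr$total_ci * tr$discrimination)
  }
  noisy <- function(mu) {
    if (tr$noise_frac == 0) return(mu)
    pmax(0, mu + stats::rnorm(length(mu), 0, tr$noise_frac * mu))
  }
  rows <- list()
  k <- 0L
  for (i in seq_len(nrow(planted))) {
    mu <- dpm_for(planted$fixed_c[i])
    for (r in seq_len(tr$n_live)) {
      k <- k + 1L
      rows[[k]] <- data.frame(
        experiment_id = experiment_id,
        cylinder_id = sprintf("%s_%s_c%d", experiment_id,
                              planted$condition[i], r),
        section_index = planted$section_index[i],
        condition = planted$condition[i], phenotype = "pink",
        status = "live", wet_weight = tr$wet_weight,
        dpm = noisy(mu), incubation = tr$incubation,
        stringsAsFactors = FALSE)
    }
    k <- k + 1L
    rows[[k]] <- data.frame(
      experiment_id = experiment_id,
      cylinder_id = sprintf("%s_%s_kill", experiment_id,
                            planted$condition[i]),
      section_index = planted$section_index[i],
      condition = planted$condition[i], phenotype = "pink",
      status = "kill", wet_weight = tr$wet_weight,
      dpm = noisy(tr$kill_background), incubation = tr$incubation,
      stringsAsFactors = FALSE)
  }
  measurements <- do.call(rbind, rows)
  rownames(measurements) <- NULL
  medium <- data.frame(experiment_id = experiment_id, tdpm = tr$tdpm,
                       total_ci = tr$total_ci,
                       sampled_fraction = tr$sampled_fraction,
                       stringsAsFactors = FALSE)
  list(measurements = measurements, medium = medium, truth = planted)
}
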