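#' Read a pathway rule set
#'
#' Loads the YAML rule file describing which gene markers (as KO/COG/HMM
#' accessions) constitute each carbon-fixation or inorganic-energy pathway,
#' the presence rule (`all_of`, `any_of`, `k_of_n`), the pathway class
#' (`fixation`, `energy`, `flag_only`) and the capability flag it sets.
#' The package ships a provisional default rule set
#' (`system.file("extdata", "pathways.yaml", package = "spongetroph")`).
#'
#' @param path Path to a rule YAML; defaults to the shipped rule set.
#' @return An object of class `pathway_rules`: a list with `pathways` (named
#'   list of definitions) and the amoABC/pmoABC substrate override table.
#' @export
read_pathway_rules <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "pathways.yaml", package = "spongetroph")
  }
  raw <- yaml::read_yaml(path)
  if (is.null(raw$pathways) || !length(raw$pathways)) {
    stop("rule file defines no pathways: ", path)
  }
  defs <- lapply(names(raw$pathways), function(nm) {
    d <- raw$pathways[[nm]]
    genes <- lapply(d$genes, as.character)
    if (!length(genes) || any(!lengths(genes))) {
      stop("pathway ", nm, " has a gene with no accessions")
    }
    rule <- match.arg(d$rule, c("all_of", "any_of", "k_of_n"))
    k <- if (rule == "k_of_n") {
      if (is.null(d$k)) stop("pathway ", nm, ": k_of_n rule requires k")
      k <- as.integer(d$k)
      if (k > length(genes)) stop("pathway ", nm, ": k exceeds gene count")
      k
    } else NA_integer_
    list(name = nm,
         class = match.arg(d$class, c("fixation", "energy", "flag_only")),
         rule = rule, k = k,
         flag = if (is.null(d$flag)) NA_character_ else d$flag,
         genes = genes)
  })
  names(defs) <- names(raw$pathways)
  structure(list(pathways = defs,
                 amo_overrides = raw$amo_substrate_overrides,
                 amo_default = raw$amo_substrate_default %||%
                   "ammonia_oxidation"),
            class = "pathway_rules")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.pathway_rules <- function(x, ...) {
  cat("<pathway_rules> ", length(x$pathways), " pathways:\n", sep = "")
  for (d in x$pathways) {
    cat(sprintf("  %-18s %-9s %-6s genes: %s\n", d$name, d$class, d$rule,
                paste(names(d$genes), collapse = ", ")))
  }
  invisible(x)
}

#' Score one pathway across MAGs
#'
#' For each MAG, a gene symbol of the definition is matched when any of its
#' accessions appears in the MAG's merged evidence ([mag_accessions()]).
#' `completeness` is the matched fraction of the definition's gene symbols;
#' `present` applies the definition's rule (`all_of`: every symbol,
#' `any_of`: at least one, `k_of_n`: at least `k`).
#'
#' @param index A `mag_index` from [merge_annotations()].
#' @param definition One pathway definition (an element of
#'   `read_pathway_rules()$pathways`).
#' @param mag_ids MAGs to score; defaults to all MAGs in the index.
#' @return data.frame with columns `mag_id`, `pathway`, `present`,
#'   `completeness` and list column `matched_genes`.
#' @export
score_pathway <- function(index, definition, mag_ids = index$mags) {
  stopifnot(inherits(index, "mag_index"))
  genes <- definition$genes
  if (!length(genes)) stop("pathway definition has no genes")
  res <- lapply(mag_ids, function(m) {
    acc <- mag_accessions(index, m)
    matched <- names(genes)[vapply(genes, function(a) any(a %in% acc),
                                   logical(1))]
    frac <- length(matched) / length(genes)
    present <- switch(definition$rule,
                      all_of = length(matched) == length(genes),
                      any_of = length(matched) >= 1L,
                      k_of_n = length(matched) >= definition$k)
    list(matched = matched, frac = frac, present = present)
  })
  out <- data.frame(mag_id = mag_ids, pathway = definition$name,
                    present = vapply(res, `[[`, logical(1), "present"),
                    completeness = vapply(res, `[[`, numeric(1), "frac"),
                    stringsAsFactors = FALSE)
  out$matched_genes <- lapply(res, `[[`, "matched")
  out
}

#' Score every pathway of a rule set
#'
#' @param index A `mag_index`.
#' @param rules A `pathway_rules` object (defaults to the shipped rules).
#' @return Long data.frame of per-MAG [score_pathway()] results, class
#'   `pathway_scores`.
#' @export
score_pathways <- function(index, rules = read_pathway_rules()) {
  out <- do.call(rbind, lapply(rules$pathways,
                               function(d) score_pathway(index, d)))
  rownames(out) <- NULL
  attr(out, "rules") <- rules
  class(out) <- c("pathway_scores", "data.frame")
  out
}

#' Detect the aerobic Mo-CODH complex
#'
#' Genomic potential for CO oxidation requires all four structural subunits
#' coxS, coxM, coxL and coxG. This strict four-subunit criterion applies to
#' genomes only; expression analyses tolerate a silent coxG, since bona fide
#' CO dehydrogenases lacking coxG are known.
#'
#' @param index A `mag_index`.
#' @param rules A `pathway_rules` containing a `Mo_CODH` pathway.
#' @return data.frame `mag_id`, `present`, list column `subunits` of matched
#'   subunit symbols.
#' @export
detect_mo_codh <- function(index, rules = read_pathway_rules()) {
  def <- rules$pathways[["Mo_CODH"]]
  if (is.null(def)) stop("rule set has no Mo_CODH pathway")
  sc <- score_pathway(index, def)
  data.frame(mag_id = sc$mag_id, present = sc$present,
             subunits = I(sc$matched_genes), stringsAsFactors = FALSE)
}

#' Screen for nickel-CODH / Wood-Ljungdahl markers
#'
#' Flags MAGs where anaerobic Ni-CODH markers pass the combined KO+COG+HMM
#' evidence. In sponge symbionts the expected report is empty: the
#' Wood-Ljungdahl pathway is absent from the sponge microbiome.
#'
#' @param index A `mag_index`.
#' @param rules Rule set with a `WL_NiCODH` pathway whose first gene entry
#'   is the Ni-CODH catalytic subunit.
#' @return data.frame of flagged MAGs (zero rows when no marker passes).
#' @export
check_wl_absence <- function(index, rules = read_pathway_rules()) {
  def <- rules$pathways[["WL_NiCODH"]]
  if (is.null(def)) stop("rule set has no WL_NiCODH pathway")
  ni_acc <- def$genes[["cooS"]] %||% def$genes[[1L]]
  flagged <- vapply(index$mags, function(m) {
    any(ni_acc %in% mag_accessions(index, m))
  }, logical(1))
  out <- data.frame(mag_id = index$mags[flagged],
                    marker = rep("Ni-CODH", sum(flagged)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

.lifestyles <- c("organoheterotroph", "lithoheterotroph",
                 "autotroph_CBB", "chemoautotroph_other")

#' Classify the trophic lifestyle of each MAG
#'
#' Pure function of the pathway scores, with fixed precedence: a complete
#' carbon-fixation pathway makes the MAG an autotroph (`autotroph_CBB` when
#' CBB is among them, otherwise `chemoautotroph_other`); otherwise any
#' complete inorganic-energy pathway makes it a `lithoheterotroph`; otherwise
#' it is an `organoheterotroph`. Capability flags are set independently of
#' the lifestyle from every present flagged pathway. MAG completeness never
#' alters a call; genomic potential is reported as observed.
#'
#' The amoABC/pmoABC complex is ambiguous between ammonia and methane
#' oxidation; when `mags` metadata is supplied the flag is resolved by the
#' rule set's phylum override table, otherwise the configured default
#' applies.
#'
#' @param scores A `pathway_scores` data.frame from [score_pathways()].
#' @param mags Optional `mag_metadata` used for amo/pmo substrate overrides.
#' @return data.frame (class `lifestyle_calls`) with `mag_id`, `lifestyle`
#'   (factor over the four classes) and list column `flags`.
#' @export
classify_lifestyle <- function(scores, mags = NULL) {
  rules <- attr(scores, "rules")
  if (is.null(rules)) stop("scores must come from score_pathways()")
  defs <- rules$pathways
  cls <- vapply(defs, `[[`, character(1), "class")
  flg <- vapply(defs, `[[`, character(1), "flag")

  split_scores <- split(seq_len(nrow(scores)), scores$mag_id)
  mag_ids <- names(split_scores)
  call_one <- function(rows) {
    present <- scores$pathway[rows][scores$present[rows]]
    fix <- present[cls[present] == "fixation"]
    energy <- present[cls[present] == "energy"]
    lifestyle <- if (length(fix)) {
      if ("CBB" %in% fix) "autotroph_CBB" else "chemoautotroph_other"
    } else if (length(energy)) "lithoheterotroph" else "organoheterotroph"
    flags <- flg[present]
    flags <- unname(flags[!is.na(flags)])
    list(lifestyle = lifestyle, flags = flags)
  }
  calls <- lapply(split_scores, call_one)
  flags <- lapply(calls, `[[`, "flags")

  if (!is.null(mags) && "AmoPmo" %in% names(defs)) {
    amo_flag <- flg[["AmoPmo"]]
    phyla <- taxonomy_rank(mags, mag_ids, "phylum")
    flags <- mapply(function(f, ph) {
      if (!amo_flag %in% f) return(f)
      substrate <- if (is.na(ph)) NULL else rules$amo_overrides[[ph]]
      substrate <- substrate %||% rules$amo_default
      unique(sub("^ammonia_oxidation$", substrate, f))
    }, flags, phyla, SIMPLIFY = FALSE)
  }

  out <- data.frame(
    mag_id = mag_ids,
    lifestyle = factor(vapply(calls, `[[`, character(1), "lifestyle"),
                       levels = .lifestyles),
    stringsAsFactors = FALSE)
  out$flags <- unname(flags)
  out <- out[order(out$mag_id, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("lifestyle_calls", "data.frame")
  out
}

#' Summarise lifestyles per taxon
#'
#' Builds the taxon-by-lifestyle summary: for every taxon at the requested
#' rank, the percentage of its MAGs in each trophic class (rows sum to 100)
#' and the underlying MAG counts.
#'
#' @param calls `lifestyle_calls` from [classify_lifestyle()].
#' @param mags `mag_metadata` covering every called MAG.
#' @param rank Taxonomic rank to aggregate at (default `"phylum"`).
#' @return List of class `lifestyle_matrix` with numeric matrices `percent`
#'   and `count` (taxon rows, lifestyle columns) and `n_mags` per taxon.
#' @export
lifestyle_matrix <- function(calls, mags, rank = "phylum") {
  rank <- match.arg(rank, .tax_ranks)
  if (nrow(calls) == 0L) {
    empty <- matrix(numeric(0), nrow = 0, ncol = length(.lifestyles),
                    dimnames = list(NULL, .lifestyles))
    return(structure(list(percent = empty, count = empty,
                          n_mags = integer(0), rank = rank),
                     class = "lifestyle_matrix"))
  }
  taxon <- taxonomy_rank(mags, calls$mag_id, rank)
  taxon[is.na(taxon)] <- "unclassified"
  count <- table(taxon, calls$lifestyle)
  count <- matrix(as.integer(count), nrow = nrow(count),
                  dimnames = dimnames(count))
  n <- rowSums(count)
  percent <- sweep(count, 1, n, "/") * 100
  structure(list(percent = percent, count = count, n_mags = n, rank = rank),
            class = "lifestyle_matrix")
}

#' @export
print.lifestyle_matrix <- function(x, digits = 1, ...) {
  cat("<lifestyle_matrix> rank = ", x$rank, ", ", nrow(x$count),
      " taxa, ", sum(x$n_mags), " MAGs\n", sep = "")
  if (nrow(x$count)) {
    shown <- matrix(sprintf("%.*f%% (%d)", digits, x$percent, x$count),
                    nrow = nrow(x$count), dimnames = dimnames(x$count))
    print(as.data.frame(shown), ...)
  }
  invisible(x)
}
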