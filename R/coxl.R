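# COG1529 (CoxL-like) partitioning: single-linkage identity clustering,
# majority substrate labelling, taxon summaries.

# substrate KO vocabulary for CoxL-like proteins (CO, xanthine, nicotinate,
# isoquinoline, aldehyde, 2-furoyl-CoA, selenate reductase relatives)
.coxl_ko_vocab <- c("K03520", "K07303", "K11177", "K18030", "K16877",
                    "K07469", "K12528", "K11178", "K03518", "K09386")

#' Validate a CoxL-like protein table
#'
#' @param proteins data.frame with `protein_id`, `mag_id`, `length`
#'   (amino acids) and optional `ko_id` (`NA` = unassigned).
#' @param ko_vocab Accepted substrate KO accessions.
#' @return The validated data.frame.
#' @export
as_coxl_proteins <- function(proteins, ko_vocab = .coxl_ko_vocab) {
  need <- c("protein_id", "mag_id", "length")
  missing_cols <- setdiff(need, names(proteins))
  if (length(missing_cols)) {
    stop("protein table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (!"ko_id" %in% names(proteins)) proteins$ko_id <- NA_character_
  if (anyDuplicated(proteins$protein_id)) stop("duplicate protein_id")
  if (any(proteins$length <= 0)) stop("protein length must be positive")
  bad_ko <- !is.na(proteins$ko_id) & !proteins$ko_id %in% ko_vocab
  if (any(bad_ko)) {
    stop("ko_id outside the substrate vocabulary: ",
         paste(unique(proteins$ko_id[bad_ko]), collapse = ", "))
  }
  proteins
}

#' Cluster CoxL-like proteins by percent identity
#'
#' Single-linkage clustering: clusters are the connected components of the
#' graph whose edges are protein pairs with pairwise identity at or above the
#' threshold. Proteins absent from the identity table form singletons.
#' Cluster identifiers are deterministic: each cluster is named after its
#' lexicographically smallest member.
#'
#' @param proteins Protein table (see [as_coxl_proteins()]).
#' @param identities data.frame `id1`, `id2`, `percent` of pairwise percent
#'   identities (sparse; only pairs with a computed identity). When both
#'   orientations of a pair are present they must agree.
#' @param threshold Percent identity in (0, 100] at or above which two
#'   proteins are linked (default 50).
#' @param mags Optional `mag_metadata`; when given, each cluster also
#'   reports its dominant taxon at `rank` and that taxon's fraction of the
#'   cluster.
#' @param rank Taxonomic rank for `dominant_taxon` (default `"phylum"`).
#' @return data.frame of class `coxl_clusters`: one row per cluster with
#'   `cluster_id`, `size`, list column `members`, `majority_ko`,
#'   `majority_fraction`, `tie`, and (with `mags`) `dominant_taxon` and
#'   `dominant_fraction`.
#' @export
cluster_proteins <- function(proteins, identities, threshold = 50,
                             mags = NULL, rank = "phylum") {
  proteins <- as_coxl_proteins(proteins)
  if (!(threshold > 0 && threshold <= 100)) {
    stop("threshold must be in (0, 100]")
  }
  ids <- sort(proteins$protein_id)
  ed <- identities[identities$id1 %in% ids & identities$id2 %in% ids, ,
                   drop = FALSE]
  if (nrow(ed)) {
    # reject contradictory duplicate orientations (asymmetric identity)
    key <- ifelse(ed$id1 < ed$id2, paste(ed$id1, ed$id2), paste(ed$id2, ed$id1))
    agg <- tapply(ed$percent, key, function(v) diff(range(v)))
    if (any(agg > 1e-8)) {
      stop("asymmetric pairwise identities for pair(s): ",
           paste(utils::head(names(agg)[agg > 1e-8], 5), collapse = "; "))
    }
  }
  keep <- ed$percent >= threshold & ed$id1 != ed$id2
  g <- igraph::graph_from_data_frame(
    ed[keep, c("id1", "id2"), drop = FALSE],
    directed = FALSE, vertices = data.frame(name = ids))
  comp <- igraph::components(g)$membership
  members <- split(names(comp), comp)
  members <- lapply(members, sort)
  cluster_id <- vapply(members, `[[`, character(1), 1L)
  ord <- order(cluster_id, method = "radix")
  members <- members[ord]
  cluster_id <- cluster_id[ord]

  lab <- lapply(members, function(m) {
    label_cluster(m, proteins)
  })
  out <- data.frame(cluster_id = cluster_id,
                    size = lengths(members),
                    majority_ko = vapply(lab, `[[`, character(1), "majority_ko"),
                    majority_fraction = vapply(lab, `[[`, numeric(1),
                                               "majority_fraction"),
                    tie = vapply(lab, `[[`, logical(1), "tie"),
                    stringsAsFactors = FALSE)
  out$members <- unname(members)
  if (!is.null(mags)) {
    rank <- match.arg(rank, .tax_ranks)
    dom <- lapply(members, function(m) {
      tx <- taxonomy_rank(mags, proteins$mag_id[match(m, proteins$protein_id)],
                          rank)
      tx[is.na(tx)] <- "unclassified"
      tab <- sort(table(tx), decreasing = TRUE)
      list(taxon = names(tab)[1L], fraction = unname(tab[1L]) / length(m))
    })
    out$dominant_taxon <- vapply(dom, `[[`, character(1), "taxon")
    out$dominant_fraction <- vapply(dom, `[[`, numeric(1), "fraction")
  }
  rownames(out) <- NULL
  attr(out, "threshold") <- threshold
  class(out) <- c("coxl_clusters", "data.frame")
  out
}

#' Majority substrate label of a cluster
#'
#' Majority vote over the annotated members only: unassigned (`NA`) proteins
#' count toward cluster size but are excluded from the denominator. A cluster
#' with no annotated member, or with a tied vote, gets no label
#' (`majority_ko` `NA`; ties additionally flagged) — a substrate is never
#' invented.
#'
#' @param members Character vector of member protein ids.
#' @param proteins Protein table carrying `ko_id`.
#' @return List with `majority_ko`, `majority_fraction` and `tie`.
#' @export
label_cluster <- function(members, proteins) {
  kos <- proteins$ko_id[match(members, proteins$protein_id)]
  kos <- kos[!is.na(kos)]
  if (!length(kos)) {
    return(list(majority_ko = NA_character_, majority_fraction = NA_real_,
                tie = FALSE))
  }
  tab <- sort(table(kos), decreasing = TRUE)
  if (length(tab) > 1L && tab[1L] == tab[2L]) {
    return(list(majority_ko = NA_character_, majority_fraction = NA_real_,
                tie = TRUE))
  }
  list(majority_ko = names(tab)[1L],
       majority_fraction = unname(tab[1L]) / length(kos),
       tie = FALSE)
}

#' Taxon-by-substrate composition of CoxL-like proteins
#'
#' Cross-tabulates COG1529 member proteins by taxon (at the requested rank)
#' and substrate KO, with unassigned proteins as an explicit `NA` column.
#' Percentages are computed over all of a taxon's proteins, annotated or
#' not, and the percentage of CO-oxidizing coxL (K03520) out of total
#' COG1529 is reported per taxon.
#'
#' @param proteins Protein table.
#' @param mags `mag_metadata` covering every protein's MAG.
#' @param rank Taxonomic rank (default `"phylum"`).
#' @return List of class `coxl_taxon_matrix` with `count` and `percent`
#'   matrices (taxon x KO, last column `"NA"`), and `pct_K03520` per taxon.
#' @export
taxon_function_matrix <- function(proteins, mags, rank = "phylum") {
  rank <- match.arg(rank, .tax_ranks)
  proteins <- as_coxl_proteins(proteins)
  if (nrow(proteins) == 0L) {
    empty <- matrix(numeric(0), 0, 0)
    return(structure(list(count = empty, percent = empty,
                          pct_K03520 = numeric(0), rank = rank),
                     class = "coxl_taxon_matrix"))
  }
  taxon <- taxonomy_rank(mags, proteins$mag_id, rank)
  taxon[is.na(taxon)] <- "unclassified"
  ko <- ifelse(is.na(proteins$ko_id), "NA", proteins$ko_id)
  ko_levels <- c(sort(unique(ko[ko != "NA"])), "NA")
  count <- table(factor(taxon), factor(ko, levels = ko_levels))
  count <- matrix(as.integer(count), nrow = nrow(count),
                  dimnames = dimnames(count))
  total <- rowSums(count)
  percent <- sweep(count, 1, total, "/") * 100
  pct_co <- if ("K03520" %in% colnames(percent)) {
    stats::setNames(percent[, "K03520", drop = TRUE], rownames(percent))
  } else {
    stats::setNames(rep(0, nrow(percent)), rownames(percent))
  }
  structure(list(count = count, percent = percent, pct_K03520 = pct_co,
                 n_proteins = total, rank = rank),
            class = "coxl_taxon_matrix")
}

#' Per-genome COG1529 copy number by taxon
#'
#' Mean and sample standard deviation (n - 1 denominator) of CoxL-like
#' protein counts per genome, per taxon. Genomes of the taxon that carry no
#' COG1529 protein enter with a count of zero, which is why the full MAG
#' metadata is required. Taxa with a single genome report `NA` for the SD.
#'
#' @param proteins Protein table.
#' @param mags `mag_metadata` for all genomes (not only those with hits).
#' @param rank Taxonomic rank (default `"phylum"`).
#' @return data.frame `taxon`, `n_genomes`, `mean`, `sd`.
#' @export
per_genome_counts <- function(proteins, mags, rank = "phylum") {
  rank <- match.arg(rank, .tax_ranks)
  proteins <- as_coxl_proteins(proteins)
  taxon_all <- mags[[rank]]
  taxon_all[is.na(taxon_all)] <- "unclassified"
  per_mag <- table(factor(proteins$mag_id, levels = mags$mag_id))
  counts <- as.integer(per_mag)
  out <- do.call(rbind, lapply(split(counts, taxon_all), function(v) {
    data.frame(n_genomes = length(v), mean = mean(v),
               sd = if (length(v) > 1L) stats::sd(v) else NA_real_)
  }))
  out <- data.frame(taxon = rownames(out), out, row.names = NULL,
                    stringsAsFactors = FALSE)
  out[order(out$taxon, method = "radix"), , drop = FALSE]
}
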