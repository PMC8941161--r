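#' Read a per-model HMM score threshold table
#'
#' Reads a YAML file mapping HMM model names to the minimum accepted bit
#' score. Records from [read_annotation_table()] whose `hmm_score` falls
#' below their model's threshold are dropped at ingestion.
#'
#' @param path Path to a YAML file of `model: score` pairs.
#' @return A named numeric vector (class `hmm_thresholds`).
#' @examples
#' thr <- read_hmm_thresholds(
#'   system.file("extdata", "hmm_thresholds.yaml", package = "spongetroph"))
#' @export
read_hmm_thresholds <- function(path) {
  if (!file.exists(path)) stop("threshold file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (length(raw) == 0L) stop("threshold file is empty: ", path)
  thr <- vapply(raw, as.numeric, numeric(1))
  if (any(!is.finite(thr))) {
    stop("non-finite threshold for model(s): ",
         paste(names(thr)[!is.finite(thr)], collapse = ", "))
  }
  structure(thr, class = "hmm_thresholds")
}

# canonical column set of an annotation table; ko_id/cog_id/hmm_* optional
.ann_required_cols <- c("gene_id", "mag_id")
.ann_optional_cols <- c("ko_id", "cog_id", "hmm_model", "hmm_score")

.read_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, na.strings = c("NA", ""),
                    check.names = FALSE)
}

#' Read a gene-level functional annotation table
#'
#' Ingests the tab-separated output of a KO search (KofamKOALA-style), a COG
#' assignment, or an hmmsearch run, already reduced to one row per gene
#' assignment with a header. Columns `gene_id` and `mag_id` are required; at
#' least one of `ko_id`, `cog_id` or `hmm_model` must be present per row, and
#' any row with an `hmm_model` must carry an `hmm_score`. HMM rows are
#' filtered against the per-model score thresholds; rows whose model has no
#' threshold are rejected with a warning.
#'
#' @param path Path to a UTF-8 tab-separated file with a header row.
#' @param thresholds Optional `hmm_thresholds` object from
#'   [read_hmm_thresholds()]. Required when the table contains HMM rows.
#' @param columns Optional named character vector mapping canonical column
#'   names to the names actually used in the file, e.g.
#'   `c(gene_id = "orf", mag_id = "bin")`.
#' @return A data.frame of annotation records with canonical column names,
#'   ordered deterministically by (mag_id, gene_id, evidence).
#' @export
read_annotation_table <- function(path, thresholds = NULL, columns = NULL) {
  tab <- .read_tsv(path)
  if (!is.null(columns)) {
    for (canon in names(columns)) {
      hit <- match(columns[[canon]], names(tab))
      if (!is.na(hit)) names(tab)[hit] <- canon
    }
  }
  missing_cols <- setdiff(.ann_required_cols, names(tab))
  if (length(missing_cols)) {
    stop("annotation table ", path, " lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  for (col in .ann_optional_cols) if (!col %in% names(tab)) tab[[col]] <- NA
  tab <- tab[, c(.ann_required_cols, .ann_optional_cols)]
  tab$hmm_score <- as.numeric(tab$hmm_score)

  no_evidence <- is.na(tab$ko_id) & is.na(tab$cog_id) & is.na(tab$hmm_model)
  if (any(no_evidence)) {
    stop("annotation rows without any KO/COG/HMM assignment: ",
         paste(utils::head(tab$gene_id[no_evidence], 5), collapse = ", "))
  }
  bad_hmm <- !is.na(tab$hmm_model) & is.na(tab$hmm_score)
  if (any(bad_hmm)) {
    stop("HMM rows missing hmm_score: ",
         paste(utils::head(tab$gene_id[bad_hmm], 5), collapse = ", "))
  }

  is_hmm <- !is.na(tab$hmm_model)
  if (any(is_hmm)) {
    if (is.null(thresholds)) {
      stop("table contains HMM rows but no thresholds were supplied")
    }
    known <- tab$hmm_model[is_hmm] %in% names(thresholds)
    if (any(!known)) {
      dropped_models <- unique(tab$hmm_model[is_hmm][!known])
      warning("rejecting HMM records with no score threshold for model(s): ",
              paste(dropped_models, collapse = ", "))
    }
    cutoff <- unname(thresholds[tab$hmm_model[is_hmm]])
    keep_hmm <- known & tab$hmm_score[is_hmm] >= cutoff
    keep <- rep(TRUE, nrow(tab))
    keep[is_hmm] <- keep_hmm
    tab <- tab[keep, , drop = FALSE]
  }

  ord <- order(tab$mag_id, tab$gene_id, tab$ko_id, tab$cog_id, tab$hmm_model,
               method = "radix", na.last = TRUE)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Write an annotation record table
#'
#' Inverse of [read_annotation_table()] (without threshold filtering);
#' reading the written file back reproduces the records field-for-field.
#'
#' @param records Annotation data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation_table <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Ordered taxonomy ranks used throughout the package
#' @keywords internal
.tax_ranks <- c("domain", "phylum", "class", "order", "family")

#' Read MAG metadata
#'
#' One row per metagenome-assembled genome: identifier, semicolon-separated
#' taxonomy string (domain to family, trailing ranks may be absent),
#' CheckM-style completeness and contamination percentages, host sponge and
#' source study. Quality metrics are ingested, never recomputed.
#'
#' @param path Tab-separated file with columns `mag_id`, `taxonomy`,
#'   `completeness`, `contamination` and optionally `host`, `source_study`.
#' @return A data.frame (class `mag_metadata`) with one column per taxonomy
#'   rank (`domain` ... `family`, `NA` where unresolved) in addition to the
#'   input columns.
#' @export
read_mag_metadata <- function(path) {
  tab <- .read_tsv(path)
  need <- c("mag_id", "taxonomy", "completeness", "contamination")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols)) {
    stop("MAG metadata lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (!"host" %in% names(tab)) tab$host <- NA_character_
  if (!"source_study" %in% names(tab)) tab$source_study <- NA_character_
  as_mag_metadata(tab)
}

#' Construct MAG metadata from a data.frame
#'
#' @param tab data.frame with at least `mag_id`, `taxonomy`, `completeness`,
#'   `contamination`.
#' @return Validated `mag_metadata` data.frame with taxonomy split per rank.
#' @export
as_mag_metadata <- function(tab) {
  dup <- duplicated(tab$mag_id)
  if (any(dup)) {
    stop("duplicate mag_id in MAG metadata: ",
         paste(unique(tab$mag_id[dup]), collapse = ", "))
  }
  tab$completeness <- as.numeric(tab$completeness)
  tab$contamination <- as.numeric(tab$contamination)
  bad_comp <- is.na(tab$completeness) | tab$completeness < 0 |
    tab$completeness > 100
  if (any(bad_comp)) {
    stop("completeness outside [0, 100] for: ",
         paste(tab$mag_id[bad_comp], collapse = ", "))
  }
  if (any(is.na(tab$contamination) | tab$contamination < 0)) {
    stop("contamination must be >= 0")
  }
  ranks <- strsplit(as.character(tab$taxonomy), ";", fixed = TRUE)
  for (i in seq_along(.tax_ranks)) {
    tab[[.tax_ranks[i]]] <- vapply(ranks, function(r) {
      v <- trimws(r[i])
      if (length(v) == 0L || is.na(v) || !nzchar(v)) NA_character_ else v
    }, character(1))
  }
  tab <- tab[order(tab$mag_id, method = "radix"), , drop = FALSE]
  rownames(tab) <- NULL
  class(tab) <- c("mag_metadata", "data.frame")
  tab
}

#' Write MAG metadata
#' @param mags `mag_metadata` data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mag_metadata <- function(mags, path) {
  keep <- c("mag_id", "taxonomy", "completeness", "contamination",
            "host", "source_study")
  utils::write.table(as.data.frame(mags)[, keep], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Look up a taxonomy rank for a set of MAGs
#'
#' @param mags `mag_metadata` data.frame.
#' @param mag_id Character vector of MAG identifiers.
#' @param rank One of `"domain"`, `"phylum"`, `"class"`, `"order"`,
#'   `"family"`.
#' @return Character vector of taxon names (`NA` where unresolved).
#' @export
taxonomy_rank <- function(mags, mag_id, rank = "phylum") {
  rank <- match.arg(rank, .tax_ranks)
  idx <- match(mag_id, mags$mag_id)
  if (anyNA(idx)) {
    stop("unknown mag_id(s): ",
         paste(unique(mag_id[is.na(idx)]), collapse = ", "))
  }
  mags[[rank]][idx]
}

#' Merge KO, COG and HMM annotations into a per-MAG evidence index
#'
#' Combines the three evidence streams into one queryable index. A gene
#' carrying assignments from several sources (or several KOs) contributes a
#' single gene but multiple evidence tags, so gene counts are never inflated
#' by multi-source annotation. The result is invariant to the row order of
#' the inputs.
#'
#' @param ko,cog,hmm Annotation data.frames as returned by
#'   [read_annotation_table()]; any may be `NULL` or empty.
#' @param mags Optional `mag_metadata`; when supplied, records referencing a
#'   MAG absent from the metadata raise an error.
#' @return An object of class `mag_index` with components `evidence`
#'   (mag_id, gene_id, accession, source), `genes` (distinct mag_id/gene_id
#'   pairs) and `mags` (sorted MAG ids).
#' @export
merge_annotations <- function(ko = NULL, cog = NULL, hmm = NULL, mags = NULL) {
  pick <- function(tab, col, source) {
    if (is.null(tab) || nrow(tab) == 0L) return(NULL)
    keep <- !is.na(tab[[col]])
    if (!any(keep)) return(NULL)
    data.frame(mag_id = tab$mag_id[keep], gene_id = tab$gene_id[keep],
               accession = as.character(tab[[col]][keep]), source = source,
               stringsAsFactors = FALSE)
  }
  ev <- rbind(pick(ko, "ko_id", "KO"),
              pick(cog, "cog_id", "COG"),
              pick(hmm, "hmm_model", "HMM"))
  if (is.null(ev)) {
    ev <- data.frame(mag_id = character(), gene_id = character(),
                     accession = character(), source = character(),
                     stringsAsFactors = FALSE)
  }
  if (!is.null(mags)) {
    unknown <- setdiff(unique(ev$mag_id), mags$mag_id)
    if (length(unknown)) {
      stop("annotation records reference unknown mag_id(s): ",
           paste(unknown, collapse = ", "))
    }
  }
  ev <- unique(ev)
  ord <- order(ev$mag_id, ev$gene_id, ev$source, ev$accession,
               method = "radix")
  ev <- ev[ord, , drop = FALSE]
  rownames(ev) <- NULL
  genes <- unique(ev[, c("mag_id", "gene_id")])
  rownames(genes) <- NULL
  mag_ids <- if (!is.null(mags)) mags$mag_id else sort(unique(ev$mag_id))
  structure(list(evidence = ev, genes = genes, mags = mag_ids),
            class = "mag_index")
}

#' @export
print.mag_index <- function(x, ...) {
  cat("<mag_index> ", length(x$mags), " MAGs, ", nrow(x$genes),
      " genes, ", nrow(x$evidence), " evidence records\n", sep = "")
  src <- table(x$evidence$source)
  if (length(src)) {
    cat("  evidence by source: ",
        paste(names(src), src, sep = "=", collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Accessions present in one MAG
#'
#' Pools KO ids, COG ids and passed HMM model names for a MAG; this is the
#' evidence set pathway rules are evaluated against.
#'
#' @param index A `mag_index`.
#' @param mag_id Single MAG identifier.
#' @return Character vector of unique accessions (empty for a MAG with no
#'   annotations).
#' @export
mag_accessions <- function(index, mag_id) {
  stopifnot(inherits(index, "mag_index"), length(mag_id) == 1L)
  unique(index$evidence$accession[index$evidence$mag_id == mag_id])
}

#' Genes annotated in one MAG
#' @param index A `mag_index`.
#' @param mag_id Single MAG identifier.
#' @return Character vector of gene ids.
#' @export
mag_genes <- function(index, mag_id) {
  stopifnot(inherits(index, "mag_index"))
  index$genes$gene_id[index$genes$mag_id == mag_id]
}
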