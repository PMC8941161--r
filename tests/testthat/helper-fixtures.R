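# shared fixture builders; everything is generated in code at test time

write_tsv_tmp <- function(df) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  path
}

ann_row <- function(gene_id, mag_id, ko_id = NA, cog_id = NA,
                    hmm_model = NA, hmm_score = NA) {
  data.frame(gene_id = gene_id, mag_id = mag_id, ko_id = ko_id,
             cog_id = cog_id, hmm_model = hmm_model, hmm_score = hmm_score,
             stringsAsFactors = FALSE)
}

mags_fixture <- function(mag_id, phylum,
                         completeness = 90, contamination = 1) {
  as_mag_metadata(data.frame(
    mag_id = mag_id, taxonomy = paste("Bacteria", phylum, sep = ";"),
    completeness = completeness, contamination = contamination,
    host = "sponge", source_study = "test", stringsAsFactors = FALSE))
}

# index built straight from (mag_id, accession) pairs via the KO table route
index_from_accessions <- function(mag_id, accessions, mags = NULL) {
  ko <- ann_row(gene_id = sprintf("g%03d", seq_along(accessions)),
                mag_id = mag_id, ko_id = accessions)
  merge_annotations(ko = ko, mags = mags)
}

# brute-force transitive-closure oracle for single-linkage clustering:
# repeated pairwise merging until fixpoint, independent of igraph
oracle_components <- function(ids, edges) {
  part <- as.list(ids)
  repeat {
    changed <- FALSE
    for (i in seq_len(nrow(edges))) {
      a <- which(vapply(part, function(s) edges$id1[i] %in% s, logical(1)))
      b <- which(vapply(part, function(s) edges$id2[i] %in% s, logical(1)))
      if (length(a) && length(b) && a != b) {
        part[[a]] <- sort(union(part[[a]], part[[b]]))
        part[[b]] <- NULL
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  part <- lapply(part, sort)
  part[order(vapply(part, `[[`, character(1), 1L))]
}

random_identity_graph <- function(n, p_edge = 0.08) {
  ids <- sprintf("p%03d", seq_len(n))
  pairs <- t(utils::combn(ids, 2L))
  keep <- stats::runif(nrow(pairs)) < p_edge
  data.frame(id1 = pairs[keep, 1L], id2 = pairs[keep, 2L],
             percent = stats::runif(sum(keep), 0, 100),
             stringsAsFactors = FALSE)
}

proteins_fixture <- function(ids, ko = NA, mag_id = "magA") {
  data.frame(protein_id = ids, mag_id = mag_id, length = 500,
             ko_id = ko, stringsAsFactors = FALSE)
}

# normalise a partition (list of member vectors) for comparison
canon_partition <- function(part) {
  part <- lapply(part, sort)
  unname(part[order(vapply(part, `[[`, character(1), 1L))])
}
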