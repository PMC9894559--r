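# CifA/CifB toxin-antitoxin pair calling (e-value / coverage / adjacency
# rules), pair localisation relative to prophage regions, and biotin operon
# detection with transposase-disruption calls.

#' Find CifA-CifB pairs
#'
#' A gene qualifies as CifA (resp. CifB) iff it has at least one reference
#' hit with that role, e-value <= `evalue_max` and query coverage within
#' `[cov_min, cov_max]` percent.  A pair is emitted iff a qualifying CifA and
#' CifB are immediately adjacent in gene order on the same replicon (either
#' order, any strands).  The type label is taken from the best-bitscore
#' reference hit over both genes; `in_eam` records whether the pair span
#' intersects any supplied prophage region.  Genes qualifying as both A and B
#' are flagged ambiguous and excluded.
#'
#' @param hits Data frame of gene-vs-reference hits with columns `gene_id`,
#'   `reference_id`, `role` ("CifA"/"CifB"), `type_label` (I..V), `evalue`,
#'   `query_coverage` (percent), `bitscore`.
#' @param annotations `gene_annotations` for one genome (defines gene order).
#' @param prophage_regions Optional list of `prophage_region`s for `in_eam`.
#' @param evalue_max,cov_min,cov_max Qualification thresholds.
#' @return List with `pairs` (data frame: genome_id, cifA_gene, cifB_gene,
#'   type_label, in_eam, evalue_A, evalue_B) and `ambiguous` (gene ids).
#' @export
find_cif_pairs <- function(hits, annotations, prophage_regions = NULL,
                           evalue_max = 1e-30, cov_min = 80, cov_max = 120,
                           circular = TRUE) {
  qual <- hits[hits$evalue <= evalue_max &
                 hits$query_coverage >= cov_min &
                 hits$query_coverage <= cov_max, , drop = FALSE]
  roleA <- unique(qual$gene_id[qual$role == "CifA"])
  roleB <- unique(qual$gene_id[qual$role == "CifB"])
  ambiguous <- intersect(roleA, roleB)
  roleA <- setdiff(roleA, ambiguous)
  roleB <- setdiff(roleB, ambiguous)

  pairs <- list()
  for (gid in unique(annotations$genome_id)) {
    ann <- annotations[annotations$genome_id == gid, , drop = FALSE]
    ann <- ann[!duplicated(ann$gene_id), , drop = FALSE]
    ann <- ann[order(ann$start), , drop = FALSE]
    if (nrow(ann) < 2L) next
    # circular replicons: the last and first genes are also neighbours
    idx2 <- if (circular) c(seq_len(nrow(ann))[-1], 1L) else seq(2L, nrow(ann))
    for (jj in seq_along(idx2)) {
      i <- jj; inext <- idx2[jj]
      g1 <- ann$gene_id[i]; g2 <- ann$gene_id[inext]
      isA1 <- g1 %in% roleA; isB1 <- g1 %in% roleB
      isA2 <- g2 %in% roleA; isB2 <- g2 %in% roleB
      if (!((isA1 && isB2) || (isB1 && isA2))) next
      cifA <- if (isA1) g1 else g2
      cifB <- if (isA1) g2 else g1
      hh <- qual[qual$gene_id %in% c(g1, g2), , drop = FALSE]
      best <- hh[which.max(hh$bitscore), , drop = FALSE]
      span <- range(ann$start[i], ann$end[i], ann$start[inext], ann$end[inext])
      in_eam <- FALSE
      if (!is.null(prophage_regions)) {
        for (r in prophage_regions) {
          if (r$genome_id != gid) next
          if (span[1] < r$span[2] && span[2] > r$span[1]) { in_eam <- TRUE; break }
        }
      }
      eA <- min(qual$evalue[qual$gene_id == cifA & qual$role == "CifA"])
      eB <- min(qual$evalue[qual$gene_id == cifB & qual$role == "CifB"])
      pairs[[length(pairs) + 1L]] <- data.frame(
        genome_id = gid, cifA_gene = cifA, cifB_gene = cifB,
        type_label = best$type_label, in_eam = in_eam,
        evalue_A = eA, evalue_B = eB, stringsAsFactors = FALSE)
    }
  }
  if (length(pairs) > 0L) {
    key <- vapply(pairs, function(p)
      paste(p$genome_id, p$cifA_gene, p$cifB_gene), character(1))
    pairs <- pairs[!duplicated(key)]
  }
  pairs_df <- if (length(pairs) > 0L) do.call(rbind, pairs) else
    data.frame(genome_id = character(), cifA_gene = character(),
               cifB_gene = character(), type_label = character(),
               in_eam = logical(), evalue_A = numeric(), evalue_B = numeric(),
               stringsAsFactors = FALSE)
  list(pairs = pairs_df, ambiguous = ambiguous)
}

#' Summarise Cif pairs
#'
#' @param pairs Pair data frame from [find_cif_pairs()].
#' @return List: `n_pairs`, `per_type` (named counts over I..V),
#'   `genomes_with_pair`, `eam` (a [percent_summary()] of pairs located in
#'   the prophage EAM).
#' @export
summarize_cif <- function(pairs) {
  per_type <- table(factor(pairs$type_label, levels = c("I", "II", "III", "IV", "V")))
  eam <- if (nrow(pairs) > 0L)
    percent_summary("cif_pairs_in_eam", sum(pairs$in_eam), nrow(pairs)) else NULL
  list(n_pairs = nrow(pairs),
       per_type = stats::setNames(as.integer(per_type), names(per_type)),
       genomes_with_pair = length(unique(pairs$genome_id)),
       eam = eam)
}

#' Detect the biotin operon and its disruption
#'
#' The operon is `present` iff all six genes (bioA, bioB, bioC, bioD, bioF,
#' bioH) are found within one locus: consecutive bio genes separated by at
#' most `max_intervening` non-bio genes.  `order_conserved` is TRUE iff the
#' six genes occur in the canonical order (default bioA,bioD,bioC,bioH,bioF,
#' bioB) or its exact reverse.  `disrupted` is TRUE iff a transposase-tagged
#' gene lies inside the locus span.
#'
#' @param annotations `gene_annotations` for one genome.
#' @param max_intervening Maximum non-bio genes between consecutive bio genes.
#' @param canonical Canonical gene order (configurable).
#' @return List of class `biotin_operon_call`: genome_id, present,
#'   genes_found, order_conserved, disrupted, span.
#' @export
find_biotin_operon <- function(annotations, max_intervening = 2L,
                               canonical = c("bioA", "bioD", "bioC",
                                             "bioH", "bioF", "bioB")) {
  gid <- unique(annotations$genome_id)
  if (length(gid) != 1L) stop("find_biotin_operon expects a single genome")
  ann <- annotations[order(annotations$start), , drop = FALSE]
  bio_tags <- c("bioA", "bioB", "bioC", "bioD", "bioF", "bioH")
  which_bio <- vapply(strsplit(ann$tags, ",", fixed = TRUE), function(tt) {
    m <- intersect(tt, bio_tags)
    if (length(m) > 0L) m[1] else NA_character_
  }, character(1))
  bio_idx <- which(!is.na(which_bio))
  empty <- list(genome_id = gid, present = FALSE,
                genes_found = character(0), order_conserved = FALSE,
                disrupted = FALSE, span = NULL)
  class(empty) <- "biotin_operon_call"
  if (length(bio_idx) == 0L) return(empty)

  # cluster bio genes into loci by the intervening-gene rule, keep the locus
  # with the most distinct bio genes
  gaps <- diff(bio_idx) - 1L
  locus_id <- cumsum(c(TRUE, gaps > max_intervening))
  loci <- split(bio_idx, locus_id)
  nfound <- vapply(loci, function(i) length(unique(which_bio[i])), integer(1))
  idx <- loci[[which.max(nfound)]]
  found <- which_bio[idx]
  present <- length(unique(found)) == 6L
  span <- c(ann$start[min(idx)], ann$end[max(idx)])
  inside <- seq(min(idx), max(idx))
  disrupted <- any(has_tag(ann[inside, , drop = FALSE], "transposase"))
  order_conserved <- present &&
    (identical(found, canonical) || identical(found, rev(canonical)))
  structure(list(genome_id = gid, present = present,
                 genes_found = sort(unique(found)),
                 order_conserved = order_conserved,
                 disrupted = disrupted, span = span),
            class = "biotin_operon_call")
}

#' Generic qualifying-gene caller for other toxin families
#'
#' Reuses the Cif qualification rule (e-value and coverage window) without
#' the pairing constraint; paired families (RelE/RelB, ParD/ParE) can be
#' paired downstream with [find_cif_pairs()]-style adjacency by passing the
#' two roles.
#'
#' @param hits Hit data frame as in [find_cif_pairs()] (any `role` values).
#' @param evalue_max,cov_min,cov_max Thresholds (per-family configuration).
#' @return Data frame of qualifying gene/role combinations.
#' @export
find_toxin_genes <- function(hits, evalue_max = 1e-30, cov_min = 80,
                             cov_max = 120) {
  qual <- hits[hits$evalue <= evalue_max &
                 hits$query_coverage >= cov_min &
                 hits$query_coverage <= cov_max, , drop = FALSE]
  unique(qual[, c("gene_id", "role")])
}
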