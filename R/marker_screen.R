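# SSU rRNA marker screening: hit filters and the 80%-of-top-20 consensus
# taxonomy rule used to decide whether a sample carries the target
# endosymbiont genus.

#' Filter SSU rRNA marker hits
#'
#' A hit is retained iff (e-value < 1e-150 OR aligned length > 1,000 nt) AND
#' percent identity > 90.  Input order is preserved.
#'
#' @param hits Data frame with columns `evalue`, `aligned_length`,
#'   `pct_identity` (plus any others, e.g. `lineage`, `bitscore`).
#' @param evalue_max E-value branch threshold (strict `<`).
#' @param min_aligned_length Aligned-length branch threshold (strict `>`).
#' @param min_identity Identity threshold in percent (strict `>`).
#' @return The retained subset of `hits`, original order.
#' @export
filter_ssu_hits <- function(hits, evalue_max = 1e-150,
                            min_aligned_length = 1000,
                            min_identity = 90) {
  need <- c("evalue", "aligned_length", "pct_identity")
  miss <- setdiff(need, names(hits))
  if (length(miss) > 0L)
    stop("hits table is missing field(s): ", paste(miss, collapse = ", "))
  if (nrow(hits) == 0L) return(hits)
  bad <- which(is.na(hits$evalue) | is.na(hits$aligned_length) |
                 is.na(hits$pct_identity))
  if (length(bad) > 0L)
    stop("missing field value in hit row(s): ", paste(bad, collapse = ", "))
  keep <- (hits$evalue < evalue_max | hits$aligned_length > min_aligned_length) &
    hits$pct_identity > min_identity
  hits[keep, , drop = FALSE]
}

split_lineage <- function(x) strsplit(x, ";", fixed = TRUE)

#' Consensus taxonomic classification of marker hits
#'
#' Hits are ranked by descending bitscore (ties: lower e-value, then lexical
#' `target_id`) and the best `top_n` are considered (all hits if fewer).
#' Walking ranks from root to leaf, the classifier descends while at least
#' `consensus_fraction` (inclusive boundary) of the considered hits agree on
#' one taxon, and returns the deepest rank reached.
#'
#' @param hits Data frame with `lineage` (semicolon-separated root-to-leaf
#'   ranks), `bitscore`, `evalue`, `target_id`.
#' @param top_n Number of best hits to consider.
#' @param consensus_fraction Agreement fraction required to descend; must be
#'   > 0.5 so the consensus taxon is unique.
#' @param lineage_col Name of the lineage column (supports dual-taxonomy
#'   classification by calling once per source).
#' @return List with `lineage` (character vector of ranks, or "unclassified")
#'   and `rank` (integer depth reached; 0 if unclassified).
#' @export
consensus_classify <- function(hits, top_n = 20, consensus_fraction = 0.8,
                               lineage_col = "lineage") {
  if (consensus_fraction <= 0.5)
    stop("consensus_fraction must be > 0.5")
  if (nrow(hits) == 0L)
    return(list(lineage = "unclassified", rank = 0L))
  ord <- order(-hits$bitscore, hits$evalue, hits$target_id)
  top <- hits[utils::head(ord, top_n), , drop = FALSE]
  lins <- split_lineage(top[[lineage_col]])
  n <- length(lins)
  maxdepth <- max(lengths(lins))
  consensus <- character(0)
  for (d in seq_len(maxdepth)) {
    taxa <- vapply(lins, function(l) if (length(l) >= d) l[d] else NA_character_,
                   character(1))
    tab <- table(taxa[!is.na(taxa)])
    if (length(tab) == 0L) break
    best <- names(tab)[which.max(tab)]
    if (max(tab) / n >= consensus_fraction) {
      consensus <- c(consensus, best)
      # only hits agreeing so far could agree deeper; but the rule counts
      # agreement against all considered hits, so keep the full denominator
      lins <- lapply(lins, function(l)
        if (length(l) >= d && l[d] == best) l else character(0))
    } else break
  }
  if (length(consensus) == 0L)
    list(lineage = "unclassified", rank = 0L)
  else
    list(lineage = consensus, rank = length(consensus))
}

#' Screen one sample for the target endosymbiont
#'
#' Applies [filter_ssu_hits()] then [consensus_classify()]; the sample is
#' positive iff any hits survive the filter and the consensus lineage contains
#' the target genus.  When the hits table carries a second lineage column
#' (`lineage2`, e.g. an alternative taxonomy), the classification is run once
#' per source and both must contain the target genus; disagreement flags the
#' decision `ambiguous` and the sample is treated as negative.
#'
#' @param sample_id Sample identifier.
#' @param hits Hit table (see [filter_ssu_hits()]).
#' @param target_genus Genus label the consensus must contain.
#' @param top_n,consensus_fraction Passed to [consensus_classify()].
#' @return List of class `screen_decision`: `sample_id`, `positive`,
#'   `ambiguous`, `retained_hits`, `consensus_lineage`, `consensus_rank`.
#' @export
screen_sample <- function(sample_id, hits, target_genus = "Wolbachia",
                          top_n = 20, consensus_fraction = 0.8) {
  retained <- filter_ssu_hits(hits)
  cls <- consensus_classify(retained, top_n = top_n,
                            consensus_fraction = consensus_fraction)
  positive <- nrow(retained) > 0L && target_genus %in% cls$lineage
  ambiguous <- FALSE
  if ("lineage2" %in% names(hits) && nrow(retained) > 0L) {
    cls2 <- consensus_classify(retained, top_n = top_n,
                               consensus_fraction = consensus_fraction,
                               lineage_col = "lineage2")
    positive2 <- target_genus %in% cls2$lineage
    if (positive != positive2) {
      ambiguous <- TRUE
      positive <- FALSE
    }
  }
  structure(list(sample_id = sample_id, positive = positive,
                 ambiguous = ambiguous, retained_hits = retained,
                 consensus_lineage = cls$lineage, consensus_rank = cls$rank),
            class = "screen_decision")
}

#' @export
print.screen_decision <- function(x, ...) {
  cat(sprintf("<screen_decision> %s: %s (consensus: %s)\n", x$sample_id,
              if (x$ambiguous) "ambiguous" else
                if (x$positive) "positive" else "negative",
              paste(x$consensus_lineage, collapse = ";")))
  invisible(x)
}

#' Read a marker hit table (TSV)
#'
#' Columns: query_id, target_id, evalue, aligned_length, pct_identity,
#' bitscore, lineage (semicolon-separated) and optionally lineage2.
#'
#' @param path TSV path with header.
#' @return Data frame of hits.
#' @export
read_hits <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("query_id", "target_id", "evalue", "aligned_length",
            "pct_identity", "bitscore", "lineage")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop("hit table missing column(s): ", paste(miss, collapse = ", "))
  df
}
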