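# Separation of endosymbiont sequence from host: coverage of contigs by
# endosymbiont-classified reads, the NUWT (nuclear insertion) filter, assembly
# candidate ranking, and relative endosymbiont abundance.

interval_union_length <- function(starts, ends) {
  if (length(starts) == 0L) return(0L)
  o <- order(starts, ends)
  s <- starts[o]; e <- ends[o]
  tot <- 0L; cs <- s[1]; ce <- e[1]
  for (i in seq_along(s)[-1]) {
    if (s[i] > ce) { tot <- tot + (ce - cs); cs <- s[i]; ce <- e[i] }
    else ce <- max(ce, e[i])
  }
  tot + (ce - cs)
}

#' Per-contig coverage from read alignments
#'
#' `covered_fraction` is the length of the union of alignment intervals over
#' the contig length (so it is invariant to splitting alignments into
#' abutting pieces); `mean_depth` is the summed interval length over the
#' contig length.
#'
#' @param alignments Read alignment data frame (see [read_alignments()]);
#'   typically restricted to endosymbiont-class reads by the caller.
#' @param contig_lengths Named integer vector, contig_id -> length.
#' @return Data frame: contig_id, length, covered_fraction, mean_depth.
#' @export
contig_coverage <- function(alignments, contig_lengths) {
  stopifnot(!is.null(names(contig_lengths)))
  unknown <- setdiff(unique(alignments$contig_id), names(contig_lengths))
  if (length(unknown) > 0L)
    stop("alignments reference unknown contig(s): ",
         paste(unknown, collapse = ", "))
  out <- lapply(names(contig_lengths), function(cid) {
    L <- contig_lengths[[cid]]
    a <- alignments[alignments$contig_id == cid, , drop = FALSE]
    if (nrow(a) > 0L && (any(a$contig_start < 0L) || any(a$contig_end > L)))
      stop("alignment interval outside contig bounds on ", cid)
    data.frame(contig_id = cid, length = L,
               covered_fraction = interval_union_length(a$contig_start, a$contig_end) / L,
               mean_depth = sum(a$contig_end - a$contig_start) / L,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Classify contigs as endosymbiont replicons vs potential NUWT carriers
#'
#' A contig is called `endosymbiont_replicon` iff its covered fraction by
#' endosymbiont-class reads reaches `full_threshold` (default 1.0, i.e. fully
#' covered); anything less is `host_with_possible_nuwt`, which avoids calling
#' nuclear insertions of endosymbiont DNA as independent replicons.
#'
#' @param coverages Output of [contig_coverage()] computed from
#'   endosymbiont-class reads.
#' @param full_threshold Covered-fraction threshold (default 1.0).
#' @return Named character vector contig_id -> class.
#' @export
classify_contigs <- function(coverages, full_threshold = 1.0) {
  stats::setNames(
    ifelse(coverages$covered_fraction >= full_threshold,
           "endosymbiont_replicon", "host_with_possible_nuwt"),
    coverages$contig_id)
}

# windowed depth over one contig from alignment intervals
windowed_depth <- function(alignments, contig_len, window = 10000L) {
  nwin <- max(1L, contig_len %/% window)
  ws <- (seq_len(nwin) - 1L) * window
  we <- pmin(ws + window, contig_len)
  vapply(seq_len(nwin), function(i) {
    ov <- pmin(alignments$contig_end, we[i]) - pmax(alignments$contig_start, ws[i])
    sum(ov[ov > 0]) / (we[i] - ws[i])
  }, numeric(1))
}

weighted_median <- function(x, w) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  unname(x[which(cw >= 0.5)[1]])
}

#' Estimate relative endosymbiont abundance
#'
#' Depth on each side is the length-weighted median of fixed-window depths
#' over the respective contig set (robust to copy-number windows such as
#' integrated prophage); the estimate is endosymbiont depth over host depth,
#' i.e. endosymbiont genome copies per host genome copy.
#'
#' @param endo_alignments,host_alignments Alignment data frames for reads on
#'   the endosymbiont and host contig sets.
#' @param endo_lengths,host_lengths Named contig length vectors.
#' @param window Window size in nt.
#' @return List of class `relative_abundance`: `endo_per_host`, `endo_depth`,
#'   `host_depth`.
#' @export
estimate_relative_abundance <- function(endo_alignments, host_alignments,
                                        endo_lengths, host_lengths,
                                        window = 10000L) {
  if (length(endo_lengths) == 0L || length(host_lengths) == 0L)
    stop("both contig sets must be non-empty")
  side_depth <- function(aln, lens) {
    d <- list(); w <- list()
    for (cid in names(lens)) {
      a <- aln[aln$contig_id == cid, , drop = FALSE]
      dep <- windowed_depth(a, lens[[cid]], window)
      d[[cid]] <- dep
      w[[cid]] <- rep(min(window, lens[[cid]]), length(dep))
    }
    weighted_median(unlist(d), unlist(w))
  }
  endo_depth <- side_depth(endo_alignments, endo_lengths)
  host_depth <- side_depth(host_alignments, host_lengths)
  if (host_depth == 0) stop("host depth is zero; abundance ratio undefined")
  structure(list(endo_per_host = endo_depth / host_depth,
                 endo_depth = endo_depth, host_depth = host_depth),
            class = "relative_abundance")
}

#' Rank candidate assemblies
#'
#' Lexicographic order: higher completeness, then lower duplication, then
#' circular before non-circular, then fewer contigs, then lower depth
#' coefficient of variation; remaining ties broken by assembler label.
#'
#' @param candidates Data frame with columns `assembler_label`,
#'   `completeness_pct`, `duplication_pct`, `n_contigs`, `circular`,
#'   `depth_cv`.
#' @return `candidates` reordered best-first.
#' @export
rank_assemblies <- function(candidates) {
  if (is.null(candidates) || nrow(candidates) == 0L)
    stop("no assembly candidates to rank")
  o <- order(-candidates$completeness_pct,
             candidates$duplication_pct,
             !candidates$circular,
             candidates$n_contigs,
             candidates$depth_cv,
             candidates$assembler_label)
  out <- candidates[o, , drop = FALSE]
  rownames(out) <- NULL
  out
}
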