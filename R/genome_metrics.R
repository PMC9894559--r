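# Intrinsic genome properties: rotation of circular genomes to a fixed origin
# anchor, GC content, windowed GC skew, and a split-maximisation skew index
# ("SkewI-like", bounded in [0,1]).

#' Rotate a circular genome so an anchor gene starts at position 0 on +
#'
#' If the single gene of `anchor_family` lies on the minus strand the genome
#' is reverse-complemented first; the sequence is then rotated so the anchor
#' starts at position 0 on the forward strand, and all annotations are shifted
#' and strand-flipped consistently.  Genes cut by the rotation point are split
#' into two parts sharing their `gene_id`.  Applying the operation twice
#' equals applying it once.
#'
#' @param genome A circular `genome_record`.
#' @param annotations `gene_annotations` for this genome (other genomes'
#'   rows are passed through untouched).
#' @param anchor_family Family id of the anchor gene (e.g. the replication
#'   origin proxy hemE).
#' @return List with rotated `genome` and shifted `annotations`.
#' @export
rotate_to_anchor <- function(genome, annotations, anchor_family = "hemE") {
  if (!genome$circular) stop("rotation requires a circular genome")
  mine <- annotations$genome_id == genome$genome_id
  ann <- annotations[mine, , drop = FALSE]
  hit <- ann[!is.na(ann$family_id) & ann$family_id == anchor_family, , drop = FALSE]
  ids <- unique(hit$gene_id)
  if (length(ids) == 0L)
    stop("anchor family '", anchor_family, "' absent from ", genome$genome_id)
  if (length(ids) > 1L)
    stop("anchor family '", anchor_family, "' present more than once in ",
         genome$genome_id, ": ", paste(ids, collapse = ", "))
  rot <- rotate_annotations(ann, genome, anchor_family)
  out_genome <- genome_record(genome$genome_id, rot$sequence,
                              circular = TRUE, supergroup = genome$supergroup,
                              host_taxon = genome$host_taxon,
                              host_order = genome$host_order)
  out_ann <- rbind(rot$annotations, annotations[!mine, , drop = FALSE])
  list(genome = out_genome, annotations = validate_annotations(out_ann))
}

# the actual rotation work: reverse-complement if needed, then rotate, with
# wraparound genes split into two parts sharing gene_id
rotate_annotations <- function(ann, genome, anchor_family) {
  L <- genome_length(genome)
  seqc <- genome$sequence
  hit <- ann[!is.na(ann$family_id) & ann$family_id == anchor_family, , drop = FALSE]
  if (hit$strand[1] == "-") {
    seqc <- revcomp(seqc)
    ns <- L - ann$end
    ann$end <- L - ann$start
    ann$start <- ns
    ann$strand <- ifelse(ann$strand == "+", "-", "+")
    hit <- ann[!is.na(ann$family_id) & ann$family_id == anchor_family, , drop = FALSE]
  }
  r <- min(hit$start)
  if (r > 0L) {
    seqc <- paste0(substr(seqc, r + 1L, L), substr(seqc, 1L, r))
    width <- ann$end - ann$start
    ann$start <- (ann$start - r) %% L
    ann$end <- ann$start + width
    wrap <- ann$end > L
    if (any(wrap)) {
      tailpart <- ann[wrap, , drop = FALSE]
      tailpart$start <- 0L
      tailpart$end <- ann$end[wrap] - L
      ann$end[wrap] <- L
      ann <- rbind(ann, tailpart)
    }
    ann <- ann[order(ann$start), , drop = FALSE]
    rownames(ann) <- NULL
  }
  list(sequence = seqc, annotations = ann)
}

#' GC content of a sequence, in percent
#'
#' N bases are excluded from the denominator.  Strand-invariant.
#'
#' @param sequence Nucleotide string.
#' @return GC percentage in [0,100].
#' @export
gc_content <- function(sequence) {
  f <- Biostrings::letterFrequency(Biostrings::DNAString(sequence),
                                   c("A", "C", "G", "T"))
  denom <- sum(f)
  if (denom == 0) stop("no counted (non-N) bases in sequence")
  100 * (f[["C"]] + f[["G"]]) / denom
}

#' Windowed GC skew profile of a circular genome
#'
#' Per-window skew is (G - C) / (G + C); windows with G + C = 0 are recorded
#' as missing (NA) and excluded from downstream statistics.  Windowing is
#' circular: the final windows wrap across the origin.
#'
#' @param sequence Nucleotide string.
#' @param window,step Window and step size in nt.
#' @return List of class `skew_profile`: `values` (with NA for missing),
#'   `window`, `step`, `n_windows`.
#' @export
skew_profile <- function(sequence, window = 10000L, step = window) {
  L <- nchar(sequence)
  if (window <= 0L) stop("window must be positive")
  if (window > L) stop("window larger than sequence")
  starts <- seq(1L, L, by = step)
  doubled <- Biostrings::DNAString(paste0(sequence, substr(sequence, 1L, window)))
  v <- Biostrings::Views(doubled, start = starts, width = window)
  f <- Biostrings::letterFrequency(v, c("C", "G"))
  gc <- f[, "G"] + f[, "C"]
  vals <- ifelse(gc == 0, NA_real_, (f[, "G"] - f[, "C"]) / gc)
  structure(list(values = as.numeric(vals), window = as.integer(window),
                 step = as.integer(step), n_windows = length(vals)),
            class = "skew_profile")
}

#' Skew index by circular two-arc split maximisation
#'
#' Over all circular two-arc splits (i, j) of the window sequence, computes
#' the fraction of non-missing windows whose skew sign matches the
#' arc-majority pattern (+ on one arc, - on the other); with f* the maximum
#' over splits, the index is 2 * max(f*, 1 - f*) - 1, guaranteed in [0, 1].
#' A genome with perfectly bipartite skew scores 1; sign-incoherent skew
#' scores near 0.  Rotation-invariant and reverse-complement-invariant.
#'
#' @param profile A `skew_profile` (or numeric vector of window skews).
#' @return List of class `skew_index_result`: `skew_index`, `best_split`
#'   (window indices (i, j) of the inferred origin/terminus boundaries).
#' @export
skew_index <- function(profile) {
  vals <- if (inherits(profile, "skew_profile")) profile$values else as.numeric(profile)
  sgn <- sign(vals)
  ok <- !is.na(sgn)
  n_ok <- sum(ok)
  if (n_ok < 4L) stop("need at least 4 non-missing windows")
  W <- length(sgn)
  pos <- as.integer(ok & sgn > 0)
  neg <- as.integer(ok & sgn < 0)
  cpos <- c(0L, cumsum(pos)); cneg <- c(0L, cumsum(neg))
  tpos <- cpos[W + 1L]; tneg <- cneg[W + 1L]
  best <- -1; best_split <- c(1L, 2L)
  # arcs [i, j) and [j, i) on the circle, 1-based window indices
  for (i in seq_len(W)) {
    for (j in seq_len(W)) {
      if (i == j) next
      if (i < j) {
        p1 <- cpos[j] - cpos[i]; n1 <- cneg[j] - cneg[i]
      } else {
        p1 <- tpos - (cpos[i] - cpos[j]); n1 <- tneg - (cneg[i] - cneg[j])
      }
      p2 <- tpos - p1; n2 <- tneg - n1
      f <- max(p1 + n2, n1 + p2) / n_ok
      if (f > best) { best <- f; best_split <- c(i, j) }
    }
  }
  idx <- 2 * max(best, 1 - best) - 1
  structure(list(skew_index = idx, best_split = best_split),
            class = "skew_index_result")
}

#' Per-genome metrics table
#'
#' Convenience wrapper computing length, GC% and skew index for a list of
#' genomes (matching the quantities typically plotted for circular
#' endosymbiont genomes).
#'
#' @param genomes List of `genome_record`s.
#' @param window Skew window size in nt.
#' @return Data frame: genome_id, length, gc_pct, skew_index, supergroup.
#' @export
genome_metrics_table <- function(genomes, window = 10000L) {
  do.call(rbind, lapply(genomes, function(g) {
    w <- min(window, max(1L, genome_length(g) %/% 8L))
    si <- skew_index(skew_profile(g$sequence, window = w))
    data.frame(genome_id = g$genome_id, length = genome_length(g),
               gc_pct = gc_content(g$sequence),
               skew_index = si$skew_index,
               supergroup = g$supergroup, stringsAsFactors = FALSE)
  }))
}
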