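# Pairwise genome comparison without external aligners: unique shared k-mer
# anchors chained into collinear blocks, a breakpoint statistic adjusted for
# aligned length, and fragment-based average nucleotide identity (ANI).
# Designed for the substitution-dominated divergence regime of closely
# related endosymbiont strains; gapped alignment is out of scope.

seq_kmers <- function(sequence, k) {
  L <- nchar(sequence)
  if (k > L) stop("k larger than sequence")
  substring(sequence, 1:(L - k + 1L), k:L)
}

# k-mers unique within a character vector
unique_mask <- function(x) !(duplicated(x) | duplicated(x, fromLast = TRUE))

seq_identity <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  mean(utf8ToInt(a) == utf8ToInt(b))
}

#' Find collinear alignment blocks between two genomes
#'
#' K-mers that occur exactly once in genome A and exactly once across both
#' strands of genome B become anchors.  Anchors sharing a diagonal (forward:
#' posB - posA; reverse: posB + posA) are chained into maximal collinear runs,
#' split where the gap between consecutive anchors exceeds `max_gap`; runs
#' spanning less than `min_block` nt on A are discarded.  Coordinates are
#' 0-based half-open.
#'
#' @param genomeA,genomeB `genome_record`s or plain sequences.
#' @param k Anchor k-mer size.
#' @param min_block Minimum block span on A, nt.
#' @param max_gap Maximum anchor gap within a chain, nt.
#' @return Data frame: a_start, a_end, b_start, b_end, strand, n_anchors,
#'   identity, length.
#' @export
collinear_blocks <- function(genomeA, genomeB, k = 21L, min_block = 500L,
                             max_gap = 2000L) {
  seqA <- if (inherits(genomeA, "genome_record")) genomeA$sequence else genomeA
  seqB <- if (inherits(genomeB, "genome_record")) genomeB$sequence else genomeB
  if (nchar(seqA) < min_block || nchar(seqB) < min_block)
    stop("sequences must be at least min_block long")
  if (k > nchar(seqA) || k > nchar(seqB)) stop("k larger than a genome")
  LB <- nchar(seqB)

  kA <- seq_kmers(seqA, k)
  kBf <- seq_kmers(seqB, k)
  kBr <- seq_kmers(revcomp(seqB), k)
  uA <- unique_mask(kA)
  # uniqueness across both strands of B
  uB <- unique_mask(c(kBf, kBr))
  uBf <- uB[seq_along(kBf)]
  uBr <- uB[length(kBf) + seq_along(kBr)]

  idxA <- which(uA)
  mf <- match(kA[idxA], ifelse(uBf, kBf, NA_character_))
  mr <- match(kA[idxA], ifelse(uBr, kBr, NA_character_))

  blocks <- list()
  add_chains <- function(posA, posB, strand, diag) {
    if (length(posA) == 0L) return()
    o <- order(diag, posA)
    posA <- posA[o]; posB <- posB[o]; diag <- diag[o]
    newgrp <- c(TRUE, diff(diag) != 0 | diff(posA) > max_gap)
    grp <- cumsum(newgrp)
    for (g in unique(grp)) {
      i <- which(grp == g)
      a0 <- posA[i[1]] - 1L; a1 <- posA[i[length(i)]] + k - 1L
      if (a1 - a0 < min_block) next
      if (strand == "+") {
        b0 <- posB[i[1]] - 1L; b1 <- posB[i[length(i)]] + k - 1L
        ident <- seq_identity(substr(seqA, a0 + 1L, a1), substr(seqB, b0 + 1L, b1))
      } else {
        b0 <- posB[i[length(i)]] - 1L; b1 <- posB[i[1]] + k - 1L
        ident <- seq_identity(substr(seqA, a0 + 1L, a1),
                              revcomp(substr(seqB, b0 + 1L, b1)))
      }
      blocks[[length(blocks) + 1L]] <<- data.frame(
        a_start = a0, a_end = a1, b_start = b0, b_end = b1,
        strand = strand, n_anchors = length(i), identity = ident,
        length = a1 - a0, stringsAsFactors = FALSE)
    }
  }

  fwd <- !is.na(mf)
  add_chains(idxA[fwd], mf[fwd], "+", mf[fwd] - idxA[fwd])
  rvs <- !is.na(mr) & !fwd  # unambiguous orientation
  # reverse match position in B coordinates: revcomp index i covers
  # B[LB - i - k + 2 .. LB - i + 1]
  posB_rev <- LB - mr[rvs] - k + 2L
  add_chains(idxA[rvs], posB_rev, "-", posB_rev + idxA[rvs])

  out <- if (length(blocks) > 0L) do.call(rbind, blocks) else
    data.frame(a_start = integer(), a_end = integer(), b_start = integer(),
               b_end = integer(), strand = character(), n_anchors = integer(),
               identity = numeric(), length = integer(),
               stringsAsFactors = FALSE)
  out <- out[order(out$a_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Breakpoint statistics from collinear blocks
#'
#' Blocks are ordered along genome A (overlaps trimmed at the overlap
#' midpoint); a breakpoint is counted between consecutive blocks whose B
#' coordinates are not contiguous with the same orientation within
#' `tolerance` nt.  For circular genomes the junction between the last and
#' first block is included and B-gaps are taken modulo the B length.  The
#' rate is breakpoints per alignable base on A.
#'
#' @param blocks Data frame from [collinear_blocks()].
#' @param genome_lengths Integer pair c(lengthA, lengthB).
#' @param circular Logical: treat both genomes as circular.
#' @param tolerance Contiguity tolerance in nt.
#' @return List of class `breakpoint_stats`: n_blocks, n_breakpoints,
#'   alignable_length, breakpoint_rate.
#' @export
breakpoint_stats <- function(blocks, genome_lengths, circular = TRUE,
                             tolerance = 1000L) {
  if (nrow(blocks) == 0L)
    stop("no alignment blocks: breakpoint rate undefined")
  LB <- genome_lengths[2]
  b <- blocks[order(blocks$a_start), , drop = FALSE]
  # trim overlaps on A at the midpoint of the overlap
  if (nrow(b) > 1L) {
    for (i in seq_len(nrow(b) - 1L)) {
      ov <- b$a_end[i] - b$a_start[i + 1L]
      if (ov > 0L) {
        mid <- b$a_start[i + 1L] + ov %/% 2L
        b$a_end[i] <- mid
        b$a_start[i + 1L] <- mid
      }
    }
    b <- b[b$a_end > b$a_start, , drop = FALSE]
  }
  n <- nrow(b)
  junctions <- if (circular) cbind(seq_len(n), c(seq_len(n)[-1], 1L)) else
    if (n > 1L) cbind(seq_len(n - 1L), seq(2L, n)) else
      matrix(integer(), ncol = 2)
  wrap_gap <- function(g) {
    if (!circular) return(g)
    g <- g %% LB
    ifelse(g > LB / 2, g - LB, g)
  }
  n_bp <- 0L
  if (nrow(junctions) > 0L) for (r in seq_len(nrow(junctions))) {
    i <- junctions[r, 1]; j <- junctions[r, 2]
    agap <- if (circular && j == 1L && i == n)
      (b$a_start[j] - b$a_end[i]) %% genome_lengths[1] else
        b$a_start[j] - b$a_end[i]
    contiguous <- FALSE
    if (b$strand[i] == b$strand[j]) {
      bgap <- if (b$strand[i] == "+") b$b_start[j] - b$b_end[i] else
        b$b_start[i] - b$b_end[j]
      contiguous <- abs(wrap_gap(bgap) - agap) <= tolerance
    }
    if (!contiguous) n_bp <- n_bp + 1L
  }
  alignable <- sum(b$a_end - b$a_start)
  structure(list(n_blocks = n, n_breakpoints = n_bp,
                 alignable_length = alignable,
                 breakpoint_rate = n_bp / alignable),
            class = "breakpoint_stats")
}

#' Fragment-based average nucleotide identity
#'
#' Genome A is cut into non-overlapping fragments; each fragment is mapped to
#' genome B by a shared-k-mer vote for the best offset (both orientations),
#' followed by ungapped comparison at that offset.  Fragments with identity at
#' or above `min_identity_to_count` count as mapped; ANI is the mean identity
#' of mapped fragments and `aligned_fraction` the mapped proportion.
#'
#' @param genomeA,genomeB `genome_record`s or sequences.
#' @param fragment Fragment length, nt.
#' @param k Vote k-mer size.
#' @param min_identity_to_count Identity threshold (percent) for a fragment
#'   to count as mapped.
#' @return List of class `ani_result`: ani, aligned_fraction,
#'   n_fragments_mapped, n_fragments_total.
#' @export
fragment_ani <- function(genomeA, genomeB, fragment = 1000L, k = 16L,
                         min_identity_to_count = 70) {
  seqA <- if (inherits(genomeA, "genome_record")) genomeA$sequence else genomeA
  seqB <- if (inherits(genomeB, "genome_record")) genomeB$sequence else genomeB
  LA <- nchar(seqA); LB <- nchar(seqB)
  if (LA < fragment) stop("genome A shorter than one fragment")
  seqBr <- revcomp(seqB)
  kB <- seq_kmers(seqB, k)
  kBr <- seq_kmers(seqBr, k)

  n_frag <- LA %/% fragment
  idents <- rep(NA_real_, n_frag)
  for (fi in seq_len(n_frag)) {
    fs <- (fi - 1L) * fragment
    frag <- substr(seqA, fs + 1L, fs + fragment)
    kF <- seq_kmers(frag, k)
    best <- best_offset_identity(frag, kF, seqB, kB)
    bestr <- best_offset_identity(frag, kF, seqBr, kBr)
    idents[fi] <- max(best, bestr, na.rm = TRUE)
  }
  idents[!is.finite(idents)] <- 0
  mapped <- idents * 100 >= min_identity_to_count
  if (!any(mapped)) stop("no fragments mapped: ANI undefined")
  structure(list(ani = 100 * mean(idents[mapped]),
                 aligned_fraction = mean(mapped),
                 n_fragments_mapped = sum(mapped),
                 n_fragments_total = n_frag),
            class = "ani_result")
}

# identity of frag against target at the k-mer-vote modal offset; -Inf when
# no shared k-mer
best_offset_identity <- function(frag, kF, target, kT) {
  m <- match(kF, kT)
  hit <- !is.na(m)
  if (!any(hit)) return(-Inf)
  offs <- m[hit] - which(hit)  # target start of frag would be offs + 1
  tab <- table(offs)
  off <- as.integer(names(tab)[which.max(tab)])
  L <- nchar(target); fl <- nchar(frag)
  t0 <- off  # 0-based start in target
  # clamp to target bounds, compare the overlapping part, uncovered bases
  # count as mismatches
  s0 <- max(0L, -t0)
  e0 <- min(fl, L - t0)
  if (e0 <= s0) return(-Inf)
  a <- substr(frag, s0 + 1L, e0)
  b <- substr(target, t0 + s0 + 1L, t0 + e0)
  sum(utf8ToInt(a) == utf8ToInt(b)) / fl
}

#' All-vs-all comparison table
#'
#' Runs [fragment_ani()] and [collinear_blocks()] + [breakpoint_stats()] for
#' every ordered genome pair and returns a long-format table.
#'
#' @param genomes List of `genome_record`s.
#' @param ... Passed to the underlying operations.
#' @return Data frame: genome_a, genome_b, ani, aligned_fraction, n_blocks,
#'   n_breakpoints, breakpoint_rate.
#' @export
compare_all <- function(genomes, ...) {
  ids <- vapply(genomes, `[[`, character(1), "genome_id")
  out <- list()
  for (i in seq_along(genomes)) for (j in seq_along(genomes)) {
    if (i >= j) next
    ani <- fragment_ani(genomes[[i]], genomes[[j]])
    blk <- collinear_blocks(genomes[[i]], genomes[[j]], ...)
    bp <- breakpoint_stats(blk, c(genome_length(genomes[[i]]),
                                  genome_length(genomes[[j]])),
                           circular = genomes[[i]]$circular &&
                             genomes[[j]]$circular)
    out[[length(out) + 1L]] <- data.frame(
      genome_a = ids[i], genome_b = ids[j], ani = ani$ani,
      aligned_fraction = ani$aligned_fraction, n_blocks = bp$n_blocks,
      n_breakpoints = bp$n_breakpoints, breakpoint_rate = bp$breakpoint_rate,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
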