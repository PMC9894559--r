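# Synthetic strain sets with planted ground truth.  The generator emulates a
# clade of small circular endosymbiont genomes: origin-anchored GC skew,
# core/accessory gene families evolving on a birth tree, multi-module WO-like
# prophage insertions, adjacent CifA/CifB toxin-antitoxin pairs, a six-gene
# biotin operon, and host genomes carrying endosymbiont nuclear insertions
# (NUWTs).  Substitutions only by default, so anchor-based comparisons have
# exact expectations.

PHAGE_MODULE_SIZES <- c(head = 6L, baseplate = 8L, tail = 6L, fibre = 6L)
BIOTIN_ORDER <- c("bioA", "bioD", "bioC", "bioH", "bioF", "bioB")

random_skewed_sequence <- function(length, gc = 0.35, skew_amplitude = 0) {
  # origin at position 0, terminus at length/2; leading strand (first half)
  # G-enriched, lagging strand C-enriched
  half <- floor(length / 2)
  at <- (1 - gc) / 2
  pg1 <- gc / 2 * (1 + skew_amplitude); pc1 <- gc / 2 * (1 - skew_amplitude)
  first <- sample(c("A", "C", "G", "T"), half, replace = TRUE,
                  prob = c(at, pc1, pg1, at))
  second <- sample(c("A", "C", "G", "T"), length - half, replace = TRUE,
                   prob = c(at, pg1, pc1, at))
  c(first, second)
}

mutate_sequence <- function(chars, p_sub) {
  if (p_sub <= 0) return(chars)
  n <- length(chars)
  k <- stats::rbinom(1, n, min(p_sub, 1))
  if (k == 0L) return(chars)
  idx <- sample.int(n, k)
  alphabet <- c("A", "C", "G", "T")
  repl <- vapply(chars[idx],
                 function(b) sample(setdiff(alphabet, b), 1L), character(1))
  chars[idx] <- repl
  chars
}

# choose an insertion point inside an intergenic gap of one genome's
# annotation table.  Two exclusion rules keep planted features recoverable:
# gaps within margin_genes (gene-order, circular) of a phage-tagged gene are
# excluded so prophage runs never merge or gain extra intervening genes, and
# gaps strictly inside a non-phage feature block (between two adjacent
# cif/bio/transposase genes) are excluded so pairs and operons stay intact.
PHAGE_TAGS <- c("head", "baseplate", "tail", "fibre", "phage_linked")
BLOCK_TAGS <- c("cifA", "cifB", "bioA", "bioB", "bioC", "bioD", "bioF",
                "bioH", "transposase")

pick_insertion_point <- function(ann, genome_len, margin_genes = 6L) {
  if (nrow(ann) == 0L) return(sample.int(genome_len, 1L) - 1L)
  ann <- ann[order(ann$start), , drop = FALSE]
  n <- nrow(ann)
  excluded <- rep(FALSE, n + 1L)  # gap i sits after gene i; gap 0 leads
  gap_idx <- 0:n
  for (f in which(has_any_tag(ann, PHAGE_TAGS))) {
    d <- pmin((gap_idx - f) %% n, (f - gap_idx) %% n)
    excluded[d <= margin_genes] <- TRUE
  }
  blocky <- which(has_any_tag(ann, BLOCK_TAGS))
  # gaps touching a block gene: inserting there could split a pair/operon or
  # create a spurious adjacency with a planted pair
  excluded[unique(c(blocky, blocky + 1L))] <- TRUE
  gaps_start <- c(0L, ann$end)
  gaps_end <- c(ann$start, genome_len)
  ok <- gaps_end - gaps_start >= 2L & !excluded
  if (!any(ok)) stop("no intergenic gap left for insertion")
  w <- (gaps_end - gaps_start)[ok]
  g <- sample(sum(ok), 1L, prob = w)
  gs <- gaps_start[ok][g]; ge <- gaps_end[ok][g]
  gs + sample.int(ge - gs - 1L, 1L)
}

# build one prophage block: structural module genes (optionally with slots
# missing), interleaved cargo genes, returning sequence + local annotations +
# truth tallies
build_prophage_block <- function(genome_id, block_id, n_missing, n_cargo,
                                 with_cif, cif_type,
                                 gene_len = 500L, gap = 50L, gc = 0.35) {
  slots <- unlist(lapply(names(PHAGE_MODULE_SIZES), function(m)
    paste0("phage_", m, "_", seq_len(PHAGE_MODULE_SIZES[[m]]))), use.names = FALSE)
  modules <- rep(names(PHAGE_MODULE_SIZES), PHAGE_MODULE_SIZES)
  if (n_missing > 0L) {
    drop <- sample(length(slots), min(n_missing, length(slots) - 1L))
    slots <- slots[-drop]; modules <- modules[-drop]
  }
  genes <- data.frame(family_id = slots, tags = modules,
                      stringsAsFactors = FALSE)
  # cargo genes (and optionally a cif pair) are placed in the interior of the
  # structural run; the number of consecutive non-phage genes never exceeds
  # the scanner's default gap of 5
  cargo <- NULL
  if (n_cargo > 0L) {
    cargo <- data.frame(
      family_id = paste0("eam_", block_id, "_", seq_len(n_cargo)),
      tags = sample(c("other", "transposase"), n_cargo, replace = TRUE),
      stringsAsFactors = FALSE)
  }
  if (with_cif) {
    cargo <- rbind(cargo, data.frame(
      family_id = c(paste0("cifA_t", cif_type), paste0("cifB_t", cif_type)),
      tags = c("cifA", "cifB"), stringsAsFactors = FALSE))
  }
  if (!is.null(cargo) && nrow(cargo) > 0L) {
    if (nrow(cargo) > 5L) cargo <- cargo[seq_len(5L), , drop = FALSE]
    at <- sample(seq_len(nrow(genes) - 1L), 1L)  # between structural genes
    genes <- rbind(genes[seq_len(at), ], cargo,
                   genes[seq(at + 1L, nrow(genes)), ])
  }
  n <- nrow(genes)
  starts <- cumsum(c(0L, rep(gene_len + gap, n - 1L)))
  seq_len_total <- starts[n] + gene_len
  ann <- data.frame(
    genome_id = genome_id,
    gene_id = paste0(genome_id, "_", block_id, "_g", seq_len(n)),
    start = starts, end = starts + gene_len,
    strand = sample(c("+", "-"), n, replace = TRUE),
    family_id = genes$family_id, tags = genes$tags,
    stringsAsFactors = FALSE)
  tally <- vapply(names(PHAGE_MODULE_SIZES), function(m)
    length(unique(genes$family_id[genes$tags == m])), integer(1))
  list(sequence = paste(sample(c("A", "C", "G", "T"), seq_len_total,
                               replace = TRUE,
                               prob = c(0.325, gc / 2, gc / 2, 0.325)),
                        collapse = ""),
       annotations = ann, tally = tally,
       complete = tally["head"] >= 5L && tally["baseplate"] >= 7L &&
         tally["fibre"] >= 5L && tally["tail"] >= 5L)
}

build_gene_pair_block <- function(genome_id, block_id, fams, tags,
                                  gene_len = 400L, gap = 40L, gc = 0.35) {
  n <- length(fams)
  starts <- cumsum(c(0L, rep(gene_len + gap, n - 1L)))
  total <- starts[n] + gene_len
  ann <- data.frame(
    genome_id = genome_id,
    gene_id = paste0(genome_id, "_", block_id, "_g", seq_len(n)),
    start = starts, end = starts + gene_len,
    strand = rep(sample(c("+", "-"), 1L), n),
    family_id = fams, tags = tags, stringsAsFactors = FALSE)
  list(sequence = paste(sample(c("A", "C", "G", "T"), total, replace = TRUE,
                               prob = c(0.325, gc / 2, gc / 2, 0.325)),
                        collapse = ""),
       annotations = ann)
}

insert_block <- function(sequence, ann, pos, block) {
  blen <- nchar(block$sequence)
  newseq <- paste0(substr(sequence, 1L, pos),
                   block$sequence,
                   substr(sequence, pos + 1L, nchar(sequence)))
  shift <- ann$start >= pos
  ann$start[shift] <- ann$start[shift] + blen
  ann$end[shift] <- ann$end[shift] + blen
  bann <- block$annotations
  bann$start <- bann$start + pos
  bann$end <- bann$end + pos
  list(sequence = newseq, annotations = rbind(ann, bann),
       block_span = c(pos, pos + blen), block_gene_ids = bann$gene_id)
}

#' Generate a synthetic endosymbiont strain set with planted ground truth
#'
#' Genomes are evolved along a random birth tree by per-site substitution from
#' a common backbone carrying an origin-anchored GC skew (sign switching at
#' position 0 and at the genome midpoint).  Gene content comprises a core set
#' (present in every strain, constant coordinates), accessory families gained
#' and lost along branches, and per-strain novel genes.  WO-like prophages are
#' inserted as blocks containing the four structural modules (6 head, 8
#' baseplate, 6 tail, 6 fibre family slots) with a configurable number of
#' missing genes; CifA/CifB pairs are planted adjacent, a configurable
#' fraction of them inside prophage spans; a six-gene biotin operon is planted
#' with configurable presence and transposase disruption.  Everything planted
#' is recorded in the returned truth tables.
#'
#' Defaults emulate the published clade: ~1.3 Mb backbones (prophage
#' insertions grow them towards ~1.5 Mb), 35% GC, up to a few percent pairwise
#' divergence, on average ~1.7 Cif pairs per genome with 70% inside prophage,
#' biotin operon in ~6% of strains, ~19 novel genes per strain.
#'
#' @param n_genomes Number of strains (>= 2).
#' @param genome_length Backbone length in nt before insertions.
#' @param core_fraction Fraction of backbone gene slots in the core set.
#' @param accessory_rate Per-unit-branch-length gain/loss rate of accessory
#'   families.
#' @param n_prophages_range Integer pair; per-genome prophage count is drawn
#'   uniformly from this range.
#' @param cif_pair_rate Mean number of Cif pairs per genome (Poisson).
#' @param cif_in_prophage_fraction Probability that a Cif pair is planted
#'   inside a prophage span rather than on the backbone.
#' @param biotin_prob Probability a strain carries the biotin operon.
#' @param biotin_disrupt_prob Probability a planted operon is disrupted by a
#'   transposase insertion.
#' @param skew_amplitude GC-skew composition bias amplitude in [0,1].
#' @param mutation_rate Expected substitutions per site from root to the
#'   deepest tip.
#' @param novel_gene_mean Mean number of strain-specific novel genes.
#' @param gene_length,intergenic Backbone gene slot geometry in nt.
#' @param prophage_missing_max Maximum number of structural slots missing per
#'   planted prophage (0 forces intact prophages).
#' @param prophage_cargo_max Maximum number of non-Cif cargo genes per
#'   prophage.
#' @param gc Backbone GC fraction.
#' @param seed Mandatory integer seed.
#' @return A list with `genomes` (list of [genome_record]s), `annotations`
#'   (one `gene_annotations` data frame covering all genomes), and `truth`
#'   (tree, prophage/Cif/biotin truth tables, family matrix, parameters).
#' @export
generate_strain_set <- function(n_genomes,
                                genome_length = 1.3e6,
                                core_fraction = 0.8,
                                accessory_rate = 0.3,
                                n_prophages_range = c(0L, 4L),
                                cif_pair_rate = 1.7,
                                cif_in_prophage_fraction = 0.7,
                                biotin_prob = 0.06,
                                biotin_disrupt_prob = 0.3,
                                skew_amplitude = 0.1,
                                mutation_rate = 0.02,
                                novel_gene_mean = 19,
                                gene_length = 900L,
                                intergenic = 100L,
                                prophage_missing_max = 4L,
                                prophage_cargo_max = 3L,
                                gc = 0.35,
                                seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (n_genomes < 2L) stop("n_genomes must be >= 2")
  stopifnot(length(n_prophages_range) == 2L,
            n_prophages_range[1] <= n_prophages_range[2])
  set.seed(seed)
  genome_length <- as.integer(genome_length)

  ids <- sprintf("g%02d", seq_len(n_genomes))
  tree <- ape::rphylo(n_genomes, birth = 1, death = 0)
  tree$tip.label <- ids
  depth <- max(ape::node.depth.edgelength(tree))
  if (depth > 0) tree$edge.length <- tree$edge.length / depth

  # backbone gene slots (constant layout across strains; substitutions only)
  usable <- floor(genome_length * 0.9)
  n_slots <- max(2L, (usable - intergenic) %/% (gene_length + intergenic))
  slot_start <- (seq_len(n_slots) - 1L) * (gene_length + intergenic)
  slot_strand <- sample(c("+", "-"), n_slots, replace = TRUE)
  slot_strand[1] <- "+"  # origin anchor on the forward strand
  n_core <- max(1L, round(core_fraction * n_slots))
  core_slots <- c(1L, if (n_core > 1L) 1L + sample(n_slots - 1L, n_core - 1L))
  slot_family <- paste0("OG", sprintf("%06d", seq_len(n_slots)))
  slot_family[1] <- "hemE"  # replication-origin anchor family
  is_core <- seq_len(n_slots) %in% core_slots

  # accessory presence/absence evolves by per-branch gain/loss on the tree
  ntip <- n_genomes
  nnode <- tree$Nnode
  root <- ntip + 1L
  edge <- tree$edge
  elen <- tree$edge.length
  edge_order <- order(edge[, 1])  # parent-before-child under rphylo numbering
  presence <- matrix(FALSE, nrow = n_slots, ncol = ntip + nnode)
  presence[, root] <- is_core | (stats::runif(n_slots) < 0.6)
  for (i in edge_order) {
    par <- edge[i, 1]; chi <- edge[i, 2]
    st <- presence[, par]
    flip <- !is_core & (stats::runif(n_slots) < 1 - exp(-accessory_rate * elen[i]))
    st[flip] <- !st[flip]
    st[is_core] <- TRUE
    presence[, chi] <- st
  }

  # evolve backbone sequences down the tree
  rootseq <- random_skewed_sequence(genome_length, gc = gc,
                                    skew_amplitude = skew_amplitude)
  seqs <- vector("list", ntip + nnode)
  seqs[[root]] <- rootseq
  for (i in edge_order) {
    p_sub <- mutation_rate * elen[i]
    seqs[[edge[i, 2]]] <- mutate_sequence(seqs[[edge[i, 1]]], p_sub)
  }

  genomes <- list(); all_ann <- list()
  prophage_truth <- list(); cif_truth <- list(); biotin_truth <- list()
  supergroups <- sample(c("A", "B"), n_genomes, replace = TRUE)

  for (t in seq_len(ntip)) {
    gid <- ids[t]
    present <- which(presence[, t])
    ann <- data.frame(
      genome_id = gid,
      gene_id = paste0(gid, "_s", sprintf("%04d", present)),
      start = slot_start[present], end = slot_start[present] + gene_length,
      strand = slot_strand[present],
      family_id = slot_family[present],
      tags = "other",
      stringsAsFactors = FALSE)

    # strain-specific novel genes occupy empty accessory slots
    absent <- setdiff(seq_len(n_slots), present)
    k_novel <- min(stats::rpois(1, novel_gene_mean), length(absent))
    if (k_novel > 0L) {
      nv <- sample(absent, k_novel)
      ann <- rbind(ann, data.frame(
        genome_id = gid,
        gene_id = paste0(gid, "_n", sprintf("%04d", nv)),
        start = slot_start[nv], end = slot_start[nv] + gene_length,
        strand = slot_strand[nv],
        family_id = paste0("NOV_", gid, "_", sprintf("%04d", nv)),
        tags = "other", stringsAsFactors = FALSE))
    }

    sequence <- paste(seqs[[t]], collapse = "")

    # planted prophages
    n_p <- n_prophages_range[1] +
      sample.int(n_prophages_range[2] - n_prophages_range[1] + 1L, 1L) - 1L
    n_cif <- stats::rpois(1, cif_pair_rate)
    cif_in_phage <- if (n_cif > 0L)
      stats::runif(n_cif) < cif_in_prophage_fraction else logical(0)
    # at most one pair per prophage block; surplus inside-draws fall outside
    n_cif_inside <- min(sum(cif_in_phage), n_p)
    cif_idx_inside <- utils::head(which(cif_in_phage), n_cif_inside)
    cif_host_block <- if (n_cif_inside > 0L)
      sample(n_p, n_cif_inside) else integer(0)
    cif_types <- if (n_cif > 0L)
      sample(c("I", "II", "III", "IV", "V"), n_cif, replace = TRUE) else character(0)

    for (b in seq_len(n_p)) {
      withcif <- b %in% cif_host_block
      # at most one cif pair per block (extra inside-draws fall back outside)
      cidx <- if (withcif) cif_idx_inside[match(b, cif_host_block)] else NA_integer_
      n_missing <- if (prophage_missing_max > 0L)
        sample(0:prophage_missing_max, 1L) else 0L
      n_cargo <- sample(0:min(prophage_cargo_max, if (withcif) 3L else 5L), 1L)
      blk <- build_prophage_block(gid, paste0("ph", b), n_missing, n_cargo,
                                  withcif, if (withcif) cif_types[cidx] else "",
                                  gc = gc)
      pos <- pick_insertion_point(ann, nchar(sequence))
      ins <- insert_block(sequence, ann, pos, blk)
      sequence <- ins$sequence; ann <- ins$annotations
      # shift previously recorded feature spans downstream of pos
      blen <- diff(ins$block_span)
      shift_spans <- function(lst) lapply(lst, function(r) {
        if (r$genome_id == gid && r$start >= pos) {
          r$start <- r$start + blen; r$end <- r$end + blen
        }
        r
      })
      prophage_truth <- shift_spans(prophage_truth)
      cif_truth <- shift_spans(cif_truth)
      biotin_truth <- shift_spans(biotin_truth)
      bann <- ann[ann$gene_id %in% ins$block_gene_ids, ]
      phg <- bann[has_any_tag(bann, c(names(PHAGE_MODULE_SIZES), "phage_linked")), ]
      prophage_truth[[length(prophage_truth) + 1L]] <- list(
        genome_id = gid, region_id = paste0(gid, "_ph", b),
        start = min(phg$start), end = max(phg$end),
        head = unname(blk$tally["head"]), baseplate = unname(blk$tally["baseplate"]),
        tail = unname(blk$tally["tail"]), fibre = unname(blk$tally["fibre"]),
        complete = blk$complete)
      if (withcif) {
        cp <- bann[has_any_tag(bann, c("cifA", "cifB")), ]
        cif_truth[[length(cif_truth) + 1L]] <- list(
          genome_id = gid, start = min(cp$start), end = max(cp$end),
          type = cif_types[cidx], in_prophage = TRUE)
      }
    }

    # cif pairs outside prophage (plus inside-draws without a host block)
    outside <- setdiff(seq_len(n_cif), cif_idx_inside)
    for (ci in outside) {
      blk <- build_gene_pair_block(gid, paste0("cif", ci),
                                   fams = paste0(c("cifA_t", "cifB_t"), cif_types[ci]),
                                   tags = c("cifA", "cifB"), gc = gc)
      pos <- pick_insertion_point(ann, nchar(sequence))
      ins <- insert_block(sequence, ann, pos, blk)
      sequence <- ins$sequence; ann <- ins$annotations
      blen <- diff(ins$block_span)
      shift_spans <- function(lst) lapply(lst, function(r) {
        if (r$genome_id == gid && r$start >= pos) {
          r$start <- r$start + blen; r$end <- r$end + blen
        }
        r
      })
      prophage_truth <- shift_spans(prophage_truth)
      cif_truth <- shift_spans(cif_truth)
      biotin_truth <- shift_spans(biotin_truth)
      cif_truth[[length(cif_truth) + 1L]] <- list(
        genome_id = gid, start = ins$block_span[1],
        end = ins$block_span[2], type = cif_types[ci], in_prophage = FALSE)
    }

    # biotin operon
    if (stats::runif(1) < biotin_prob) {
      disrupted <- stats::runif(1) < biotin_disrupt_prob
      fams <- BIOTIN_ORDER; tags <- BIOTIN_ORDER
      if (disrupted) {
        at <- sample(2:5, 1L)
        fams <- append(fams, paste0("tnp_", gid), after = at)
        tags <- append(tags, "transposase", after = at)
      }
      blk <- build_gene_pair_block(gid, "bio", fams = fams, tags = tags, gc = gc)
      pos <- pick_insertion_point(ann, nchar(sequence))
      ins <- insert_block(sequence, ann, pos, blk)
      sequence <- ins$sequence; ann <- ins$annotations
      blen <- diff(ins$block_span)
      shift_spans <- function(lst) lapply(lst, function(r) {
        if (r$genome_id == gid && r$start >= pos) {
          r$start <- r$start + blen; r$end <- r$end + blen
        }
        r
      })
      prophage_truth <- shift_spans(prophage_truth)
      cif_truth <- shift_spans(cif_truth)
      biotin_truth[[length(biotin_truth) + 1L]] <- list(
        genome_id = gid, start = ins$block_span[1], end = ins$block_span[2],
        present = TRUE, disrupted = disrupted)
    }

    if (any(ann$end > nchar(sequence)))
      stop("planted feature exceeds genome length in ", gid)
    ann <- ann[order(ann$start), ]
    rownames(ann) <- NULL
    genomes[[t]] <- genome_record(gid, sequence, circular = TRUE,
                                  supergroup = supergroups[t])
    all_ann[[t]] <- ann
  }

  annotations <- validate_annotations(do.call(rbind, all_ann))
  fam <- family_matrix_from_annotations(annotations, genome_ids = ids)

  as_df <- function(lst) if (length(lst) == 0L) NULL else
    do.call(rbind, lapply(lst, function(x) as.data.frame(x, stringsAsFactors = FALSE)))

  list(genomes = genomes,
       annotations = annotations,
       truth = list(
         tree = tree,
         prophages = as_df(prophage_truth),
         cif_pairs = as_df(cif_truth),
         biotin = as_df(biotin_truth),
         family_matrix = fam,
         origin = 0L,
         seed = seed))
}

#' Apply random inversions and transpositions to a genome
#'
#' Segment bounds are drawn away from each other by at least `min_segment`.
#' The true breakpoint count is the number of adjacencies of the original
#' (circular) genome that are broken in the derived genome, computed from the
#' signed segment permutation.
#'
#' @param genome A `genome_record`.
#' @param n_inversions,n_transpositions Non-negative operation counts.
#' @param seed Integer seed.
#' @param min_segment Minimum distance between cut points, nt.
#' @return List with `genome` (derived record), `n_breakpoints` (true count),
#'   and `pieces` (the signed segment layout in original coordinates).
#' @export
apply_rearrangements <- function(genome, n_inversions, n_transpositions, seed,
                                 min_segment = 5000L) {
  if (n_inversions < 0L || n_transpositions < 0L)
    stop("operation counts must be >= 0")
  set.seed(seed)
  L <- genome_length(genome)
  if (3L * min_segment >= L) stop("genome too short for min_segment")
  pieces <- data.frame(start = 0L, end = L, strand = "+",
                       stringsAsFactors = FALSE)

  piece_lengths <- function(p) p$end - p$start
  # split the piece list at derived-coordinate position pos
  cut_at <- function(p, pos) {
    cum <- cumsum(piece_lengths(p))
    offs <- c(0L, cum[-length(cum)])
    i <- which(pos > offs & pos < cum)
    if (length(i) == 0L) return(p)  # already a boundary
    within <- pos - offs[i]
    a <- p[i, ]; b <- p[i, ]
    if (a$strand == "+") {
      a$end <- a$start + within; b$start <- a$end
    } else {
      a$start <- a$end - within; b$end <- a$start
    }
    rbind(p[seq_len(i - 1L), ], a, b, p[seq(i + 1L, length.out = nrow(p) - i), ])
  }
  piece_index_range <- function(p, p1, p2) {
    cum <- cumsum(piece_lengths(p))
    offs <- c(0L, cum[-length(cum)])
    which(offs >= p1 & cum <= p2)
  }
  flip <- function(p) {
    p <- p[rev(seq_len(nrow(p))), , drop = FALSE]
    p$strand <- ifelse(p$strand == "+", "-", "+")
    p
  }

  # circular distance of positions to the nearest existing piece boundary;
  # keeping every cut min_segment away from all previous boundaries makes
  # each derived junction an unambiguous, well-separated breakpoint
  clear_of_boundaries <- function(pos, bounds, len) {
    d <- vapply(pos, function(p) min(abs(p - bounds),
                                     len - abs(p - bounds)), numeric(1))
    all(d >= min_segment)
  }

  ops <- sample(c(rep("inv", n_inversions), rep("tra", n_transpositions)))
  for (op in ops) {
    bounds <- c(0L, cumsum(piece_lengths(pieces)))
    for (try in 1:500) {
      cuts <- sort(sample.int(L - 1L, 2L))
      p1 <- cuts[1]; p2 <- cuts[2]
      ok <- (p2 - p1) >= min_segment && (L - (p2 - p1)) >= min_segment &&
        clear_of_boundaries(cuts, bounds, L)
      if (ok) break
      if (try == 500L) stop("could not draw segment bounds; reduce min_segment or operation count")
    }
    pieces <- cut_at(pieces, p1)
    pieces <- cut_at(pieces, p2)
    idx <- piece_index_range(pieces, p1, p2)
    mid <- pieces[idx, , drop = FALSE]
    rest <- pieces[-idx, , drop = FALSE]
    if (op == "inv") {
      before <- pieces[seq_len(min(idx) - 1L), , drop = FALSE]
      after <- pieces[seq(max(idx) + 1L, length.out = nrow(pieces) - max(idx)), ,
                      drop = FALSE]
      pieces <- rbind(before, flip(mid), after)
    } else {
      # transposition: reinsert the excised segment at a cut of the remaining
      # pieces, away from all existing boundaries (so never back in place)
      rbounds <- c(0L, cumsum(piece_lengths(rest)))
      rlen <- L - (p2 - p1)
      for (try in 1:500) {
        target_pos <- sample.int(rlen - 1L, 1L)
        if (clear_of_boundaries(target_pos, rbounds, rlen)) break
        if (try == 500L) stop("could not place transposed segment")
      }
      rest <- cut_at(rest, target_pos)
      cumr <- cumsum(piece_lengths(rest))
      offs <- c(0L, cumr[-length(cumr)])
      j <- which(offs == target_pos)
      if (length(j) == 0L) j <- nrow(rest) + 1L
      pieces <- rbind(rest[seq_len(j - 1L), , drop = FALSE], mid,
                      rest[seq(j, length.out = nrow(rest) - j + 1L), ,
                           drop = FALSE])
    }
    rownames(pieces) <- NULL
  }

  n_bp <- count_broken_adjacencies(pieces, L, circular = genome$circular)

  seqs <- mapply(function(s, e, st) {
    sub <- substr(genome$sequence, s + 1L, e)
    if (st == "-") revcomp(sub) else sub
  }, pieces$start, pieces$end, pieces$strand)
  derived <- genome_record(paste0(genome$genome_id, "_rearr"),
                           paste(seqs, collapse = ""),
                           circular = genome$circular,
                           supergroup = genome$supergroup)
  list(genome = derived, n_breakpoints = n_bp, pieces = pieces)
}

# count original adjacencies broken in the derived piece layout
count_broken_adjacencies <- function(pieces, L, circular = TRUE) {
  n <- nrow(pieces)
  if (n == 1L) {
    if (!circular) return(0L)
    p <- pieces[1, ]
    ok <- (p$strand == "+" && p$start == 0L && p$end == L) ||
      (p$strand == "-" && p$start == 0L && p$end == L)
    return(if (ok) 0L else 1L)
  }
  idx <- if (circular) cbind(seq_len(n), c(seq_len(n)[-1], 1L)) else
    cbind(seq_len(n - 1L), seq(2L, n))
  broken <- 0L
  for (r in seq_len(nrow(idx))) {
    a <- pieces[idx[r, 1], ]; b <- pieces[idx[r, 2], ]
    contig <-
      (a$strand == "+" && b$strand == "+" &&
         (a$end == b$start || (circular && a$end == L && b$start == 0L))) ||
      (a$strand == "-" && b$strand == "-" &&
         (b$end == a$start || (circular && b$end == L && a$start == 0L)))
    if (!contig) broken <- broken + 1L
  }
  broken
}

#' Simulate error-free long reads from a host + endosymbiont mixture
#'
#' NUWT spans (endosymbiont-derived blocks) are copied into the host sequence
#' at random positions before sampling.  Reads are sampled uniformly from the
#' circularised sequences at the requested fold-coverages; read counts are
#' Poisson around depth x length / read_length.  Host-derived reads that
#' overlap an inserted NUWT block are labelled `nuwt`.
#'
#' @param host_genome,endosymbiont_genome `genome_record`s.
#' @param nuwt_spans Data frame with `start`,`end` (0-based half-open spans of
#'   the endosymbiont genome to copy into the host), or NULL.
#' @param host_depth,endo_depth Requested mean fold-coverage (>= 0).
#' @param read_length_mean Read length in nt (fixed; HiFi-like, error-free).
#' @param seed Integer seed.
#' @return List with `reads` (data frame: read_id, sequence, source in
#'   \{host, endosymbiont, nuwt\}, ref, start, end), `depths`, and
#'   `nuwt_spans_host` (where blocks landed in the augmented host).
#' @export
simulate_reads <- function(host_genome, endosymbiont_genome, nuwt_spans = NULL,
                           host_depth, endo_depth, read_length_mean = 12000L,
                           seed) {
  if (host_depth < 0 || endo_depth < 0) stop("depths must be >= 0")
  set.seed(seed)
  rl <- as.integer(read_length_mean)

  host_seq <- host_genome$sequence
  nuwt_host <- NULL
  if (!is.null(nuwt_spans) && nrow(nuwt_spans) > 0L) {
    spans <- nuwt_spans[order(nuwt_spans$start), , drop = FALSE]
    placed <- list()
    for (i in seq_len(nrow(spans))) {
      blk <- substr(endosymbiont_genome$sequence, spans$start[i] + 1L, spans$end[i])
      pos <- sample.int(nchar(host_seq) - 1L, 1L)
      host_seq <- paste0(substr(host_seq, 1L, pos), blk,
                         substr(host_seq, pos + 1L, nchar(host_seq)))
      placed <- lapply(placed, function(s) {
        if (s$start >= pos) { s$start <- s$start + nchar(blk); s$end <- s$end + nchar(blk) }
        s
      })
      placed[[length(placed) + 1L]] <- list(start = pos, end = pos + nchar(blk))
    }
    nuwt_host <- do.call(rbind, lapply(placed, as.data.frame))
  }

  sample_reads <- function(sequence, circular, depth, prefix, ref) {
    L <- nchar(sequence)
    if (depth == 0) return(NULL)
    if (rl > L) stop("read length exceeds genome length")
    n <- stats::rpois(1, depth * L / rl)
    if (n == 0L) return(NULL)
    starts <- if (circular) sample.int(L, n, replace = TRUE) - 1L else
      sample.int(L - rl + 1L, n, replace = TRUE) - 1L
    seq2 <- if (circular) paste0(sequence, substr(sequence, 1L, rl)) else sequence
    data.frame(read_id = paste0(prefix, seq_len(n)),
               sequence = substring(seq2, starts + 1L, starts + rl),
               ref = ref, start = starts, end = starts + rl,
               stringsAsFactors = FALSE)
  }

  host_reads <- sample_reads(host_seq, host_genome$circular, host_depth,
                             "hr", "host")
  endo_reads <- sample_reads(endosymbiont_genome$sequence,
                             endosymbiont_genome$circular, endo_depth,
                             "er", "endo")
  if (!is.null(host_reads)) {
    src <- rep("host", nrow(host_reads))
    if (!is.null(nuwt_host)) {
      Lh <- nchar(host_seq)
      for (i in seq_len(nrow(nuwt_host))) {
        ov <- host_reads$start < nuwt_host$end[i] &
          host_reads$end > nuwt_host$start[i]
        # wrapped reads: check the wrapped prefix too
        wrap <- host_reads$end > Lh
        ov <- ov | (wrap & (host_reads$end - Lh) > nuwt_host$start[i] &
                      0L < nuwt_host$end[i])
        src[ov] <- "nuwt"
      }
    }
    host_reads$source <- src
  }
  if (!is.null(endo_reads)) endo_reads$source <- "endosymbiont"
  reads <- rbind(host_reads, endo_reads)
  if (is.null(reads)) {
    reads <- data.frame(read_id = character(), sequence = character(),
                        ref = character(), start = integer(), end = integer(),
                        source = character(), stringsAsFactors = FALSE)
  }
  list(reads = reads[, c("read_id", "sequence", "source", "ref", "start", "end")],
       depths = c(host = host_depth, endosymbiont = endo_depth),
       nuwt_spans_host = nuwt_host,
       host_length = nchar(host_seq),
       endo_length = genome_length(endosymbiont_genome))
}
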