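# Pangenome statistics on the orthogroup x genome copy-number matrix:
# family clustering, near-single-copy selection, strain-specific gene counts,
# and core/pan rarefaction by addition-order permutation.

#' Build a family x genome copy-number matrix from annotations
#'
#' @param annotations `gene_annotations` data frame (one `family_id` per
#'   gene; parts sharing a `gene_id` count once).
#' @param genome_ids Optional genome order for the columns.
#' @return Integer matrix, families x genomes.
#' @export
family_matrix_from_annotations <- function(annotations, genome_ids = NULL) {
  ann <- annotations[!duplicated(paste(annotations$genome_id,
                                       annotations$gene_id)), , drop = FALSE]
  ann <- ann[!is.na(ann$family_id), , drop = FALSE]
  gids <- if (is.null(genome_ids)) sort(unique(ann$genome_id)) else genome_ids
  fams <- sort(unique(ann$family_id))
  m <- matrix(0L, nrow = length(fams), ncol = length(gids),
              dimnames = list(fams, gids))
  tab <- table(ann$family_id, ann$genome_id)
  m[rownames(tab), colnames(tab)] <- as.integer(tab)
  m
}

#' Cluster genes into families by single-linkage over a similarity graph
#'
#' Families are the connected components of the gene graph restricted to
#' edges with score at or above `identity_threshold`; genes without any
#' qualifying edge form singleton (novel) families.  Family ids are the
#' lexically smallest member gene id, making the assignment deterministic.
#'
#' @param gene_ids Character vector of all genes.
#' @param similarity_edges Data frame with columns `gene1`, `gene2`, `score`
#'   (symmetric scored pairs), or NULL for no edges.
#' @param identity_threshold Minimum score for an edge to count.
#' @return Named character vector gene_id -> family_id.
#' @export
cluster_families <- function(gene_ids, similarity_edges = NULL,
                             identity_threshold = 50) {
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(gene_ids), name = gene_ids)
  if (!is.null(similarity_edges) && nrow(similarity_edges) > 0L) {
    keep <- similarity_edges$score >= identity_threshold
    e <- similarity_edges[keep, , drop = FALSE]
    if (nrow(e) > 0L)
      g <- igraph::add_edges(g, rbind(match(e$gene1, gene_ids),
                                      match(e$gene2, gene_ids)))
  }
  comp <- igraph::components(g)$membership
  fam_of_comp <- vapply(split(gene_ids, comp), min, character(1))
  stats::setNames(fam_of_comp[as.character(comp)], gene_ids)
}

#' Select near-single-copy families
#'
#' A family qualifies iff it is present in exactly one copy in strictly more
#' than `min_fraction` of the genomes.
#'
#' @param matrix Family x genome count matrix.
#' @param min_fraction Strict lower bound on the single-copy genome fraction.
#' @return Character vector of family ids.
#' @export
single_copy_families <- function(matrix, min_fraction = 0.95) {
  frac1 <- rowMeans(matrix == 1L)
  rownames(matrix)[frac1 > min_fraction]
}

#' Count strain-specific (novel) genes per genome
#'
#' For each genome, the number of gene copies belonging to families present
#' in that genome only.
#'
#' @param matrix Family x genome count matrix.
#' @return Named integer vector genome_id -> count.
#' @export
strain_specific_counts <- function(matrix) {
  novel <- rowSums(matrix > 0L) == 1L
  out <- colSums(matrix[novel, , drop = FALSE])
  stats::setNames(as.integer(out), colnames(matrix))
}

#' Core/pan rarefaction curves by addition-order permutation
#'
#' For each random permutation of genome addition order, `core_k` counts
#' families present in all of the first k genomes and `pan_k` families
#' present in any; curves are means over permutations.  Novel (single-genome)
#' families are excluded by default, mirroring rarefaction of co-occurring
#' orthogroups.  Presence means count >= 1.
#'
#' @param matrix Family x genome count matrix.
#' @param n_permutations Number of addition-order permutations (>= 1);
#'   ignored when `exhaustive`.
#' @param seed Integer seed.
#' @param exclude_novel Drop families present in exactly one genome.
#' @param exhaustive Enumerate all N! addition orders instead of sampling
#'   (N <= 8 only); the result is then the exact expectation.
#' @return List of class `rarefaction_curve`: k, mean_core, mean_pan,
#'   n_permutations, seed.
#' @export
rarefaction <- function(matrix, n_permutations = 10000L, seed = 1L,
                        exclude_novel = TRUE, exhaustive = FALSE) {
  if (n_permutations < 1L) stop("n_permutations must be >= 1")
  P <- matrix > 0L
  if (exclude_novel) P <- P[rowSums(P) != 1L, , drop = FALSE]
  N <- ncol(P)
  perms <- NULL
  if (exhaustive) {
    if (N > 8L) stop("exhaustive enumeration limited to N <= 8")
    perms <- all_permutations(N)
    n_permutations <- nrow(perms)
  }
  set.seed(seed)
  core_acc <- numeric(N); pan_acc <- numeric(N)
  nf <- nrow(P)
  for (p in seq_len(n_permutations)) {
    perm <- if (is.null(perms)) sample.int(N) else perms[p, ]
    if (nf == 0L) next
    Pp <- P[, perm, drop = FALSE]
    # first genome (in addition order) containing / lacking each family
    w <- N:1
    first_in <- integer(nf); first_out <- integer(nf)
    any_in <- rowSums(Pp) > 0L
    all_in <- rowSums(Pp) == N
    first_in[any_in] <- max.col(sweep(Pp[any_in, , drop = FALSE], 2, w, `*`),
                                ties.method = "first")
    first_in[!any_in] <- N + 1L
    first_out[!all_in] <- max.col(sweep(!Pp[!all_in, , drop = FALSE], 2, w, `*`),
                                  ties.method = "first")
    first_out[all_in] <- N + 1L
    pan_acc <- pan_acc + cumsum(tabulate(first_in, N))
    core_acc <- core_acc + (nf - cumsum(tabulate(first_out, N)))
  }
  structure(list(k = seq_len(N),
                 mean_core = core_acc / n_permutations,
                 mean_pan = pan_acc / n_permutations,
                 n_permutations = n_permutations, seed = seed),
            class = "rarefaction_curve")
}

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- setdiff(seq_len(n), i)
    cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

#' Family size histogram
#'
#' @param matrix Family x genome count matrix.
#' @param by Either "copies" (total gene count per family) or "genomes"
#'   (number of genomes a family occurs in).
#' @return Named integer vector size -> number of families.
#' @export
family_size_histogram <- function(matrix, by = c("copies", "genomes")) {
  by <- match.arg(by)
  if (nrow(matrix) == 0L) return(stats::setNames(integer(0), character(0)))
  size <- if (by == "copies") rowSums(matrix) else rowSums(matrix > 0L)
  tab <- table(size)
  stats::setNames(as.integer(tab), names(tab))
}
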