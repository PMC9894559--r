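# Distance-based phylogeny from concatenated single-copy family alignments
# and phylogenetically corrected regression (PGLS) under a Brownian model.

#' Concatenate per-family alignments into a supermatrix
#'
#' Families are concatenated in lexical family-id order.  Every family must
#' cover every taxon exactly once with equal row lengths; a family missing a
#' taxon is rejected with an error naming both.
#'
#' @param per_family_alignments Named list (family_id -> named character
#'   vector taxon -> aligned sequence).
#' @param taxa Character vector of taxa to include.
#' @return List of class `supermatrix`: `taxa`, `sequences` (named
#'   concatenated strings), `family_boundaries` (family_id, start, end;
#'   0-based half-open column spans).
#' @export
build_supermatrix <- function(per_family_alignments, taxa) {
  fams <- sort(names(per_family_alignments))
  seqs <- stats::setNames(rep("", length(taxa)), taxa)
  bounds <- list()
  offset <- 0L
  for (f in fams) {
    aln <- per_family_alignments[[f]]
    miss <- setdiff(taxa, names(aln))
    if (length(miss) > 0L)
      stop("family ", f, " is missing taxon/taxa: ", paste(miss, collapse = ", "))
    w <- unique(nchar(aln[taxa]))
    if (length(w) != 1L)
      stop("family ", f, " has ragged alignment rows")
    seqs <- paste0(seqs, aln[taxa])
    names(seqs) <- taxa
    bounds[[length(bounds) + 1L]] <- data.frame(
      family_id = f, start = offset, end = offset + w, stringsAsFactors = FALSE)
    offset <- offset + w
  }
  structure(list(taxa = taxa, sequences = seqs,
                 family_boundaries = do.call(rbind, bounds)),
            class = "supermatrix")
}

#' Pairwise distance matrix from a supermatrix
#'
#' p-distance is mismatches over compared columns, excluding columns with a
#' gap or N in either sequence of the pair; jc69 applies the Jukes-Cantor
#' correction -(3/4) ln(1 - 4p/3), erroring when p >= 0.75.
#'
#' @param supermatrix A `supermatrix` (or named character vector of equal
#'   length sequences).
#' @param model "p" or "jc69".
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
distance_matrix <- function(supermatrix, model = c("p", "jc69")) {
  model <- match.arg(model)
  seqs <- if (inherits(supermatrix, "supermatrix")) supermatrix$sequences
  else supermatrix
  n <- length(seqs)
  if (n < 2L) stop("need at least 2 taxa")
  chars <- lapply(seqs, function(s) strsplit(s, "", fixed = TRUE)[[1]])
  usable <- lapply(chars, function(cc) !(cc %in% c("-", "N", "n", ".")))
  D <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    ok <- usable[[i]] & usable[[j]]
    if (!any(ok)) stop("no comparable columns between ", names(seqs)[i],
                       " and ", names(seqs)[j])
    p <- mean(chars[[i]][ok] != chars[[j]][ok])
    d <- if (model == "p") p else {
      if (p >= 0.75) stop("jc69 undefined for p >= 0.75 (pair ",
                          names(seqs)[i], ", ", names(seqs)[j], ")")
      -0.75 * log(1 - 4 * p / 3)
    }
    D[i, j] <- D[j, i] <- d
  }
  D
}

#' Neighbor-joining tree with deterministic tie-breaking
#'
#' Standard NJ agglomeration; ties in the Q criterion are broken by the
#' lexically smallest joined taxon pair, so permuting the input order yields
#' the identical tree.  Negative branch lengths are clamped to zero with the
#' deficit moved to the sibling edge (total path lengths preserved).  On
#' additive matrices the source tree is recovered exactly.
#'
#' @param D Symmetric non-negative distance matrix with zero diagonal.
#' @return An \pkg{ape} `phylo` tree (unrooted; trifurcating root).  Two taxa
#'   yield the trivial single-edge tree.
#' @export
neighbor_joining <- function(D) {
  n <- nrow(D)
  if (is.null(rownames(D))) rownames(D) <- colnames(D) <- paste0("t", seq_len(n))
  if (n < 2L) stop("need at least 2 taxa")
  if (n == 2L)
    return(ape::read.tree(text = sprintf("(%s:%.10g,%s:%.10g);",
                                         rownames(D)[1], D[1, 2] / 2,
                                         rownames(D)[2], D[1, 2] / 2)))
  lab <- rownames(D)      # current node newick fragments
  key <- rownames(D)      # lexical keys for deterministic ties
  while (length(lab) > 3L) {
    m <- length(lab)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    pk <- apply(cand, 1, function(ij) {
      ks <- sort(c(key[ij[1]], key[ij[2]])); paste(ks, collapse = "\r")
    })
    sel <- cand[order(pk)[1], ]
    i <- sel[1]; j <- sel[2]
    d_ij <- D[i, j]
    bi <- 0.5 * d_ij + (r[i] - r[j]) / (2 * (m - 2))
    bj <- d_ij - bi
    if (bi < 0) { bj <- bj + bi; bi <- 0 }
    if (bj < 0) { bi <- bi + bj; bj <- 0 }
    newlab <- sprintf("(%s:%.10g,%s:%.10g)", lab[i], bi, lab[j], bj)
    newkey <- min(key[i], key[j])
    dnew <- 0.5 * (D[i, ] + D[j, ] - d_ij)
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
                c(dnew[keep], 0))
    lab <- c(lab[keep], newlab)
    key <- c(key[keep], newkey)
    D <- D2
  }
  a <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  b <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  c3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  bl <- c(a, b, c3)
  for (i in 1:3) if (bl[i] < 0) {
    others <- setdiff(1:3, i)
    bl[others] <- bl[others] + bl[i] / 2
    bl[i] <- 0
  }
  o <- order(key)
  txt <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                 lab[o[1]], bl[o[1]], lab[o[2]], bl[o[2]], lab[o[3]], bl[o[3]])
  ape::read.tree(text = txt)
}

#' Phylogenetic generalised least squares under a Brownian model
#'
#' The error covariance C has C_ij equal to the shared root-to-tip path
#' length of taxa i and j on the (midpoint-rooted, if unrooted) tree.  The
#' estimator is beta = (X' C^-1 X)^-1 X' C^-1 y with X = [1, x];
#' sigma2 = r' C^-1 r / (n - 2); R^2 = 1 - (r' C^-1 r) / (yc' C^-1 yc) with
#' yc centred by the GLS intercept-only fit.  On a star tree with equal
#' branch lengths the fit equals ordinary least squares.
#'
#' @param tree `phylo` tree whose tip labels match `names(x)`/`names(y)`.
#' @param x,y Named numeric vectors of predictor and response per taxon.
#' @return List of class `pgls_fit`: slope, intercept, slope_se,
#'   intercept_se, r_squared, sigma2, n, df.
#' @export
pgls_fit <- function(tree, x, y) {
  if (is.null(names(x)) || is.null(names(y)))
    stop("x and y must be named by taxon")
  taxa <- tree$tip.label
  if (!setequal(taxa, names(x)) || !setequal(taxa, names(y)))
    stop("tree tips and trait names must match exactly")
  if (!ape::is.rooted(tree)) tree <- phangorn::midpoint(tree)
  C <- ape::vcv.phylo(tree)
  C <- C[taxa, taxa]
  x <- x[taxa]; y <- y[taxa]
  n <- length(taxa)
  if (n < 3L) stop("need at least 3 taxa")
  Ci <- tryCatch(solve(C), error = function(e)
    stop("singular phylogenetic covariance: ", conditionMessage(e)))
  X <- cbind(intercept = 1, x = x)
  XtCi <- t(X) %*% Ci
  XtCiX <- XtCi %*% X
  beta <- solve(XtCiX, XtCi %*% y)
  resid <- y - X %*% beta
  rss <- drop(t(resid) %*% Ci %*% resid)
  df <- n - 2L
  sigma2 <- rss / df
  covb <- sigma2 * solve(XtCiX)
  one <- rep(1, n)
  mu <- drop((t(one) %*% Ci %*% y) / (t(one) %*% Ci %*% one))
  yc <- y - mu
  tss <- drop(t(yc) %*% Ci %*% yc)
  structure(list(slope = unname(beta["x", 1]),
                 intercept = unname(beta["intercept", 1]),
                 slope_se = sqrt(covb["x", "x"]),
                 intercept_se = sqrt(covb["intercept", "intercept"]),
                 r_squared = 1 - rss / tss, sigma2 = sigma2,
                 n = n, df = df),
            class = "pgls_fit")
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat(sprintf("<pgls_fit> n=%d  slope=%.4g (se %.3g)  intercept=%.4g  R2=%.3f\n",
              x$n, x$slope, x$slope_se, x$intercept, x$r_squared))
  invisible(x)
}
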