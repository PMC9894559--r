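test_that("supermatrix concatenates in family order and validates taxa", {
  taxa <- c("t1", "t2", "t3")
  alns <- list(
    famB = c(t1 = strrep("A", 20), t2 = strrep("C", 20), t3 = strrep("G", 20)),
    famA = c(t1 = strrep("T", 10), t2 = strrep("T", 10), t3 = strrep("A", 10)))
  sm <- build_supermatrix(alns, taxa)
  expect_equal(nchar(sm$sequences[["t1"]]), 30L)
  expect_equal(sm$family_boundaries$family_id, c("famA", "famB"))  # lexical
  # boundary round trip
  b <- sm$family_boundaries
  for (i in seq_len(nrow(b))) {
    got <- substr(sm$sequences, b$start[i] + 1L, b$end[i])
    expect_equal(unname(got), unname(alns[[b$family_id[i]]][taxa]))
  }
  alns$famA <- alns$famA[c("t1", "t2")]
  expect_error(build_supermatrix(alns, taxa), "famA.*t3")
  alns$famA <- c(t1 = "AC", t2 = "A", t3 = "AC")
  expect_error(build_supermatrix(alns, taxa), "ragged")
})

test_that("p-distance and jc69 follow the closed forms", {
  seqs <- c(a = strrep("A", 100),
            b = paste0(strrep("C", 10), strrep("A", 90)))
  D <- distance_matrix(seqs, "p")
  expect_equal(D["a", "b"], 0.10)
  expect_equal(D["a", "a"], 0)
  Dj <- distance_matrix(seqs, "jc69")
  expect_equal(Dj["a", "b"], 0.10732, tolerance = 1e-4)
  # gaps and N excluded pairwise
  seqs2 <- c(a = "ACGT-N", b = "ACTTAA")
  expect_equal(distance_matrix(seqs2, "p")["a", "b"], 0.25)
  expect_error(distance_matrix(c(a = "--", b = "AA")), "no comparable")
  expect_error(distance_matrix(c(a = "A")), "at least 2")
  # jc69 saturation guard
  seqs3 <- c(a = strrep("A", 100), b = strrep("C", 100))
  expect_error(distance_matrix(seqs3, "jc69"), "undefined")
})

test_that("NJ: 3-taxon closed form, additive recovery, order invariance", {
  D3 <- matrix(c(0, 5, 9, 5, 0, 10, 9, 10, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr3 <- neighbor_joining(D3)
  bl <- setNames(tr3$edge.length[match(seq_len(3), tr3$edge[, 2])],
                 tr3$tip.label)
  expect_equal(unname(bl[c("A", "B", "C")]), c(2, 3, 7))

  set.seed(41)
  for (i in 1:5) {
    tr <- ape::unroot(ape::rtree(6))
    D <- cophenetic(tr)
    rec <- neighbor_joining(D)
    expect_equal(suppressMessages(phangorn::RF.dist(tr, rec)), 0)
    expect_equal(max(abs(cophenetic(rec)[rownames(D), colnames(D)] - D)), 0,
                 tolerance = 1e-8)
    # permuting taxa gives the identical tree
    p <- sample(6)
    rec2 <- neighbor_joining(D[p, p])
    expect_equal(suppressMessages(phangorn::RF.dist(rec, rec2)), 0)
    expect_equal(sort(cophenetic(rec2)[rownames(D), colnames(D)]),
                 sort(cophenetic(rec)[rownames(D), colnames(D)]),
                 tolerance = 1e-8)
  }

  # two taxa: trivial single-edge tree
  D2 <- matrix(c(0, 4, 4, 0), 2, 2, dimnames = list(c("x", "y"), c("x", "y")))
  t2 <- neighbor_joining(D2)
  expect_equal(sum(t2$edge.length), 4)
})

test_that("NJ agrees with the reference implementation on noisy matrices", {
  set.seed(4)
  for (i in 1:3) {
    tr <- ape::rtree(8)
    D <- cophenetic(tr) + matrix(runif(64, 0, 1e-3), 8, 8)
    D <- (D + t(D)) / 2; diag(D) <- 0
    expect_equal(suppressMessages(phangorn::RF.dist(neighbor_joining(D),
                                                    ape::nj(D))), 0)
  }
})

test_that("PGLS on a star tree equals OLS; perfect fits are exact", {
  star <- ape::stree(10, "star")
  star$edge.length <- rep(1, 10)
  set.seed(6)
  x <- setNames(rnorm(10), star$tip.label)
  y <- setNames(3 + 2 * x + rnorm(10, sd = 0.5), star$tip.label)
  f <- pgls_fit(star, x, y)
  o <- lm(y ~ x)
  expect_equal(f$slope, unname(coef(o)[2]), tolerance = 1e-10)
  expect_equal(f$intercept, unname(coef(o)[1]), tolerance = 1e-10)
  expect_equal(f$r_squared, summary(o)$r.squared, tolerance = 1e-10)

  tr <- ape::rtree(12)
  x2 <- setNames(rnorm(12), tr$tip.label)
  y2 <- 2 * x2
  f2 <- pgls_fit(tr, x2, y2)
  expect_equal(f2$slope, 2, tolerance = 1e-10)
  expect_equal(f2$r_squared, 1, tolerance = 1e-10)
})

test_that("PGLS slope is invariant to shifting x or y", {
  set.seed(7)
  tr <- ape::rtree(15)
  x <- setNames(rnorm(15), tr$tip.label)
  C <- ape::vcv.phylo(tr)
  y <- setNames(drop(t(chol(C)) %*% rnorm(15)) + 1.5 * x, tr$tip.label)
  f <- pgls_fit(tr, x, y)
  f_shift_x <- pgls_fit(tr, x + 100, y)
  f_shift_y <- pgls_fit(tr, x, y + 100)
  expect_equal(f_shift_x$slope, f$slope, tolerance = 1e-8)
  expect_equal(f_shift_y$slope, f$slope, tolerance = 1e-8)
  expect_equal(f_shift_y$intercept, f$intercept + 100, tolerance = 1e-8)
})

test_that("PGLS matches a generalised least squares reference", {
  set.seed(8)
  tr <- ape::rtree(10)
  C <- ape::vcv.phylo(tr)
  x <- setNames(rnorm(10), tr$tip.label)
  y <- setNames(drop(t(chol(C)) %*% rnorm(10)) + 0.8 * x, tr$tip.label)
  f <- pgls_fit(tr, x, y)
  # whitened OLS oracle: L^-1 y = L^-1 X beta + e with C = L L'
  L <- t(chol(C[tr$tip.label, tr$tip.label]))
  yw <- solve(L, y[tr$tip.label])
  Xw <- solve(L, cbind(1, x[tr$tip.label]))
  ref <- lm(yw ~ Xw - 1)
  expect_equal(f$intercept, unname(coef(ref)[1]), tolerance = 1e-8)
  expect_equal(f$slope, unname(coef(ref)[2]), tolerance = 1e-8)
  expect_equal(f$slope_se, unname(sqrt(diag(vcov(ref)))[2]), tolerance = 1e-8)
})

test_that("size ~ prophage span regression is positive, R2 grows as noise shrinks", {
  set.seed(9)
  tr <- ape::rtree(16)
  C <- ape::vcv.phylo(tr)
  span <- setNames(runif(16, 0, 3e5), tr$tip.label)
  r2 <- vapply(c(2e5, 5e4, 1e4), function(noise) {
    bm <- drop(t(chol(C)) %*% rnorm(16)) * noise
    size <- setNames(1.3e6 + span + bm, tr$tip.label)
    f <- pgls_fit(tr, span, size)
    expect_gt(f$slope, 0)
    f$r_squared
  }, numeric(1))
  expect_true(all(diff(r2) > 0))
})
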