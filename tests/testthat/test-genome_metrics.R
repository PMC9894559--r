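test_that("rotation moves the anchor to position 0 and is idempotent", {
  g <- genome_record("gr", "AAAACCGGTT", circular = TRUE)
  ann <- gene_annotations(genome_id = "gr", gene_id = "anchor",
                          start = 4L, end = 6L, strand = "+",
                          family_id = "hemE", tags = "other")
  rot <- rotate_to_anchor(g, ann, "hemE")
  expect_equal(rot$genome$sequence, "CCGGTTAAAA")
  expect_equal(rot$annotations$start[1], 0L)
  expect_equal(rot$annotations$end[1], 2L)

  again <- rotate_to_anchor(rot$genome, rot$annotations, "hemE")
  expect_equal(again$genome$sequence, rot$genome$sequence)
  expect_equal(again$annotations, rot$annotations)
})

test_that("minus-strand anchor triggers reverse complement; genes preserved", {
  set.seed(31)
  g <- make_genome(2000, seed = 31, id = "gm")
  ann <- gene_annotations(genome_id = "gm",
                          gene_id = c("anchor", "other1"),
                          start = c(500L, 1200L), end = c(700L, 1400L),
                          strand = c("-", "+"),
                          family_id = c("hemE", "f2"), tags = "other")
  rot <- rotate_to_anchor(g, ann, "hemE")
  a <- rot$annotations[rot$annotations$gene_id == "anchor", ]
  expect_equal(a$start, 0L)
  expect_equal(a$strand, "+")
  # anchor subsequence is the reverse complement of the original
  expect_equal(substr(rot$genome$sequence, 1, 200),
               revcomp(substr(g$sequence, 501, 700)))
  # gene set preserved (same ids, same widths)
  expect_setequal(rot$annotations$gene_id, ann$gene_id)
  widths <- function(d) sort(tapply(d$end - d$start, d$gene_id, sum))
  expect_equal(widths(rot$annotations), widths(ann))

  expect_error(rotate_to_anchor(g, ann, "nope"), "absent")
  ann2 <- rbind(ann, ann[1, ]); ann2$gene_id[3] <- "anchor2"
  expect_error(rotate_to_anchor(g, ann2, "hemE"), "more than once")
})

test_that("gc_content arithmetic, N handling, and strand invariance", {
  expect_equal(gc_content("GGCC"), 100)
  expect_equal(gc_content("ATAT"), 0)
  expect_equal(gc_content("GCAT"), 50)
  expect_equal(gc_content("GCNN"), 100)  # N excluded from denominator
  expect_error(gc_content("NNNN"), "no counted")
  s <- random_seq(5000, seed = 3)
  expect_equal(gc_content(s), gc_content(revcomp(s)))
})

test_that("skew profile values and missing-window convention", {
  expect_true(all(skew_profile(strrep("G", 1000), 100)$values == 1))
  expect_true(all(skew_profile(strrep("GC", 500), 100)$values == 0))
  p <- skew_profile(strrep("AT", 500), 100)
  expect_true(all(is.na(p$values)))  # G+C = 0 windows are missing
  expect_error(skew_profile("ACGT", 0), "positive")
  expect_error(skew_profile("ACGT", 10), "larger than sequence")
})

test_that("skew index: perfect bipartition scores 1; enumeration oracle", {
  g <- paste0(strrep("G", 5000), strrep("C", 5000))
  si <- skew_index(skew_profile(g, 500))
  expect_equal(si$skew_index, 1.0)

  # independent exhaustive-enumeration oracle on a 10-window profile
  oracle <- function(sgn) {
    W <- length(sgn)
    best <- 0
    for (i in 1:W) for (j in 1:W) {
      if (i == j) next
      arc1 <- if (i < j) seq(i, j - 1) else c(seq(i, W), seq_len(j - 1))
      arc2 <- setdiff(1:W, arc1)
      f <- max(sum(sgn[arc1] > 0) + sum(sgn[arc2] < 0),
               sum(sgn[arc1] < 0) + sum(sgn[arc2] > 0)) / sum(sgn != 0)
      best <- max(best, f)
    }
    2 * max(best, 1 - best) - 1
  }
  alternating <- rep(c(1, -1), 5)
  prof <- structure(list(values = alternating), class = "skew_profile")
  expect_equal(skew_index(prof)$skew_index, oracle(alternating))
  set.seed(12)
  for (i in 1:10) {
    v <- sample(c(-1, 1), 10, replace = TRUE)
    prof <- structure(list(values = v), class = "skew_profile")
    expect_equal(skew_index(prof)$skew_index, oracle(v))
  }
  expect_error(skew_index(structure(list(values = c(1, -1, 1)),
                                    class = "skew_profile")), "at least 4")
})

test_that("skew index is rotation- and reverse-complement-invariant", {
  set.seed(77)
  s <- paste(endosym:::random_skewed_sequence(20000, skew_amplitude = 0.3),
             collapse = "")
  w <- 1000L
  base <- skew_index(skew_profile(s, w))$skew_index
  # rotation by whole windows
  for (k in c(3L, 9L)) {
    rot <- paste0(substr(s, k * w + 1L, 20000L), substr(s, 1L, k * w))
    expect_equal(skew_index(skew_profile(rot, w))$skew_index, base)
  }
  expect_equal(skew_index(skew_profile(revcomp(s), w))$skew_index, base)
})

test_that("planted skew flips sign at origin and terminus", {
  set.seed(42)
  s <- paste(endosym:::random_skewed_sequence(40000, skew_amplitude = 0.5),
             collapse = "")
  p <- skew_profile(s, 2000)
  # first half positive, second half negative
  expect_true(all(p$values[1:10] > 0))
  expect_true(all(p$values[11:20] < 0))
  si <- skew_index(p)
  expect_gt(si$skew_index, 0.9)
})

test_that("iid random sequences have low skew index on average", {
  set.seed(1234)
  vals <- vapply(1:40, function(i) {
    s <- random_seq(25000)
    skew_index(skew_profile(s, 500))$skew_index
  }, numeric(1))
  expect_lt(mean(vals), 0.35)
})
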