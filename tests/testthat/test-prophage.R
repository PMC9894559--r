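test_that("gap rule: five intervening genes join, six split", {
  # two head-tagged genes with k "other" genes between them
  mk <- function(k) ann_track(c("head", rep("other", k), "baseplate"))
  joined <- scan_prophage(mk(5), circular = FALSE)
  expect_length(joined, 1L)
  expect_length(joined[[1]]$gene_ids, 7L)

  split <- scan_prophage(mk(6), circular = FALSE)
  expect_length(split, 2L)  # both halves carry a core-module gene

  # when one half lacks a core-module gene it is dropped
  mixed <- ann_track(c("head", rep("other", 6), "phage_linked"))
  kept <- scan_prophage(mixed, circular = FALSE)
  expect_length(kept, 1L)
  expect_equal(kept[[1]]$span, c(0, 100))
})

test_that("phage_linked genes extend but cannot seed regions", {
  only_linked <- ann_track(rep("phage_linked", 4))
  expect_length(scan_prophage(only_linked, circular = FALSE), 0L)
  none <- ann_track(rep("other", 5))
  expect_length(scan_prophage(none, circular = FALSE), 0L)
  # linked gene at the edge extends the span
  ext <- ann_track(c("phage_linked", "head", "phage_linked"))
  r <- scan_prophage(ext, circular = FALSE)
  expect_length(r, 1L)
  expect_equal(r[[1]]$span, c(0, 320))
})

test_that("completeness thresholds follow the 5/6, 7/8, 5/6, 5/6 rule", {
  expect_true(completeness_call(c(head = 5, baseplate = 7, tail = 5, fibre = 5)))
  expect_false(completeness_call(c(head = 4, baseplate = 8, tail = 6, fibre = 6)))
  expect_true(completeness_call(c(head = 6, baseplate = 8, tail = 6, fibre = 6)))
  expect_false(completeness_call(c(head = 6, baseplate = 6, tail = 6, fibre = 6)))
})

test_that("module inventory counts distinct family slots, not copies", {
  fams <- c("phage_head_1", "phage_head_1", "phage_head_2",
            "phage_baseplate_1")
  ann <- ann_track(c("head", "head", "head", "baseplate"), families = fams)
  r <- scan_prophage(ann, circular = FALSE)
  expect_equal(unname(r[[1]]$inventory["head"]), 2L)  # duplicated slot counts once
})

test_that("planted prophages are recovered exactly, spans to the base pair", {
  ss <- generate_strain_set(n_genomes = 4, genome_length = 60000,
                            n_prophages_range = c(1, 3), seed = 77)
  truth <- ss$truth$prophages
  for (g in ss$genomes) {
    ann <- ss$annotations[ss$annotations$genome_id == g$genome_id, ]
    regs <- scan_prophage(ann, circular = TRUE, genome_len = genome_length(g))
    mine <- truth[truth$genome_id == g$genome_id, ]
    expect_equal(length(regs), nrow(mine))
    got <- do.call(rbind, lapply(regs, function(r)
      data.frame(start = r$span[1], end = r$span[2], complete = r$complete)))
    got <- got[order(got$start), ]
    mine <- mine[order(mine$start), ]
    expect_equal(got$start, mine$start)
    expect_equal(got$end, mine$end)
    expect_equal(got$complete, mine$complete)
  }
})

test_that("detection is rotation-invariant on circular genomes", {
  ss <- generate_strain_set(n_genomes = 2, genome_length = 50000,
                            n_prophages_range = c(2, 2), seed = 13)
  g <- ss$genomes[[1]]
  ann <- ss$annotations[ss$annotations$genome_id == g$genome_id, ]
  base <- scan_prophage(ann, circular = TRUE, genome_len = genome_length(g))
  rot <- rotate_to_anchor(g, ann, "hemE")
  # rotate again from an arbitrary gene family to move the origin
  fam2 <- ann$family_id[which(ann$start > 20000 & !is.na(ann$family_id))[1]]
  rot2 <- rotate_to_anchor(g, ann, fam2)
  regs2 <- scan_prophage(rot2$annotations[order(rot2$annotations$start), ],
                         circular = TRUE, genome_len = genome_length(g))
  expect_equal(length(regs2), length(base))
  expect_setequal(
    vapply(regs2, function(r) r$span[2] - r$span[1], numeric(1)),
    vapply(base, function(r) r$span[2] - r$span[1], numeric(1)))
  expect_equal(sort(vapply(regs2, function(r) r$complete, logical(1))),
               sort(vapply(base, function(r) r$complete, logical(1))))
})

test_that("deleting a module gene never makes an incomplete region complete", {
  inv <- c(head = 5, baseplate = 7, tail = 5, fibre = 5)
  for (m in names(inv)) {
    lowered <- inv; lowered[m] <- lowered[m] - 1
    expect_false(completeness_call(lowered) && !completeness_call(inv))
    expect_false(completeness_call(lowered))
  }
})

test_that("span fraction arithmetic and overlap guard", {
  g <- make_genome(10000, seed = 44)
  expect_equal(prophage_span_fraction(g, list()), 0)
  r1 <- structure(list(genome_id = "gx", span = c(1000, 2000)),
                  class = "prophage_region")
  expect_equal(prophage_span_fraction(g, list(r1)), 0.1)
  r2 <- structure(list(genome_id = "gx", span = c(1500, 3000)),
                  class = "prophage_region")
  expect_error(prophage_span_fraction(g, list(r1, r2)), "overlap")
})

test_that("EAM cargo excludes structural genes; boundary rule uses gene start", {
  ann <- ann_track(c("head", "cifA", "cifB", "baseplate", "tail"),
                   families = c("phage_head_1", "cifA_tI", "cifB_tI",
                                "phage_baseplate_1", "phage_tail_1"))
  r <- scan_prophage(ann, circular = FALSE)[[1]]
  cargo <- eam_cargo(r, ann)
  expect_setequal(cargo, ann$gene_id[2:3])

  # all-structural region has empty cargo
  ann2 <- ann_track(c("head", "baseplate"), families = c("h1", "b1"))
  r2 <- scan_prophage(ann2, circular = FALSE)[[1]]
  expect_length(eam_cargo(r2, ann2), 0L)

  # gene straddling the boundary included iff its start is inside
  ann3 <- ann_track(c("head", "baseplate"))
  r3 <- scan_prophage(ann3, circular = FALSE)[[1]]
  straddler <- gene_annotations(genome_id = "g1", gene_id = "strad",
                                start = r3$span[2] - 10L,
                                end = r3$span[2] + 400L, strand = "+",
                                family_id = "sx", tags = "other")
  outside <- gene_annotations(genome_id = "g1", gene_id = "out",
                              start = r3$span[2] + 5L,
                              end = r3$span[2] + 300L, strand = "+",
                              family_id = "sy", tags = "other")
  cargo3 <- eam_cargo(r3, rbind(ann3, straddler, outside))
  expect_true("strad" %in% cargo3)
  expect_false("out" %in% cargo3)
})

test_that("genome size correlates with planted prophage span across a panel", {
  set.seed(91)
  sizes <- numeric(0); spans <- numeric(0)
  ss <- generate_strain_set(n_genomes = 8, genome_length = 120000,
                            n_prophages_range = c(0, 4), seed = 91)
  tp <- ss$truth$prophages
  for (g in ss$genomes) {
    sizes <- c(sizes, genome_length(g))
    mine <- tp[!is.null(tp) & tp$genome_id == g$genome_id, , drop = FALSE]
    spans <- c(spans, if (is.null(tp) || nrow(mine) == 0) 0 else
      sum(mine$end - mine$start))
  }
  expect_gt(coef(lm(sizes ~ spans))[2], 0)
})
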