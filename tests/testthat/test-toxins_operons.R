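cif_hit <- function(gene, role, type = "I", evalue = 1e-50, cov = 100,
                    bitscore = 500) {
  data.frame(gene_id = gene, reference_id = paste0("ref", type), role = role,
             type_label = type, evalue = evalue, query_coverage = cov,
             bitscore = bitscore, stringsAsFactors = FALSE)
}

pair_ann <- function(tags = c("other", "cifA", "cifB", "other")) {
  ann_track(tags, families = paste0("f", seq_along(tags)))
}

test_that("cif qualification enforces e-value and the 80-120% coverage window", {
  ann <- pair_ann()
  g <- ann$gene_id
  ok <- rbind(cif_hit(g[2], "CifA"), cif_hit(g[3], "CifB"))
  expect_equal(nrow(find_cif_pairs(ok, ann)$pairs), 1L)

  low_cov <- rbind(cif_hit(g[2], "CifA", cov = 75), cif_hit(g[3], "CifB"))
  expect_equal(nrow(find_cif_pairs(low_cov, ann)$pairs), 0L)
  hi_cov <- rbind(cif_hit(g[2], "CifA", cov = 121), cif_hit(g[3], "CifB"))
  expect_equal(nrow(find_cif_pairs(hi_cov, ann)$pairs), 0L)
  weak_e <- rbind(cif_hit(g[2], "CifA", evalue = 1e-20), cif_hit(g[3], "CifB"))
  expect_equal(nrow(find_cif_pairs(weak_e, ann)$pairs), 0L)
  boundary <- rbind(cif_hit(g[2], "CifA", evalue = 1e-30, cov = 80),
                    cif_hit(g[3], "CifB", cov = 120))
  expect_equal(nrow(find_cif_pairs(boundary, ann)$pairs), 1L)
  expect_equal(nrow(find_cif_pairs(ok[0, ], ann)$pairs), 0L)
})

test_that("strict adjacency: one intervening gene kills the pair; order-agnostic", {
  sep <- ann_track(c("cifA", "other", "cifB"),
                   families = c("fa", "fx", "fb"))
  g <- sep$gene_id
  hits <- rbind(cif_hit(g[1], "CifA"), cif_hit(g[3], "CifB"))
  expect_equal(nrow(find_cif_pairs(hits, sep, circular = FALSE)$pairs), 0L)

  swapped <- ann_track(c("cifB", "cifA"), families = c("fb", "fa"))
  g2 <- swapped$gene_id
  hits2 <- rbind(cif_hit(g2[1], "CifB"), cif_hit(g2[2], "CifA"))
  p <- find_cif_pairs(hits2, swapped)$pairs
  expect_equal(nrow(p), 1L)
  expect_equal(p$cifA_gene, g2[2])
  expect_equal(p$cifB_gene, g2[1])
})

test_that("type label comes from the best-bitscore reference; ambiguity excluded", {
  ann <- pair_ann()
  g <- ann$gene_id
  hits <- rbind(cif_hit(g[2], "CifA", type = "I", bitscore = 300),
                cif_hit(g[3], "CifB", type = "IV", bitscore = 900))
  p <- find_cif_pairs(hits, ann)$pairs
  expect_equal(p$type_label, "IV")

  amb <- rbind(cif_hit(g[2], "CifA"), cif_hit(g[2], "CifB"),
               cif_hit(g[3], "CifB"))
  res <- find_cif_pairs(amb, ann)
  expect_equal(res$ambiguous, g[2])
  expect_equal(nrow(res$pairs), 0L)
})

test_that("pairs are located relative to prophage regions and summarised", {
  ann <- ann_track(c("head", "cifA", "cifB", "baseplate", "other", "other",
                     "other", "other", "other", "other", "cifA", "cifB"),
                   families = c("ph1", "fa1", "fb1", "pb1", paste0("x", 1:6),
                                "fa2", "fb2"))
  g <- ann$gene_id
  regions <- scan_prophage(ann, circular = FALSE)
  hits <- rbind(cif_hit(g[2], "CifA"), cif_hit(g[3], "CifB"),
                cif_hit(g[11], "CifA", type = "V"),
                cif_hit(g[12], "CifB", type = "V"))
  res <- find_cif_pairs(hits, ann, prophage_regions = regions,
                        circular = FALSE)
  expect_equal(nrow(res$pairs), 2L)
  expect_equal(sort(res$pairs$in_eam), c(FALSE, TRUE))

  s <- summarize_cif(res$pairs)
  expect_equal(s$n_pairs, 2L)
  expect_equal(unname(s$per_type["I"]), 1L)
  expect_equal(unname(s$per_type["V"]), 1L)
  expect_equal(s$eam$percent, 50)

  s0 <- summarize_cif(res$pairs[0, ])
  expect_equal(s0$n_pairs, 0L)
  expect_null(s0$eam)
})

test_that("EAM fraction rounding follows the n (p%) convention", {
  pairs <- data.frame(genome_id = "g", cifA_gene = letters[1:3],
                      cifB_gene = LETTERS[1:3], type_label = "I",
                      in_eam = c(TRUE, TRUE, FALSE),
                      evalue_A = 0, evalue_B = 0, stringsAsFactors = FALSE)
  expect_equal(summarize_cif(pairs)$eam$percent, 67)
})

test_that("planted cif pairs (and EAM placement) are recovered exactly", {
  ss <- generate_strain_set(n_genomes = 4, genome_length = 50000,
                            n_prophages_range = c(1, 2), cif_pair_rate = 2,
                            seed = 29)
  truth <- ss$truth$cif_pairs
  expect_false(is.null(truth))  # pairs are drawn under this seed
  hits <- endosym:::cif_hits_from_tags(ss$annotations)
  found <- 0L
  for (g in ss$genomes) {
    ann <- ss$annotations[ss$annotations$genome_id == g$genome_id, ]
    regs <- scan_prophage(ann, circular = TRUE, genome_len = genome_length(g))
    res <- find_cif_pairs(hits, ann, prophage_regions = regs)
    mine <- truth[truth$genome_id == g$genome_id, , drop = FALSE]
    expect_equal(nrow(res$pairs), nrow(mine))
    expect_equal(sum(res$pairs$in_eam), sum(mine$in_prophage))
    found <- found + nrow(res$pairs)
  }
  expect_equal(found, nrow(truth))
})

test_that("biotin operon detection: completeness, order, disruption", {
  intact <- ann_track(c("other", "bioA", "bioD", "bioC", "bioH", "bioF",
                        "bioB", "other"))
  call <- find_biotin_operon(intact)
  expect_true(call$present)
  expect_true(call$order_conserved)
  expect_false(call$disrupted)
  expect_setequal(call$genes_found,
                  c("bioA", "bioB", "bioC", "bioD", "bioF", "bioH"))

  five <- ann_track(c("bioA", "bioD", "bioC", "bioH", "bioF"))
  c5 <- find_biotin_operon(five)
  expect_false(c5$present)
  expect_length(c5$genes_found, 5L)

  disrupted <- ann_track(c("bioA", "bioD", "bioC", "transposase", "bioH",
                           "bioF", "bioB"))
  cd <- find_biotin_operon(disrupted)
  expect_true(cd$present)
  expect_true(cd$disrupted)

  scrambled <- ann_track(c("bioB", "bioD", "bioC", "bioH", "bioF", "bioA"))
  cs <- find_biotin_operon(scrambled)
  expect_true(cs$present)
  expect_false(cs$order_conserved)

  reverse <- ann_track(rev(c("bioA", "bioD", "bioC", "bioH", "bioF", "bioB")))
  expect_true(find_biotin_operon(reverse)$order_conserved)

  none <- ann_track(c("other", "other"))
  expect_false(find_biotin_operon(none)$present)

  # genes split across distant loci do not form one operon
  tags <- c("bioA", "bioD", "bioC", rep("other", 4), "bioH", "bioF", "bioB")
  expect_false(find_biotin_operon(ann_track(tags), max_intervening = 2)$present)
})

test_that("planted biotin operons and disruption states are recovered", {
  ss <- generate_strain_set(n_genomes = 6, genome_length = 40000,
                            n_prophages_range = c(0, 1), biotin_prob = 1,
                            biotin_disrupt_prob = 0.5, seed = 101)
  truth <- ss$truth$biotin
  expect_equal(nrow(truth), 6L)
  for (i in seq_len(nrow(truth))) {
    ann <- ss$annotations[ss$annotations$genome_id == truth$genome_id[i], ]
    call <- find_biotin_operon(ann)
    expect_true(call$present)
    expect_equal(call$disrupted, truth$disrupted[i])
    expect_true(call$order_conserved)
  }
})
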