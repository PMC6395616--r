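test_that("replicate pooling sums counts and keeps unshared sites", {
  r1 <- methylation_table("c1", c(10, 20), "+", "CG", c(3, 1), c(10, 5))
  r2 <- methylation_table("c1", c(10, 30), "+", "CG", c(2, 4), c(10, 8))
  pooled <- pool_replicates(list(r1, r2))
  shared <- pooled[pooled$position == 10]
  expect_equal(shared$count_methylated, 5L)
  expect_equal(shared$count_total, 20L)
  expect_equal(nrow(pooled), 3L)          # unshared sites carried through
  # mediant inequality: pooled level between the replicate levels
  expect_true(shared$count_methylated / shared$count_total >= min(3 / 10, 2 / 10) &&
                shared$count_methylated / shared$count_total <= max(3 / 10, 2 / 10))
  # conflicting context at one site is an error
  bad <- methylation_table("c1", 10, "+", "CHG", 1, 2)
  expect_error(pool_replicates(list(r1, bad)), "conflicting context")
})

test_that("weighted levels pool counts and report absence as NA", {
  mt <- methylation_table("c1", c(100, 200, 300), "+", "CG",
                          c(3, 1, 9), c(10, 10, 9))
  r <- weighted_methylation(mt, "c1", 0, 250, "CG")
  expect_equal(r$level, 4 / 20)
  expect_equal(r$covered_cytosines, 2L)
  expect_true(is.na(weighted_methylation(mt, "c1", 0, 250, "CHG")$level))
  expect_equal(weighted_methylation(mt, "c1", 250, 350, "CG")$level, 1.0)
  # min_total filters shallow cytosines
  expect_equal(weighted_methylation(mt, "c1", 0, 350, "CG",
                                    min_total = 10)$level, 4 / 20)
})

test_that("pooled-count bin levels are invariant to splitting a replicate", {
  sim <- small_sim(seed = 41, n = 400)
  me <- simulate_methylation(sim)
  full <- pool_replicates(me$replicates)
  half1 <- full[seq(1, nrow(full), by = 2)]
  half2 <- full[seq(2, nrow(full), by = 2)]
  genes <- sim$genes_dup[1:100, ]
  p_full <- metagene_profile(genes, full, "CG")
  p_split <- metagene_profile(genes, pool_replicates(list(half1, half2)),
                              "CG")
  expect_equal(p_full$level, p_split$level)
})

test_that("metagene profiles are flat under uniform methylation", {
  g <- gene_table("g1", "c1", 5000, 9000, "+")
  pos <- seq(2001, 12000, by = 50)
  mt <- methylation_table("c1", pos, "+", "CG", rep(5, length(pos)),
                          rep(10, length(pos)))
  p <- metagene_profile(g, mt, "CG")
  expect_equal(nrow(p), 100L)
  expect_true(all(abs(p$level - 0.5) < 1e-12, na.rm = TRUE))
  expect_equal(attr(p, "n_genes"), 1L)
})

test_that("profiles are transcription-oriented (strand flip)", {
  # plus gene and a mirror-image minus gene; methylation only on the
  # genome-left flank of each
  gp <- gene_table("gp", "c1", 5000, 6000, "+")
  gm <- gene_table("gm", "c2", 5000, 6000, "-")
  pos <- seq(2001, 5000, by = 25)  # genome-left flank
  mk <- function(chrom) methylation_table(chrom, pos, "+", "CG",
                                          rep(8, length(pos)),
                                          rep(10, length(pos)))
  pp <- metagene_profile(gp, mk("c1"), "CG")
  pm <- metagene_profile(gm, mk("c2"), "CG")
  # for the plus gene the signal is upstream; for the minus gene downstream
  expect_true(all(pp$covered_cytosines[pp$segment == "upstream"] > 0))
  expect_true(all(pp$covered_cytosines[pp$segment == "downstream"] == 0))
  expect_true(all(pm$covered_cytosines[pm$segment == "downstream"] > 0))
  expect_true(all(pm$covered_cytosines[pm$segment == "upstream"] == 0))
  # and the minus profile is the reverse of the plus profile
  expect_equal(pm$level, rev(pp$level))
})

test_that("body-elevated methylation shows up in body bins", {
  sim <- small_sim(seed = 42, n = 400)
  me <- simulate_methylation(sim)
  pooled <- pool_replicates(me$replicates)
  p <- metagene_profile(sim$genes_dup, pooled, "CG")
  body <- mean(p$level[p$segment == "body"])
  flank <- mean(p$level[p$segment != "body"])
  expect_gt(body, flank)   # CG defaults: body 0.45 vs flanks 0.35
  expect_lt(abs(body - 0.45), 0.02)
  expect_lt(abs(flank - 0.35), 0.02)
})

test_that("group comparisons detect planted differences and respect nulls", {
  sim <- simulate_genomes(simulation_config(
    seed = 43, n_outgroup_genes = 1200, rearrangement_events = 0L,
    ancient_segments = 0L, tandem_fraction = 0, spurious_hit_fraction = 0,
    meth_body_shift = list(context = "CHG", copy = "B", delta = 0.15)))
  me <- simulate_methylation(sim)
  pooled <- pool_replicates(me$replicates)
  tr <- sim$truth
  gA <- sim$genes_dup[sim$genes_dup$gene_id %in%
                        tr$gene_id[tr$copy == "A"][1:500], ]
  gB <- sim$genes_dup[sim$genes_dup$gene_id %in%
                        tr$gene_id[tr$copy == "B"][1:500], ]
  planted <- compare_region_methylation(gA, gB, pooled, "body", "CHG")
  expect_lt(planted$p, 0.01)
  expect_lt(planted$median_a, planted$median_b)
  null_cmp <- compare_region_methylation(gA, gB, pooled, "body", "CG")
  expect_gt(null_cmp$p, 0.01)
  # identical groups cannot be flagged
  self_cmp <- compare_region_methylation(gA, gA, pooled, "body", "CHG")
  expect_equal(self_cmp$p, 1)
  expect_error(compare_region_methylation(gA[1:2, ], gB, pooled, "body",
                                          "CG"), "at least 3")
})
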