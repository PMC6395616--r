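# toy world: outgroup chromosome of 10 genes, two duplicated regions with a
# hand-chosen retention pattern
toy_world <- function(pattern1 = c(1, 1, 1, 0, 1, 1, 0, 1, 1, 1),
                      pattern2 = c(1, 0, 1, 1, 0, 1, 0, 1, 0, 1)) {
  gt_out <- toy_genes(10, chrom = "o1", prefix = "o", genome_id = "out")
  ids_a <- sprintf("A%d", which(pattern1 == 1))
  ids_b <- sprintf("B%d", which(pattern2 == 1))
  gt_dup <- gene_table(
    c(ids_a, ids_b),
    rep(c("dA", "dB"), c(length(ids_a), length(ids_b))),
    c((seq_along(ids_a) - 1) * 1000, (seq_along(ids_b) - 1) * 1000),
    c((seq_along(ids_a) - 1) * 1000 + 500,
      (seq_along(ids_b) - 1) * 1000 + 500),
    "+", genome_id = "dup")
  hits <- toy_hits(c(ids_a, ids_b),
                   paste0("o", c(which(pattern1 == 1), which(pattern2 == 1))))
  blocks <- chain_anchors(hits, gt_dup, gt_out,
                          chain_params(match_size = 3))
  list(gt_out = gt_out, gt_dup = gt_dup, blocks = blocks,
       pattern1 = pattern1, pattern2 = pattern2)
}

test_that("region pairing and singleton counts match hand enumeration", {
  w <- toy_world()
  rp <- pair_homologous_regions(w$blocks, w$gt_out, min_shared = 5)
  expect_equal(nrow(rp$pairs), 1L)
  rp <- count_singletons(rp, w$blocks)
  p1 <- w$pattern1; p2 <- w$pattern2
  # counts claimed over the shared interval (all 10 outgroup genes)
  expect_equal(rp$pairs$n1, sum(p1 == 1 & p2 == 0))
  expect_equal(rp$pairs$n2, sum(p1 == 0 & p2 == 1))
  expect_equal(rp$pairs$n_homeolog, sum(p1 == 1 & p2 == 1))
  expect_equal(rp$pairs$n_lost, sum(p1 == 0 & p2 == 0))
  # counting identity
  expect_equal(rp$pairs$n1 + rp$pairs$n2 + rp$pairs$n_homeolog +
                 rp$pairs$n_lost, rp$pairs$n_claimed)
})

test_that("the singleton rule labels regions and genes", {
  w <- toy_world()  # region A has 3 singletons, region B has 2
  rp <- pair_homologous_regions(w$blocks, w$gt_out, min_shared = 5)
  asg <- assign_subgenomes(rp, w$blocks, w$gt_dup)
  regions <- attr(asg, "regions")
  expect_equal(regions$subgenome_block1, "subgenome1")
  expect_equal(unique(asg$subgenome[grepl("^A", asg$gene_id)]), "subgenome1")
  expect_equal(unique(asg$subgenome[grepl("^B", asg$gene_id)]), "subgenome2")
  # homeolog pairs are mutual and span both labels
  h <- asg[asg$class == "homeolog", ]
  expect_equal(asg$partner[match(h$partner, asg$gene_id)], h$gene_id)
  expect_setequal(unique(h$subgenome), c("subgenome1", "subgenome2"))
  # singletons carry no partner
  expect_true(all(is.na(asg$partner[asg$class == "singleton"])))
  # label partition: every anchored gene in exactly one class
  expect_true(all(asg$subgenome %in%
                    c("subgenome1", "subgenome2", "unassigned")))
})

test_that("ties fall back to total retention then chromosome name", {
  # equal singleton counts (1 each), region A retains more genes in total
  w <- toy_world(pattern1 = c(1, 1, 1, 1, 1, 1, 1, 1, 1, 0),
                 pattern2 = c(0, 1, 1, 1, 1, 1, 1, 1, 1, 1))
  rp <- count_singletons(pair_homologous_regions(w$blocks, w$gt_out,
                                                 min_shared = 5), w$blocks)
  expect_equal(rp$pairs$n1, rp$pairs$n2)
  asg <- assign_subgenomes(rp, w$blocks, w$gt_dup)
  # full tie (same totals): lexicographic chromosome name dA < dB
  labA <- asg$subgenome[grepl("^A", asg$gene_id) & asg$subgenome != "unassigned"]
  expect_equal(unique(labA), "subgenome1")
})

test_that("single-region pairs label genes by the surviving region", {
  w <- toy_world(pattern2 = rep(0, 10))  # copy B entirely lost
  rp <- pair_homologous_regions(w$blocks, w$gt_out, min_shared = 5)
  expect_true(is.na(rp$pairs$block_2))
  asg <- assign_subgenomes(rp, w$blocks, w$gt_dup)
  lab <- asg$subgenome[grepl("^A", asg$gene_id)]
  expect_equal(unique(lab), "subgenome1")
  expect_true(all(asg$class[grepl("^A", asg$gene_id)] == "singleton"))
})

test_that("simulator truth is recovered: pairing, labels, counting identity", {
  sim <- simulate_genomes(simulation_config(
    seed = 21, n_outgroup_genes = 600, rearrangement_events = 0L,
    ancient_segments = 0L, tandem_fraction = 0, spurious_hit_fraction = 0))
  blocks <- filter_blocks(chain_anchors(sim$hits_dup_out, sim$genes_dup,
                                        sim$genes_out))
  rp <- count_singletons(pair_homologous_regions(blocks, sim$genes_out),
                         blocks)
  # zero rearrangement: one region pair per outgroup chromosome
  expect_equal(nrow(rp$pairs), length(unique(sim$genes_out$chromosome)))
  expect_true(all(!is.na(rp$pairs$block_2)))
  asg <- assign_subgenomes(rp, blocks, sim$genes_dup)
  tr <- sim$truth
  copy <- tr$copy[match(asg$gene_id, tr$gene_id)]
  # within each region pair, labels separate the two planted copies exactly
  for (k in seq_len(nrow(rp$pairs))) {
    sel <- asg$subgenome != "unassigned" &
      asg$outgroup_anchor %in% rp$claimed[[k]]
    agree <- mean((asg$subgenome[sel] == "subgenome1") == (copy[sel] == "A"))
    expect_true(agree %in% c(0, 1))
  }
  # class truth: homeolog/singleton calls match the planted classes
  called <- asg$class[asg$subgenome != "unassigned"]
  planted <- tr$class[match(asg$gene_id[asg$subgenome != "unassigned"],
                            tr$gene_id)]
  expect_gte(mean(called == planted), 0.99)
  # subgenome-1 singletons >= subgenome-2 singletons on every pair
  expect_true(all(pmax(rp$pairs$n1, rp$pairs$n2) - pmin(rp$pairs$n1,
                                                        rp$pairs$n2) >= 0))
})

test_that("high-confidence flags require anchors in both outgroups", {
  sim <- simulate_genomes(simulation_config(
    seed = 22, n_outgroup_genes = 600, rearrangement_events = 0L,
    ancient_segments = 0L, tandem_fraction = 0, spurious_hit_fraction = 0,
    outgroup2_retention = 1))
  blocks <- filter_blocks(chain_anchors(sim$hits_dup_out, sim$genes_dup,
                                        sim$genes_out))
  rp <- pair_homologous_regions(blocks, sim$genes_out)
  blocks2 <- filter_blocks(chain_anchors(sim$hits_dup_out2, sim$genes_dup,
                                         sim$genes_out2))
  asg <- flag_high_confidence(assign_subgenomes(rp, blocks, sim$genes_dup),
                              blocks2)
  assigned <- asg$subgenome != "unassigned"
  # full second-outgroup retention: essentially all assigned genes flagged
  expect_gte(mean(asg$high_confidence[assigned]), 0.99)
  expect_true(all(!asg$high_confidence[!assigned]))
})
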