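test_that("tandem arrays close transitively over near-adjacent hits", {
  gt <- toy_genes(10)
  # adjacent pair -> both members
  expect_equal(classify_tandem(toy_hits("g7", "g8"), gt), c("g7", "g8"))
  # different chromosomes -> nothing
  gt2 <- gene_table(c("x1", "y1"), c("c1", "c2"), c(0, 0), c(500, 500), "+")
  expect_equal(classify_tandem(toy_hits("x1", "y1"), gt2), character())
  # chain g1-g2, g2-g3 -> one array of three (brute-force closure agrees)
  hits <- toy_hits(c("g1", "g2"), c("g2", "g3"))
  expect_equal(classify_tandem(hits, gt), c("g1", "g2", "g3"))
  # max_intervening honoured: g1..g3 with one intervening gene
  expect_equal(classify_tandem(toy_hits("g1", "g3"), gt, max_intervening = 0L),
               character())
  expect_equal(classify_tandem(toy_hits("g1", "g3"), gt, max_intervening = 1L),
               c("g1", "g3"))
  expect_error(classify_tandem(toy_hits("g1", "nope"), gt), "absent")
})

test_that("chainer reports minimal blocks and respects match_size", {
  gt_a <- toy_genes(30, prefix = "a")
  gt_b <- toy_genes(30, prefix = "b")
  b5 <- chain_anchors(diagonal_hits(0:4, 0:4), gt_a, gt_b)
  expect_equal(nrow(b5$blocks), 1L)
  expect_equal(b5$blocks$n_pairs, 5L)
  expect_equal(b5$blocks$orientation, "same")
  b4 <- chain_anchors(diagonal_hits(0:3, 0:3), gt_a, gt_b)
  expect_equal(nrow(b4$blocks), 0L)
  expect_equal(nrow(chain_anchors(toy_hits(character(), character()),
                                  gt_a, gt_b)$blocks), 0L)
})

test_that("a gap above max_gaps splits a chain in two", {
  gt_a <- toy_genes(60, prefix = "a")
  gt_b <- toy_genes(60, prefix = "b")
  # 10 anchors, then a 30-gene gap, then 10 anchors: exceeds max_gaps = 25
  orders <- c(0:9, 40:49)
  blocks <- chain_anchors(diagonal_hits(orders, orders), gt_a, gt_b)
  expect_equal(nrow(blocks$blocks), 2L)
  expect_equal(sort(blocks$blocks$n_pairs), c(10L, 10L))
  # with a permissive gap limit the same anchors form one chain
  wide <- chain_anchors(diagonal_hits(orders, orders), gt_a, gt_b,
                        chain_params(max_gaps = 40))
  expect_equal(nrow(wide$blocks), 1L)
  expect_equal(wide$blocks$n_pairs, 20L)
})

test_that("inverted blocks are found and pair orders stay monotone", {
  gt_a <- toy_genes(30, prefix = "a")
  gt_b <- toy_genes(30, prefix = "b")
  inv <- chain_anchors(diagonal_hits(0:7, 7:0), gt_a, gt_b)
  expect_equal(inv$blocks$orientation, "inverted")
  expect_equal(inv$blocks$n_pairs, 8L)
  sim <- small_sim(seed = 4)
  blocks <- chain_anchors(sim$hits_dup_out, sim$genes_dup, sim$genes_out)
  for (id in blocks$blocks$block_id) {
    p <- blocks$pairs[blocks$pairs$block_id == id, ]
    da <- diff(p$order_a)
    db <- diff(p$order_b)
    expect_true(all(da > 0))
    expect_true(all(db > 0) || all(db < 0))
  }
})

test_that("block filters implement both removal criteria", {
  gt_a <- toy_genes(40, prefix = "a")
  gt_b <- toy_genes(40, prefix = "b")
  # criterion 1: weak anchors -> block e-value above 1e-10
  weak <- chain_anchors(diagonal_hits(0:4, 0:4, evalue = 1e-1),
                        gt_a, gt_b, chain_params(evalue_cutoff = 1))
  expect_equal(weak$blocks$block_evalue, 1e-5)
  f1 <- filter_blocks(weak)
  expect_equal(nrow(f1$blocks), 0L)
  expect_equal(attr(f1, "removed")$criterion, "block_evalue")
  # criterion 2: 8 pairs, 5 of them weak (62.5% > 50%)
  mixed <- chain_anchors(diagonal_hits(0:7, 0:7,
                                       evalue = c(rep(1e-8, 5), rep(1e-30, 3))),
                         gt_a, gt_b, chain_params(evalue_cutoff = 1))
  f2 <- filter_blocks(mixed)
  expect_equal(nrow(f2$blocks), 0L)
  expect_equal(attr(f2, "removed")$criterion, "weak_pairs")
  # 12 strong pairs survive both criteria
  strong <- chain_anchors(diagonal_hits(0:11, 0:11, evalue = 1e-20),
                          gt_a, gt_b)
  f3 <- filter_blocks(strong)
  expect_equal(nrow(f3$blocks), 1L)
  # output is always a subset of input
  expect_true(all(f3$blocks$block_id %in% strong$blocks$block_id))
})

test_that("syntenic depth tallies counterpart regions per reference gene", {
  gt_a <- toy_genes(40, prefix = "a", chrom = c(rep("cA1", 20), rep("cA2", 20)))
  gt_b <- toy_genes(20, prefix = "b")
  # two duplicated-genome regions covering the same outgroup interval
  hits <- rbind(diagonal_hits(0:9, 0:9),
                toy_hits(paste0("a", 21:30), paste0("b", 1:10)))
  blocks <- chain_anchors(hits, gt_a, gt_b)
  expect_equal(nrow(blocks$blocks), 2L)
  d <- syntenic_depth(blocks, gt_b, "b")
  expect_equal(d$gene_count[d$ratio == "2:1"], 10L)
  expect_equal(d$gene_count[d$ratio == "0:1"], 10L)
  expect_equal(d$pct_covered[d$ratio == "2:1"], 100)
  # full-retention simulator: every covered outgroup gene at depth 2
  sim <- simulate_genomes(simulation_config(
    seed = 3, n_outgroup_genes = 400, retention = c(1, 1),
    rearrangement_events = 0L, tandem_fraction = 0,
    spurious_hit_fraction = 0, ancient_segments = 0L))
  sb <- chain_anchors(sim$hits_dup_out, sim$genes_dup, sim$genes_out)
  ds <- syntenic_depth(sb, sim$genes_out, "b")
  expect_equal(ds$pct_covered[ds$ratio == "2:1"], 100)
})

test_that("coverage percentages match the published arithmetic", {
  expect_equal(coverage_percentage(11108, 26873), 41.34)
  expect_equal(coverage_percentage(16509, 42341), 38.99)
  expect_equal(coverage_percentage(0, 100), 0)
  expect_error(coverage_percentage(5, 0), "positive")
  expect_error(coverage_percentage(101, 100), "n_total")
})

test_that("planted blocks are recovered exactly under clean conditions", {
  sim <- simulate_genomes(simulation_config(
    seed = 7, n_outgroup_genes = 400, retention = c(1, 1),
    rearrangement_events = 0L, tandem_fraction = 0,
    spurious_hit_fraction = 0, ancient_segments = 0L))
  blocks <- chain_anchors(sim$hits_dup_out, sim$genes_dup, sim$genes_out)
  # one block per (duplicated chromosome, outgroup chromosome) copy
  expect_equal(nrow(blocks$blocks), 2L * length(unique(sim$genes_out$chromosome)))
  # every anchor is a planted ancestor link and all are recovered
  expect_equal(nrow(blocks$pairs), nrow(sim$truth))
  expect_equal(sort(unique(blocks$pairs$gene_a)), sort(sim$truth$gene_id))
})

test_that("dot-plot export carries one row per anchor pair", {
  gt_a <- toy_genes(10, prefix = "a")
  gt_b <- toy_genes(10, prefix = "b")
  blocks <- chain_anchors(diagonal_hits(0:5, 0:5), gt_a, gt_b)
  dp <- dotplot_data(blocks)
  expect_equal(nrow(dp), 6L)
  expect_equal(dp$order_a, dp$order_b)
})
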