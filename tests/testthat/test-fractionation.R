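# minimal hand-made assignment: outgroup genes o1..o10, sg1 retains a given
# subset, sg2 another
toy_assignment <- function(sg1_anchors, sg2_anchors) {
  n <- length(sg1_anchors) + length(sg2_anchors)
  data.frame(
    gene_id = c(sprintf("x%d", seq_along(sg1_anchors)),
                sprintf("y%d", seq_along(sg2_anchors))),
    chromosome = rep_len("d1", n),
    subgenome = rep(c("subgenome1", "subgenome2"),
                    c(length(sg1_anchors), length(sg2_anchors))),
    class = rep_len("singleton", n), partner = rep_len(NA_character_, n),
    outgroup_anchor = c(sg1_anchors, sg2_anchors),
    high_confidence = rep_len(FALSE, n), stringsAsFactors = FALSE)
}

test_that("window retention covers the trivial regimes", {
  gt <- toy_genes(10, chrom = "o1", prefix = "o")
  all_in <- toy_assignment(paste0("o", 1:10), paste0("o", 1:10))
  w <- window_retention(gt, all_in, window = 5, step = 1)
  expect_equal(nrow(w), 6L)
  expect_true(all(w$retained_sg1 == 1 & w$retained_sg2 == 1 &
                    w$retained_both == 1))
  none <- toy_assignment(character(), character())
  w0 <- window_retention(gt, none, window = 5)
  expect_true(all(w0$retained_sg1 == 0 & w0$retained_both == 0))
  # short chromosome: one truncated window with a warning
  expect_warning(wt <- window_retention(gt, all_in, window = 50), "truncated")
  expect_equal(nrow(wt), 1L)
  # excluded (tandem) outgroup genes leave the denominator
  w2 <- window_retention(gt, all_in, window = 5, exclude = paste0("o", 1:5))
  expect_equal(nrow(w2), 1L)
})

test_that("window means track the planted retention probability", {
  sim <- simulate_genomes(simulation_config(
    seed = 13, n_outgroup_genes = 2000, n_chromosomes = 2L,
    retention = c(0.2, 0.2), rearrangement_events = 0L,
    ancient_segments = 0L, tandem_fraction = 0, spurious_hit_fraction = 0))
  blocks <- filter_blocks(chain_anchors(sim$hits_dup_out, sim$genes_dup,
                                        sim$genes_out))
  rp <- pair_homologous_regions(blocks, sim$genes_out)
  asg <- assign_subgenomes(rp, blocks, sim$genes_dup)
  w <- window_retention(sim$genes_out, asg, window = 100, step = 10)
  expect_lt(abs(mean(w$retained_sg1) - 0.2), 0.05)
  expect_lt(abs(mean(w$retained_sg2) - 0.2), 0.05)
  # invariant: both <= min(sg1, sg2) in every window
  expect_true(all(w$retained_both <= pmin(w$retained_sg1, w$retained_sg2)))
})

test_that("per-chromosome loss rates mirror whole-chromosome windows", {
  sim <- small_sim(seed = 14)
  sa <- small_assignment(sim)
  lr <- chromosome_loss_rates(sim$genes_out, sa$assignment)
  for (chr in lr$chromosome) {
    n <- sum(sim$genes_out$chromosome == chr)
    w <- window_retention(sim$genes_out[sim$genes_out$chromosome == chr, ],
                          sa$assignment, window = n)
    expect_equal(lr$raw_loss_sg1[lr$chromosome == chr], 1 - w$retained_sg1)
    expect_equal(lr$raw_loss_sg2[lr$chromosome == chr], 1 - w$retained_sg2)
  }
  # row invariants from the table's construction
  expect_true(all(lr$raw_loss_both <=
                    pmin(lr$raw_loss_sg1, lr$raw_loss_sg2) + 1e-12))
  expect_true(all(lr$raw_loss_both >=
                    lr$raw_loss_sg1 + lr$raw_loss_sg2 - 1 - 1e-12))
  expect_true(all(lr$difference >= 0))
})

test_that("loss-rate differences reproduce the published arithmetic", {
  # (sg1, sg2) rows of the published per-chromosome table
  expect_equal(loss_rate_difference(0.85, 0.85), 0)
  expect_equal(loss_rate_difference(0.83, 0.85), 0.02)
  expect_equal(loss_rate_difference(0.79, 0.83), 0.04)
  expect_equal(loss_rate_difference(0.78, 0.82), 0.04)
  # symmetry for any rate
  for (x in seq(0, 1, by = 0.1)) expect_equal(loss_rate_difference(x, x), 0)
  expect_error(loss_rate_difference(1.2, 0.5), "0, 1")
})

test_that("biased retention flips the loss-rate sign on every chromosome", {
  sim <- simulate_genomes(simulation_config(
    seed = 15, n_outgroup_genes = 4000, n_chromosomes = 2L,
    retention = c(0.63, 0.57), rearrangement_events = 0L,
    ancient_segments = 0L, tandem_fraction = 0, spurious_hit_fraction = 0))
  blocks <- filter_blocks(chain_anchors(sim$hits_dup_out, sim$genes_dup,
                                        sim$genes_out))
  rp <- pair_homologous_regions(blocks, sim$genes_out)
  asg <- assign_subgenomes(rp, blocks, sim$genes_dup)
  lr <- chromosome_loss_rates(sim$genes_out, asg)
  # the retained-more copy is subgenome 1 everywhere, so sg2 loses more
  expect_true(all(lr$raw_loss_sg2 > lr$raw_loss_sg1))
})
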