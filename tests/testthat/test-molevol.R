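test_that("NG86 handles forced cases and agrees with the oracle", {
  ident <- ng86_kaks("ATGGCT", "ATGGCT")
  expect_equal(ident$ka, 0)
  expect_equal(ident$ks, 0)
  # TTT -> TTC is one synonymous change (Phe -> Phe)
  phe <- ng86_kaks("TTT", "TTC")
  expect_equal(phe$s_diffs, 1)
  expect_equal(phe$n_diffs, 0)
  expect_gt(phe$ks, 0)
  expect_equal(phe$ka, 0)
  # two-codon toy pair against the pathway-enumeration oracle
  toy <- ng86_kaks("TTGGCA", "AGAGCA")
  orc <- oracle_ng86("TTGGCA", "AGAGCA")
  expect_equal(toy$ka, orc$ka, tolerance = 1e-12)
  expect_equal(toy$ks, orc$ks, tolerance = 1e-12)
  expect_equal(toy$s_sites, orc$s_sites, tolerance = 1e-12)
  # symmetry in the arguments
  fwd <- ng86_kaks("TTGGCATCA", "AGAGCTTCG")
  rev <- ng86_kaks("AGAGCTTCG", "TTGGCATCA")
  expect_equal(fwd$ka, rev$ka)
  expect_equal(fwd$ks, rev$ks)
  # gap-containing codons dropped pairwise; length errors raised
  gap <- ng86_kaks("TTT---AAA", "TTCGGGAAA")
  expect_equal(gap$n_codons, 2L)
  expect_error(ng86_kaks("TTT", "TTTAAA"), "length")
  expect_error(ng86_kaks("TTTA", "TTTG"), "multiple of 3")
})

test_that("sequences simulated at dN/dS 0.2 are estimated near 0.2", {
  pairs <- simulate_cds_pairs(6, 600, dnds = 0.2, ks_target = 0.5, seed = 11)
  est <- vapply(pairs, function(p) ng86_kaks(p$a, p$b)$ratio, 0)
  expect_lt(abs(mean(est) - 0.2), 0.05)
  # zero branch length leaves the pair identical
  same <- simulate_cds_pairs(1, 50, dnds = 1, ks_target = 0, seed = 1)[[1]]
  expect_identical(same$a, same$b)
})

test_that("block Ks is the median over finite pair values", {
  gt_a <- toy_genes(10, prefix = "a")
  gt_b <- toy_genes(10, prefix = "b")
  blocks <- chain_anchors(diagonal_hits(0:4, 0:4), gt_a, gt_b)
  kaks <- data.frame(gene_a = paste0("a", 1:5), gene_b = paste0("b", 1:5),
                     ks = c(0.1, 0.3, 0.5, Inf, NA))
  expect_equal(block_ks(blocks, kaks)$blocks$median_ks, 0.3)
  # single finite pair -> that value; all saturated -> NA
  kaks$ks <- c(0.2, Inf, Inf, Inf, Inf)
  expect_equal(block_ks(blocks, kaks)$blocks$median_ks, 0.2)
  kaks$ks <- rep(Inf, 5)
  expect_true(is.na(block_ks(blocks, kaks)$blocks$median_ks))
})

test_that("EM recovers mixture structure and log-likelihood behaves", {
  set.seed(42)
  one <- rnorm(300, 0.5, 0.05)
  f1 <- fit_ks_mixture(one, k = 1, seed = 1)
  expect_equal(f1$means, mean(one[one > 0 & one <= 3]), tolerance = 1e-6)
  draws <- simulate_ks_values(2000, seed = 9)
  f2 <- fit_ks_mixture(draws$ks, k = 2, seed = 1)
  expect_lt(abs(f2$means[1] - 0.404), 0.03)
  expect_lt(abs(f2$means[2] - 1.37), 0.05)
  # nesting: k = 2 fits bimodal data at least as well as k = 1
  f1b <- fit_ks_mixture(draws$ks, k = 1, seed = 1)
  expect_gte(f2$loglik, f1b$loglik)
  # EM log-likelihood is non-decreasing along the trace
  expect_true(all(diff(f2$loglik_trace) > -1e-6))
  expect_error(fit_ks_mixture(c(0.1, 0.2), k = 2), "at least")
  bic <- ks_mixture_bic(draws$ks, k_range = 1:3, seed = 1)
  expect_equal(which.min(bic$bic), 2L)
})

test_that("posterior rule separates recent from ancient blocks", {
  draws <- simulate_ks_values(1500, seed = 5)
  model <- fit_ks_mixture(draws$ks, k = 2, seed = 1)
  # blocks whose median Ks sits exactly on a component mean
  gt_a <- toy_genes(60, prefix = "a")
  gt_b <- toy_genes(60, prefix = "b")
  blocks <- chain_anchors(rbind(diagonal_hits(0:4, 0:4),
                                diagonal_hits(40:44, 40:44)), gt_a, gt_b)
  blocks$blocks$median_ks <- c(model$means[1], model$means[2])
  cls <- classify_blocks_by_ks(blocks, model)
  expect_equal(cls$recent$blocks$median_ks, model$means[1])
  expect_equal(cls$ancient$blocks$median_ks, model$means[2])
  # planted labels recovered on simulated block medians (3-sd separation)
  med <- c(rnorm(60, 0.404, 0.02), rnorm(60, 1.37, 0.05))
  post <- mixture_posterior(model, med)
  called_ancient <- post[, 2] > 0.5
  expect_gte(mean(called_ancient == rep(c(FALSE, TRUE), each = 60)), 0.95)
  # hard-interval mode
  blocks$blocks$median_ks <- c(0.4, 1.4)
  ci <- classify_blocks_by_ks(blocks, method = "interval",
                              interval = c(1.0, 2.0))
  expect_equal(ci$ancient$blocks$median_ks, 1.4)
})
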