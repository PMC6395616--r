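test_that("intergenic threshold is the mean of per-tissue medians", {
  m <- matrix(1, nrow = 5, ncol = 7)
  expect_equal(intergenic_threshold(m)$value, 1)
  expect_equal(intergenic_threshold(matrix(0, 3, 7))$value, 0)
  expect_error(intergenic_threshold(matrix(numeric(), 0, 0)), "at least")
  # exponential intergenic TPM: threshold ~ ln(2) * mean
  set.seed(31)
  mi <- matrix(rexp(5000 * 7, rate = 1 / 0.7), ncol = 7)
  expect_lt(abs(intergenic_threshold(mi)$value - log(2) * 0.7), 0.03)
})

test_that("expression breadth uses a strict threshold rule", {
  expect_equal(expression_breadth(rep(1, 7), 0.715), 100)
  expect_equal(expression_breadth(rep(0, 7), 0.715), 0)
  # 0.71 and exactly-threshold values do not count as expressed
  tpm <- c(1.0, 0.5, 0.8, 0.2, 2.0, 0.71, 0.72)
  expect_equal(expression_breadth(tpm, 0.715), 100 * 4 / 7, tolerance = 1e-9)
  expect_equal(expression_breadth(c(0.715, 1), 0.715), 50)
  m <- rbind(a = c(1, 1, 0), b = c(0, 0, 0))
  expect_equal(unname(expression_breadth(m, 0.5)), c(200 / 3, 0))
})

test_that("dominance classification follows the strict twofold rule", {
  expect_equal(classify_dominance(10, 4, threshold = 0.715), "dominant_sg1")
  # exactly twofold is conserved ("more than" is strict)
  expect_equal(classify_dominance(4, 8, threshold = 0.715), "conserved")
  expect_equal(classify_dominance(0, 0, threshold = 0.715), "both_silent")
  expect_equal(classify_dominance(0.5, 0.7, threshold = 0.715), "both_silent")
  # zero against an expressed member is dominant, not an error
  expect_equal(classify_dominance(0, 5, threshold = 0.715), "dominant_sg2")
  # antisymmetry under swapping the members
  a <- c(10, 4, 0, 3, 8); b <- c(4, 8, 0, 9, 8)
  fwd <- classify_dominance(a, b, threshold = 0.715)
  swp <- classify_dominance(b, a, threshold = 0.715)
  flip <- c(dominant_sg1 = "dominant_sg2", dominant_sg2 = "dominant_sg1",
            conserved = "conserved", both_silent = "both_silent")
  expect_equal(unname(flip[fwd]), swp)
  expect_error(classify_dominance(-1, 2), "non-negative")
})

test_that("dominance summaries partition pair-tissue calls", {
  calls <- data.frame(
    tissue = rep(c("t1", "t2"), each = 2),
    class = c("conserved", "conserved", "dominant_sg2", "both_silent"))
  s <- dominance_summary(calls)
  expect_equal(s$conserved, c(100, 0))
  expect_equal(s$dominant_sg2, c(0, 50))
  expect_equal(rowSums(s[, c("dominant_sg1", "dominant_sg2", "conserved",
                             "both_silent")]), c(1, 2) * 0 + 100)
})

test_that("a planted twofold effect fraction is recovered", {
  sim <- small_sim(seed = 33, n = 2000, dominance_fraction = 0.25,
                   dominance_fold = 4)
  ex <- simulate_expression(sim)
  tr <- sim$truth
  pairs <- tr[tr$class == "homeolog" & tr$copy == "A", ]
  th <- intergenic_threshold(ex$tpm_intergenic)
  cls <- classify_dominance(ex$tpm[pairs$gene_id, 1],
                            ex$tpm[pairs$partner, 1], threshold = th)
  est <- mean(cls %in% c("dominant_sg1", "dominant_sg2"))
  expect_lt(abs(est - 0.25), 0.04)
  # with no effect, dominance is rare and symmetric between the copies
  sim0 <- small_sim(seed = 34, n = 2000)
  ex0 <- simulate_expression(sim0)
  pairs0 <- sim0$truth[sim0$truth$class == "homeolog" &
                         sim0$truth$copy == "A", ]
  cls0 <- classify_dominance(ex0$tpm[pairs0$gene_id, 1],
                             ex0$tpm[pairs0$partner, 1], threshold = th)
  expect_lt(mean(cls0 %in% c("dominant_sg1", "dominant_sg2")), 0.02)
})

test_that("2^-ddCt reproduces its defining arithmetic", {
  expect_equal(relative_expression_ddct(20, 18, 22, 20), 1)   # ddCt = 0
  expect_equal(relative_expression_ddct(21, 18, 22, 20), 0.5) # ddCt = 1
  expect_equal(relative_expression_ddct(18, 18, 22, 20), 4)   # ddCt = -2
  expect_error(relative_expression_ddct(-1, 18, 22, 20), "positive")
})
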