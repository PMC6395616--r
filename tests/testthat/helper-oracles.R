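# Independent brute-force NG86 oracle. Uses Biostrings' genetic code table
# and naive recursive pathway enumeration; shares only the published
# conventions with the implementation (stop-codon changes nonsynonymous,
# stop-passing pathways excluded when avoidable, Jukes-Cantor correction).
oracle_ng86 <- function(a, b) {
  code <- Biostrings::GENETIC_CODE
  bases <- c("A", "C", "G", "T")
  codons_a <- substring(a, seq(1, nchar(a), 3), seq(3, nchar(a), 3))
  codons_b <- substring(b, seq(1, nchar(b), 3), seq(3, nchar(b), 3))
  keep <- code[codons_a] != "*" & code[codons_b] != "*"
  codons_a <- codons_a[keep]; codons_b <- codons_b[keep]
  syn_sites <- function(codon) {
    s <- 0
    for (pos in 1:3) {
      for (nb in setdiff(bases, substr(codon, pos, pos))) {
        mut <- codon
        substr(mut, pos, pos) <- nb
        if (code[[mut]] == code[[codon]]) s <- s + 1 / 3
      }
    }
    s
  }
  paths <- function(cur, target) {
    dp <- which(strsplit(cur, "")[[1]] != strsplit(target, "")[[1]])
    if (!length(dp)) return(list(list(sy = 0, ns = 0, stopped = FALSE)))
    out <- list()
    for (pos in dp) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(target, pos, pos)
      step_syn <- code[[nxt]] == code[[cur]]
      stopped <- code[[nxt]] == "*" && nxt != target
      for (tail in paths(nxt, target)) {
        out[[length(out) + 1]] <- list(
          sy = tail$sy + step_syn, ns = tail$ns + !step_syn,
          stopped = stopped || tail$stopped)
      }
    }
    out
  }
  S <- (sum(vapply(codons_a, syn_sites, 0)) +
          sum(vapply(codons_b, syn_sites, 0))) / 2
  N <- 3 * length(codons_a) - S
  sd_ <- 0; nd_ <- 0
  for (i in seq_along(codons_a)) {
    pp <- paths(codons_a[i], codons_b[i])
    ok <- !vapply(pp, `[[`, FALSE, "stopped")
    if (!any(ok)) ok <- rep(TRUE, length(pp))
    sd_ <- sd_ + mean(vapply(pp[ok], `[[`, 0, "sy"))
    nd_ <- nd_ + mean(vapply(pp[ok], `[[`, 0, "ns"))
  }
  jc <- function(p) if (p >= 0.75) Inf else -0.75 * log(1 - 4 * p / 3)
  list(ka = jc(nd_ / N), ks = jc(sd_ / S), s_sites = S, n_sites = N)
}

random_codons <- function(n, rng) {
  non_stop <- setdiff(names(Biostrings::GENETIC_CODE),
                      c("TAA", "TAG", "TGA"))
  paste(sample(non_stop, n, replace = TRUE), collapse = "")
}


# brute-force exact oracle: enumerate every split of the combined ranks
oracle_mwu_exact <- function(a, b) {
  na <- length(a); n <- na + length(b)
  r <- rank(c(a, b))
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  splits <- utils::combn(n, na)
  us <- apply(splits, 2, function(ix) sum(r[ix])) - na * (na + 1) / 2
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

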