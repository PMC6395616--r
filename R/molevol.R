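# Standard (universal) genetic code, codon -> amino acid (stop = "*").
.GENETIC_CODE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L", CTT = "L", CTC = "L",
  CTA = "L", CTG = "L", ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V", TCT = "S", TCC = "S",
  TCA = "S", TCG = "S", CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T", GCT = "A", GCC = "A",
  GCA = "A", GCG = "A", TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q", AAT = "N", AAC = "N",
  AAA = "K", AAG = "K", GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W", CGT = "R", CGC = "R",
  CGA = "R", CGG = "R", AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G")

.BASES <- c("T", "C", "A", "G")

#' Translate a codon under the universal genetic code
#' @param codon character vector of 3-letter codons.
#' @return amino-acid letters, `"*"` for stops, `NA` for unknown codons.
#' @export
translate_codon <- function(codon) {
  unname(.GENETIC_CODE[toupper(codon)])
}

# Synonymous site count of one codon: for each position, the fraction of the
# three possible single-nucleotide changes that are synonymous. Changes to
# stop codons count as nonsynonymous.
.syn_sites_codon <- function(codon) {
  aa <- .GENETIC_CODE[[codon]]
  s <- 0
  chars <- strsplit(codon, "")[[1L]]
  for (pos in 1:3) {
    for (b in setdiff(.BASES, chars[pos])) {
      mut <- chars
      mut[pos] <- b
      mut_aa <- .GENETIC_CODE[[paste(mut, collapse = "")]]
      if (mut_aa == aa) s <- s + 1 / 3
    }
  }
  s
}

# Average synonymous / nonsynonymous difference counts between two codons
# over all minimal mutational pathways. Pathways passing through a stop
# codon are excluded; if every pathway passes through a stop, all pathways
# are used. Returns c(syn, nonsyn).
.codon_path_diffs <- function(ca, cb) {
  a <- strsplit(ca, "")[[1L]]
  b <- strsplit(cb, "")[[1L]]
  diff_pos <- which(a != b)
  nd <- length(diff_pos)
  if (nd == 0L) return(c(0, 0))
  perms <- if (nd == 1L) list(diff_pos) else {
    if (nd == 2L) {
      list(diff_pos, rev(diff_pos))
    } else {
      idx <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                  c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
      lapply(idx, function(i) diff_pos[i])
    }
  }
  count_path <- function(path) {
    cur <- a
    sy <- 0; ns <- 0; through_stop <- FALSE
    for (pos in path) {
      nxt <- cur
      nxt[pos] <- b[pos]
      aa1 <- .GENETIC_CODE[[paste(cur, collapse = "")]]
      aa2 <- .GENETIC_CODE[[paste(nxt, collapse = "")]]
      if (aa2 == "*" && !identical(nxt, b)) through_stop <- TRUE
      if (aa1 == aa2) sy <- sy + 1 else ns <- ns + 1
      cur <- nxt
    }
    c(sy, ns, through_stop)
  }
  res <- vapply(perms, count_path, numeric(3))
  ok <- res[3, ] == 0
  if (!any(ok)) ok <- rep(TRUE, ncol(res))
  c(mean(res[1, ok]), mean(res[2, ok]))
}

# memoised per-codon-pair tables, filled lazily
.ng86_cache <- new.env(parent = emptyenv())

.codon_diffs_cached <- function(ca, cb) {
  key <- paste0(ca, cb)
  val <- .ng86_cache[[key]]
  if (is.null(val)) {
    val <- .codon_path_diffs(ca, cb)
    .ng86_cache[[key]] <- val
  }
  val
}

.syn_sites_cached <- function(codon) {
  key <- paste0("S_", codon)
  val <- .ng86_cache[[key]]
  if (is.null(val)) {
    val <- .syn_sites_codon(codon)
    .ng86_cache[[key]] <- val
  }
  val
}

#' Ka/Ks by the NG86 counting method
#'
#' Nei-Gojobori (1986) counting: per-codon synonymous site fractions are
#' averaged over both sequences; observed differences are classified by
#' averaging over all minimal mutational pathways between each codon pair
#' (pathways through stop codons excluded when any stop-free pathway
#' exists); proportions are corrected for multiple hits with the
#' Jukes-Cantor formula `d = -3/4 * log(1 - 4p/3)`. Codons containing a gap
#' (`-`) in either sequence are dropped pairwise, as are codon pairs where
#' either codon is a stop. A proportion of 3/4 or more is reported as `Inf`
#' with `saturated = TRUE`.
#'
#' @param cds_a,cds_b aligned coding sequences (equal length, multiple of 3),
#'   as single strings or character vectors of single letters.
#' @return list of class `kaks_result` with `ka`, `ks`, `ratio`,
#'   `n_sites`, `s_sites`, `n_diffs`, `s_diffs`, `n_codons`, `saturated`.
#' @export
ng86_kaks <- function(cds_a, cds_b) {
  a <- .as_base_vector(cds_a)
  b <- .as_base_vector(cds_b)
  if (length(a) != length(b)) stop("sequences differ in length")
  if (length(a) %% 3L != 0L) stop("sequence length not a multiple of 3")
  ca <- .split_codons(a)
  cb <- .split_codons(b)
  keep <- !grepl("-", ca) & !grepl("-", cb)
  ca <- ca[keep]; cb <- cb[keep]
  if (any(is.na(.GENETIC_CODE[ca])) || any(is.na(.GENETIC_CODE[cb]))) {
    stop("non-ACGT character in coding sequence")
  }
  stops <- .GENETIC_CODE[ca] == "*" | .GENETIC_CODE[cb] == "*"
  ca <- ca[!stops]; cb <- cb[!stops]
  if (!length(ca)) stop("no comparable codons")
  s_a <- vapply(ca, .syn_sites_cached, numeric(1))
  s_b <- vapply(cb, .syn_sites_cached, numeric(1))
  s_sites <- (sum(s_a) + sum(s_b)) / 2
  n_sites <- 3 * length(ca) - s_sites
  diffs <- mapply(.codon_diffs_cached, ca, cb)
  s_diffs <- sum(diffs[1, ])
  n_diffs <- sum(diffs[2, ])
  ps <- if (s_sites > 0) s_diffs / s_sites else 0
  pn <- if (n_sites > 0) n_diffs / n_sites else 0
  jc <- function(p) if (p >= 0.75) Inf else -0.75 * log(1 - 4 * p / 3)
  ks <- jc(ps)
  ka <- jc(pn)
  structure(list(ka = ka, ks = ks,
                 ratio = if (is.finite(ks) && ks > 0) ka / ks else NA_real_,
                 n_sites = n_sites, s_sites = s_sites,
                 n_diffs = n_diffs, s_diffs = s_diffs,
                 n_codons = length(ca),
                 saturated = !is.finite(ka) || !is.finite(ks)),
            class = "kaks_result")
}

#' @export
print.kaks_result <- function(x, ...) {
  cat(sprintf("NG86: Ka = %.4f (N = %.1f), Ks = %.4f (S = %.1f), Ka/Ks = %s\n",
              x$ka, x$n_sites, x$ks, x$s_sites,
              ifelse(is.na(x$ratio), "NA", sprintf("%.4f", x$ratio))))
  invisible(x)
}

.as_base_vector <- function(x) {
  if (length(x) == 1L && nchar(x) > 1L) x <- strsplit(x, "")[[1L]]
  toupper(x)
}

.split_codons <- function(x) {
  n <- length(x) %/% 3L
  vapply(seq_len(n), function(i) paste(x[(3 * i - 2):(3 * i)], collapse = ""),
         character(1))
}

#' Summarise block Ks as the median of finite pair Ks values
#'
#' @param blocks a [synteny_blocks()] object.
#' @param kaks data.frame with `gene_a`, `gene_b`, `ks` for anchor pairs.
#' @return `blocks` with `median_ks` filled per block (NA when every pair of
#'   a block is saturated / missing; such blocks are excluded from mixture
#'   fitting downstream).
#' @export
block_ks <- function(blocks, kaks) {
  key <- paste(kaks$gene_a, kaks$gene_b, sep = "\r")
  ksv <- kaks$ks[match(paste(blocks$pairs$gene_a, blocks$pairs$gene_b,
                             sep = "\r"), key)]
  med <- vapply(blocks$blocks$block_id, function(id) {
    v <- ksv[blocks$pairs$block_id == id]
    v <- v[is.finite(v)]
    if (!length(v)) NA_real_ else stats::median(v)
  }, numeric(1))
  blocks$blocks$median_ks <- med
  blocks
}

#' Fit a one-dimensional Gaussian mixture to Ks values by EM
#'
#' Used to locate the synonymous-divergence peaks of syntenic-block Ks
#' distributions (e.g. a speciation peak and an older WGD peak). Values above
#' `ks_cap` are excluded as saturated before fitting. Initialisation is by
#' quantile (k-means-style) partition; EM iterates until the log-likelihood
#' gain drops below `tol`. A degenerate component (sd < 1e-4) triggers a
#' restart with jittered initialisation, up to 5 restarts.
#'
#' @param ks numeric vector of Ks values (finite, > 0).
#' @param k number of components (default 2).
#' @param seed integer seed for restarts.
#' @param max_iter maximum EM iterations.
#' @param tol log-likelihood convergence tolerance.
#' @param ks_cap saturation cap (default 3).
#' @return object of class `ks_mixture`: `k`, `weights`, `means`, `sds`
#'   (components sorted by ascending mean), `loglik`, `n`, `converged`,
#'   `loglik_trace`.
#' @export
fit_ks_mixture <- function(ks, k = 2L, seed = 1L, max_iter = 500L,
                           tol = 1e-8, ks_cap = 3) {
  x <- ks[is.finite(ks) & ks > 0 & ks <= ks_cap]
  n <- length(x)
  if (n < 10L * k) stop("need at least 10*k Ks values, got ", n)
  for (restart in 0:5) {
    if (restart == 5L) stop("EM failed: degenerate component after 5 restarts")
    set.seed(seed + restart)
    xs <- sort(x)
    cut_id <- ceiling(seq_along(xs) / (n / k))
    if (restart > 0L) {
      cut_id <- sort(sample.int(k, n, replace = TRUE))
    }
    mu <- vapply(1:k, function(j) mean(xs[cut_id == j]), numeric(1))
    sdv <- vapply(1:k, function(j) {
      s <- stats::sd(xs[cut_id == j])
      if (!is.finite(s) || s < 1e-3) 1e-3 else s
    }, numeric(1))
    w <- rep(1 / k, k)
    ll_old <- -Inf
    trace <- numeric(0)
    degenerate <- FALSE
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      dens <- vapply(1:k, function(j) w[j] * stats::dnorm(x, mu[j], sdv[j]),
                     numeric(n))
      if (is.null(dim(dens))) dens <- matrix(dens, nrow = n)
      tot <- rowSums(dens)
      tot[tot == 0] <- .Machine$double.xmin
      resp <- dens / tot
      ll <- sum(log(tot))
      trace <- c(trace, ll)
      nk <- colSums(resp)
      w <- nk / n
      mu <- colSums(resp * x) / nk
      sdv <- sqrt(colSums(resp * (x - rep(mu, each = n))^2) / nk)
      if (any(!is.finite(sdv)) || any(sdv < 1e-4)) {
        degenerate <- TRUE
        break
      }
      if (ll - ll_old < tol && it > 1L) {
        converged <- TRUE
        break
      }
      ll_old <- ll
    }
    if (!degenerate) break
  }
  o <- order(mu)
  structure(list(k = k, weights = w[o], means = mu[o], sds = sdv[o],
                 loglik = trace[length(trace)], n = n,
                 converged = converged, loglik_trace = trace),
            class = "ks_mixture")
}

#' @export
print.ks_mixture <- function(x, ...) {
  cat(sprintf("Gaussian mixture (k = %d, n = %d, loglik = %.2f)\n",
              x$k, x$n, x$loglik))
  for (j in seq_len(x$k)) {
    cat(sprintf("  component %d: weight %.3f, mean %.3f, sd %.3f\n",
                j, x$weights[j], x$means[j], x$sds[j]))
  }
  invisible(x)
}

#' Posterior component probabilities under a fitted Ks mixture
#'
#' @param model a [fit_ks_mixture()] result.
#' @param x numeric vector of Ks values.
#' @return matrix `length(x)` x `k` of posterior probabilities.
#' @export
mixture_posterior <- function(model, x) {
  dens <- vapply(seq_len(model$k), function(j) {
    model$weights[j] * stats::dnorm(x, model$means[j], model$sds[j])
  }, numeric(length(x)))
  if (is.null(dim(dens))) dens <- matrix(dens, nrow = length(x))
  tot <- rowSums(dens)
  tot[tot == 0] <- .Machine$double.xmin
  dens / tot
}

#' BIC across component counts for a Ks mixture
#'
#' @param ks numeric Ks values.
#' @param k_range integer vector of component counts to evaluate.
#' @param seed seed passed to each fit.
#' @param ... further arguments to [fit_ks_mixture()].
#' @return data.frame with `k`, `loglik`, `bic`.
#' @export
ks_mixture_bic <- function(ks, k_range = 1:4, seed = 1L, ...) {
  rows <- lapply(k_range, function(k) {
    fit <- fit_ks_mixture(ks, k = k, seed = seed, ...)
    p <- 3 * k - 1
    data.frame(k = k, loglik = fit$loglik,
               bic = -2 * fit$loglik + p * log(fit$n))
  })
  do.call(rbind, rows)
}

#' Split blocks into recent and ancient cohorts by Ks
#'
#' A block is called ancient when the posterior probability of the ancient
#' mixture component at its median Ks exceeds 0.5 (default), or, in
#' `"interval"` mode, when its median Ks falls inside a hard Ks interval.
#' Blocks without a median Ks are excluded with a warning.
#'
#' @param blocks a [synteny_blocks()] object with `median_ks` filled.
#' @param model a [fit_ks_mixture()] result (posterior mode).
#' @param ancient_component index of the ancient component (default: the
#'   component with the largest mean).
#' @param method `"posterior"` or `"interval"`.
#' @param interval length-2 numeric Ks interval for `"interval"` mode.
#' @return list with `recent` and `ancient` [synteny_blocks()] objects.
#' @export
classify_blocks_by_ks <- function(blocks, model = NULL,
                                  ancient_component = NULL,
                                  method = c("posterior", "interval"),
                                  interval = NULL) {
  method <- match.arg(method)
  b <- blocks$blocks
  has_ks <- is.finite(b$median_ks)
  if (any(!has_ks)) {
    warning(sum(!has_ks), " block(s) without median Ks excluded")
  }
  if (method == "posterior") {
    if (is.null(model)) stop("posterior mode requires a fitted mixture model")
    if (is.null(ancient_component)) ancient_component <- which.max(model$means)
    post <- mixture_posterior(model, b$median_ks[has_ks])
    ancient <- logical(nrow(b))
    ancient[has_ks] <- post[, ancient_component] > 0.5
  } else {
    if (is.null(interval) || length(interval) != 2L) {
      stop("interval mode requires a length-2 Ks interval")
    }
    ancient <- logical(nrow(b))
    ancient[has_ks] <- b$median_ks[has_ks] >= interval[1L] &
      b$median_ks[has_ks] <= interval[2L]
  }
  subset_blocks <- function(keep) {
    synteny_blocks(b[keep, , drop = FALSE],
                   blocks$pairs[blocks$pairs$block_id %in% b$block_id[keep], ,
                                drop = FALSE])
  }
  list(recent = subset_blocks(has_ks & !ancient),
       ancient = subset_blocks(ancient))
}
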