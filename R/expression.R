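#' Expression threshold from intergenic TPM
#'
#' The threshold separating "expressed" from background is the mean over
#' tissues of the median intergenic TPM of each tissue (the analog of the
#' published 0.715, which is data-dependent and always recomputed).
#'
#' @param intergenic_tpm numeric matrix, intergenic regions x tissues.
#' @return list of class `expression_threshold` with `value` and
#'   `per_tissue_medians`.
#' @export
intergenic_threshold <- function(intergenic_tpm) {
  if (is.null(dim(intergenic_tpm)) || nrow(intergenic_tpm) < 1L ||
      ncol(intergenic_tpm) < 1L) {
    stop("intergenic TPM matrix must have at least one region and one tissue")
  }
  med <- apply(intergenic_tpm, 2L, stats::median)
  structure(list(value = mean(med), per_tissue_medians = med),
            class = "expression_threshold")
}

#' @export
print.expression_threshold <- function(x, ...) {
  cat(sprintf("expression threshold: %.4g (mean of %d per-tissue medians)\n",
              x$value, length(x$per_tissue_medians)))
  invisible(x)
}

#' Expression breadth of genes
#'
#' Percentage of surveyed tissues in which a gene's TPM strictly exceeds the
#' threshold.
#'
#' @param tpm numeric matrix (genes x tissues) or a single gene's vector.
#' @param threshold TPM threshold (number or [intergenic_threshold()] result).
#' @return numeric vector of percentages in `[0, 100]`.
#' @export
expression_breadth <- function(tpm, threshold) {
  if (inherits(threshold, "expression_threshold")) threshold <- threshold$value
  if (is.null(dim(tpm))) tpm <- matrix(tpm, nrow = 1L)
  100 * rowSums(tpm > threshold) / ncol(tpm)
}

#' Classify homeolog expression dominance in one tissue
#'
#' A pair with both members at or below the threshold is `both_silent`.
#' Otherwise, a strictly more-than-`fold` difference makes the
#' higher-expressed member dominant (`dominant_sg1` / `dominant_sg2`);
#' a difference of exactly `fold` or less is `conserved`. A zero opposite
#' an expressed member is dominant (guarded by `eps`).
#'
#' @param tpm_sg1,tpm_sg2 TPM of the subgenome-1 and subgenome-2 member
#'   (vectorised).
#' @param fold fold-change cutoff (default 2; strict inequality).
#' @param threshold expression threshold (number or
#'   [intergenic_threshold()] result).
#' @param eps divide-by-zero guard.
#' @return character vector of `dominant_sg1`, `dominant_sg2`, `conserved`,
#'   `both_silent`.
#' @export
classify_dominance <- function(tpm_sg1, tpm_sg2, fold = 2,
                               threshold = 0, eps = 1e-9) {
  if (inherits(threshold, "expression_threshold")) threshold <- threshold$value
  if (any(tpm_sg1 < 0) || any(tpm_sg2 < 0)) stop("TPM must be non-negative")
  hi <- pmax(tpm_sg1, tpm_sg2)
  lo <- pmin(tpm_sg1, tpm_sg2)
  ratio <- hi / pmax(lo, eps)
  cls <- ifelse(tpm_sg1 <= threshold & tpm_sg2 <= threshold, "both_silent",
         ifelse(ratio <= fold, "conserved",
         ifelse(tpm_sg1 > tpm_sg2, "dominant_sg1", "dominant_sg2")))
  cls
}

#' Per-tissue dominance class percentages
#'
#' @param calls data.frame with columns `tissue` and `class` (one row per
#'   homeolog pair and tissue), e.g. built from [classify_dominance()].
#' @return data.frame with `tissue`, `dominant_sg1`, `dominant_sg2`,
#'   `conserved`, `both_silent` (percentages summing to 100 per tissue) and
#'   `n_pairs`.
#' @export
dominance_summary <- function(calls) {
  lv <- c("dominant_sg1", "dominant_sg2", "conserved", "both_silent")
  rows <- lapply(unique(calls$tissue), function(t) {
    cl <- calls$class[calls$tissue == t]
    pct <- 100 * vapply(lv, function(x) mean(cl == x), numeric(1))
    out <- data.frame(tissue = t, stringsAsFactors = FALSE)
    out[lv] <- as.list(pct)
    out$n_pairs <- length(cl)
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Relative expression by the 2^-ddCt method
#'
#' `2^-((Ct_target,sample - Ct_ref,sample) - (Ct_target,calibrator -
#' Ct_ref,calibrator))`.
#'
#' @param ct_target_sample,ct_ref_sample Ct of target and reference gene in
#'   the sample of interest.
#' @param ct_target_calibrator,ct_ref_calibrator Ct of target and reference
#'   gene in the calibrator sample.
#' @return fold change (vectorised).
#' @export
relative_expression_ddct <- function(ct_target_sample, ct_ref_sample,
                                     ct_target_calibrator,
                                     ct_ref_calibrator) {
  if (any(c(ct_target_sample, ct_ref_sample, ct_target_calibrator,
            ct_ref_calibrator) <= 0)) {
    stop("Ct values must be positive")
  }
  ddct <- (ct_target_sample - ct_ref_sample) -
    (ct_target_calibrator - ct_ref_calibrator)
  2^(-ddct)
}
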