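# Per-outgroup-gene retention flags derived from a subgenome assignment:
# an outgroup gene is "retained in subgenome X" when some duplicated-genome
# gene labelled X carries it as outgroup anchor.
.retention_flags <- function(genes_out, assignment, exclude = character()) {
  asg <- assignment[!is.na(assignment$outgroup_anchor) &
                      assignment$subgenome %in% c("subgenome1", "subgenome2"), ,
                    drop = FALSE]
  keep <- !(genes_out$gene_id %in% exclude)
  out <- data.frame(
    gene_id = genes_out$gene_id,
    chromosome = genes_out$chromosome,
    order_index = genes_out$order_index,
    sg1 = genes_out$gene_id %in%
      asg$outgroup_anchor[asg$subgenome == "subgenome1"],
    sg2 = genes_out$gene_id %in%
      asg$outgroup_anchor[asg$subgenome == "subgenome2"],
    stringsAsFactors = FALSE)
  out[keep, , drop = FALSE]
}

#' Sliding-window gene retention along outgroup chromosomes
#'
#' For windows of `window` outgroup genes (stepped by `step` genes along each
#' chromosome), computes the fraction of outgroup genes with a retained
#' ortholog in subgenome 1, in subgenome 2, and in both. Chromosomes shorter
#' than the window yield a single truncated window with a warning.
#'
#' @param genes_out outgroup [gene_table()].
#' @param assignment a subgenome assignment table (see [assign_subgenomes()]).
#' @param window window size in genes (default 100).
#' @param step step size in genes (default 1).
#' @param exclude outgroup gene ids to drop first (e.g. tandem duplicates).
#' @return data.frame with `chromosome`, `window_start` (order index of the
#'   first gene), `retained_sg1`, `retained_sg2`, `retained_both`.
#' @export
window_retention <- function(genes_out, assignment, window = 100L, step = 1L,
                             exclude = character()) {
  fl <- .retention_flags(genes_out, assignment, exclude)
  rows <- list()
  for (chr in unique(fl$chromosome)) {
    f <- fl[fl$chromosome == chr, , drop = FALSE]
    f <- f[order(f$order_index), , drop = FALSE]
    m <- nrow(f)
    w <- window
    if (m < window) {
      warning("chromosome ", chr, " shorter than window; single truncated window")
      w <- m
    }
    starts <- seq(1L, m - w + 1L, by = step)
    c1 <- cumsum(c(0L, f$sg1))
    c2 <- cumsum(c(0L, f$sg2))
    cb <- cumsum(c(0L, f$sg1 & f$sg2))
    rows[[chr]] <- data.frame(
      chromosome = chr,
      window_start = f$order_index[starts],
      retained_sg1 = (c1[starts + w] - c1[starts]) / w,
      retained_sg2 = (c2[starts + w] - c2[starts]) / w,
      retained_both = (cb[starts + w] - cb[starts]) / w,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-chromosome gene loss rates of the two subgenomes
#'
#' For each outgroup chromosome, the loss rate of subgenome X is the fraction
#' of outgroup genes with no retained ortholog in subgenome X; `loss_both` is
#' the fraction lost from both. Rates are rounded half-up to 2 decimals for
#' reporting; the difference column is computed from the unrounded rates and
#' then rounded (so it can differ from the difference of the rounded rates).
#'
#' @inheritParams window_retention
#' @return data.frame with `chromosome`, `outgroup_genes`, `loss_sg1`,
#'   `loss_sg2`, `loss_both`, `difference`, plus unrounded columns prefixed
#'   `raw_`.
#' @export
chromosome_loss_rates <- function(genes_out, assignment,
                                  exclude = character()) {
  fl <- .retention_flags(genes_out, assignment, exclude)
  rows <- lapply(unique(fl$chromosome), function(chr) {
    f <- fl[fl$chromosome == chr, , drop = FALSE]
    if (!nrow(f)) return(NULL)
    l1 <- mean(!f$sg1)
    l2 <- mean(!f$sg2)
    lb <- mean(!f$sg1 & !f$sg2)
    data.frame(chromosome = chr, outgroup_genes = nrow(f),
               loss_sg1 = .round2(l1), loss_sg2 = .round2(l2),
               loss_both = .round2(lb),
               difference = .round2(abs(l1 - l2)),
               raw_loss_sg1 = l1, raw_loss_sg2 = l2, raw_loss_both = lb,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# round half-up to 2 decimals (R's round() is banker's rounding)
.round2 <- function(x) floor(x * 100 + 0.5) / 100

#' Absolute loss-rate difference between subgenomes
#'
#' @param r1,r2 loss-rate fractions in `[0, 1]`.
#' @return `|r1 - r2|` rounded half-up to 2 decimals.
#' @export
loss_rate_difference <- function(r1, r2) {
  if (any(r1 < 0 | r1 > 1) || any(r2 < 0 | r2 > 1)) {
    stop("loss rates must lie in [0, 1]")
  }
  .round2(abs(r1 - r2))
}
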