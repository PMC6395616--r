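#' Container for syntenic blocks
#'
#' Bundles a per-block summary table with the per-anchor-pair table. Created
#' by [chain_anchors()] or [read_collinearity()].
#'
#' @param blocks data.frame with columns `block_id`, `chrom_a`, `chrom_b`,
#'   `orientation`, `n_pairs`, `score`, `block_evalue`, `median_ks`.
#' @param pairs data.frame with columns `block_id`, `gene_a`, `gene_b`,
#'   `evalue`, `order_a`, `order_b`.
#' @return object of class `synteny_blocks`.
#' @export
synteny_blocks <- function(blocks, pairs) {
  if (is.null(blocks)) {
    blocks <- data.frame(block_id = integer(), chrom_a = character(),
                         chrom_b = character(), orientation = character(),
                         n_pairs = integer(), score = numeric(),
                         block_evalue = numeric(), median_ks = numeric(),
                         stringsAsFactors = FALSE)
    pairs <- data.frame(block_id = integer(), gene_a = character(),
                        gene_b = character(), evalue = numeric(),
                        order_a = integer(), order_b = integer(),
                        stringsAsFactors = FALSE)
  }
  structure(list(blocks = blocks, pairs = pairs), class = "synteny_blocks")
}

#' @export
print.synteny_blocks <- function(x, ...) {
  cat(sprintf("synteny_blocks: %d blocks, %d anchor pairs\n",
              nrow(x$blocks), nrow(x$pairs)))
  invisible(x)
}

#' Chaining parameters
#'
#' Defaults follow the standard collinearity-detection parameterisation:
#' `match_score` 50, `match_size` 5 (minimum anchor pairs per block),
#' `gap_penalty` -1 per unit of gene-rank gap, `overlap_window` 5,
#' `max_gaps` 25, and an anchor E-value cutoff of 1e-5.
#'
#' @param match_score score earned per chained anchor pair.
#' @param match_size minimum anchor pairs for a reported block.
#' @param gap_penalty (negative) penalty per skipped gene rank on either genome.
#' @param overlap_window chains on one chromosome pair overlapping by more
#'   than this many genes are merged when compatible, else trimmed.
#' @param max_gaps maximum gene-rank gap allowed for a chain extension.
#' @param evalue_cutoff anchors at or above this E-value are ignored.
#' @return list of class `chain_params`.
#' @export
chain_params <- function(match_score = 50, match_size = 5, gap_penalty = -1,
                         overlap_window = 5, max_gaps = 25,
                         evalue_cutoff = 1e-5) {
  stopifnot(match_size >= 2, max_gaps >= 0, gap_penalty <= 0)
  structure(list(match_score = match_score, match_size = match_size,
                 gap_penalty = gap_penalty, overlap_window = overlap_window,
                 max_gaps = max_gaps, evalue_cutoff = evalue_cutoff),
            class = "chain_params")
}

#' Identify tandem duplicate genes
#'
#' Two hit genes on the same chromosome separated by at most `max_intervening`
#' genes seed a tandem array; arrays are closed transitively, and all member
#' genes are returned. Tandem genes are excluded from synteny-based counts.
#'
#' @param hits intra-genome hit table (`query`, `subject`, `evalue`).
#' @param genes the genome's [gene_table()].
#' @param max_intervening maximum genes allowed between two tandem members
#'   (default 1, i.e. adjacency-based).
#' @return character vector of tandem gene ids.
#' @export
classify_tandem <- function(hits, genes, max_intervening = 1L) {
  if (nrow(hits) == 0L) return(character())
  idx <- match(hits$query, genes$gene_id)
  jdx <- match(hits$subject, genes$gene_id)
  if (anyNA(idx) || anyNA(jdx)) {
    stop("hit gene(s) absent from gene table")
  }
  same <- genes$chromosome[idx] == genes$chromosome[jdx] &
    abs(genes$order_index[idx] - genes$order_index[jdx]) <= max_intervening + 1L &
    idx != jdx
  if (!any(same)) return(character())
  # union-find over gene table rows for transitive array closure
  parent <- seq_len(nrow(genes))
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in which(same)) {
    ri <- find(idx[k]); rj <- find(jdx[k])
    if (ri != rj) parent[ri] <- rj
  }
  roots <- vapply(seq_len(nrow(genes)), find, integer(1))
  members <- which(roots %in% roots[c(idx[same], jdx[same])])
  in_array <- tabulate(roots, nbins = nrow(genes))[roots[members]] >= 2L
  sort(genes$gene_id[members[in_array]])
}

# Block E-value surrogate: min per-pair E-value raised to the pair count,
# floored at 1e-300 (computed in log10 space to avoid underflow).
.block_evalue <- function(pair_evalues) {
  e <- min(pair_evalues)
  le <- if (e <= 0) -300 else log10(e)
  10^max(-300, length(pair_evalues) * le)
}

# One DP pass over anchors of a single chromosome pair, one orientation.
# Anchors given as integer order vectors oa, ob (ob already sign-flipped for
# the inverted orientation). Returns best chain (indices) and its score.
.best_chain <- function(oa, ob, params) {
  n <- length(oa)
  ord <- order(oa, ob)
  oa <- oa[ord]; ob <- ob[ord]
  score <- rep(params$match_score, n)
  prev <- rep(0L, n)
  max_reach <- params$max_gaps + 1L
  for (i in seq_len(n)) {
    lo <- findInterval(oa[i] - max_reach, oa, left.open = TRUE) + 1L
    js <- seq(lo, length.out = i - lo)
    if (!length(js)) next
    ok <- oa[js] < oa[i] & ob[js] < ob[i] & (ob[i] - ob[js]) <= max_reach
    js <- js[ok]
    if (!length(js)) next
    gap <- (oa[i] - oa[js] - 1L) + (ob[i] - ob[js] - 1L)
    cand <- score[js] + params$gap_penalty * gap
    best <- which.max(cand)
    if (cand[best] > 0) {
      score[i] <- params$match_score + cand[best]
      prev[i] <- js[best]
    }
  }
  end <- which(score == max(score))
  # ties: longer chain, then lower starting order
  chain_of <- function(e) {
    ch <- integer(0)
    while (e != 0L) {
      ch <- c(e, ch)
      e <- prev[e]
    }
    ch
  }
  chains <- lapply(end, chain_of)
  lens <- lengths(chains)
  starts <- vapply(chains, function(ch) oa[ch[1L]], integer(1))
  pick <- order(-lens, starts)[1L]
  list(idx = ord[chains[[pick]]], score = max(score))
}

#' Chain anchors into syntenic blocks
#'
#' Dynamic-programming chainer over homologous gene pairs (anchors). Within
#' each chromosome pair, chains are grown over anchors sorted by genome-A
#' gene rank: each chained anchor earns `match_score` and each skipped gene
#' rank on either genome pays `gap_penalty`; extensions with a gap larger
#' than `max_gaps` on either genome are forbidden. Both orientations are
#' searched; chains are extracted best-first, and chains with fewer than
#' `match_size` anchor pairs are discarded. Chains on one chromosome pair
#' overlapping by more than `overlap_window` genes are merged when the merged
#' chain is still collinear, otherwise the lower-scoring chain is trimmed.
#' The block E-value is the minimum per-pair E-value raised to the number of
#' pairs (floored at 1e-300), a monotone surrogate used by [filter_blocks()].
#'
#' @param hits hit table between genome A and genome B (`query` in A,
#'   `subject` in B).
#' @param genes_a,genes_b [gene_table()]s of the two genomes.
#' @param params a [chain_params()] object.
#' @return A [synteny_blocks()] object.
#' @export
chain_anchors <- function(hits, genes_a, genes_b, params = chain_params()) {
  if (nrow(hits) == 0L) return(synteny_blocks(NULL, NULL))
  hits <- hits[hits$evalue < params$evalue_cutoff, , drop = FALSE]
  ia <- match(hits$query, genes_a$gene_id)
  ib <- match(hits$subject, genes_b$gene_id)
  keep <- !is.na(ia) & !is.na(ib)
  hits <- hits[keep, , drop = FALSE]
  ia <- ia[keep]; ib <- ib[keep]
  if (!nrow(hits)) return(synteny_blocks(NULL, NULL))
  anchors <- data.frame(
    gene_a = hits$query, gene_b = hits$subject, evalue = hits$evalue,
    chrom_a = genes_a$chromosome[ia], order_a = genes_a$order_index[ia],
    chrom_b = genes_b$chromosome[ib], order_b = genes_b$order_index[ib],
    stringsAsFactors = FALSE)
  anchors <- unique(anchors)
  groups <- split(seq_len(nrow(anchors)),
                  paste(anchors$chrom_a, anchors$chrom_b, sep = "\r"))
  blocks <- list(); pairs <- list()
  for (g in groups) {
    g <- g[order(anchors$order_a[g], anchors$order_b[g])]
    remaining <- g
    chains <- list()
    while (length(remaining) >= params$match_size) {
      oa <- anchors$order_a[remaining]
      ob <- anchors$order_b[remaining]
      fwd <- .best_chain(oa, ob, params)
      rev <- .best_chain(oa, -ob, params)
      use_fwd <- fwd$score > rev$score ||
        (fwd$score == rev$score && length(fwd$idx) >= length(rev$idx))
      ch <- if (use_fwd) fwd else rev
      sel <- remaining[ch$idx]
      remaining <- setdiff(remaining, sel)
      if (length(sel) < params$match_size) break
      chains[[length(chains) + 1L]] <- list(
        idx = sel, score = ch$score,
        orientation = if (use_fwd) "same" else "inverted")
    }
    chains <- .resolve_overlaps(chains, anchors, params)
    for (ch in chains) {
      sel <- ch$idx
      id <- length(blocks) + 1L
      a <- anchors[sel, , drop = FALSE]
      a <- a[order(a$order_a), , drop = FALSE]
      blocks[[id]] <- data.frame(
        block_id = id, chrom_a = a$chrom_a[1L], chrom_b = a$chrom_b[1L],
        orientation = ch$orientation, n_pairs = nrow(a), score = ch$score,
        block_evalue = .block_evalue(a$evalue), median_ks = NA_real_,
        stringsAsFactors = FALSE)
      pairs[[id]] <- data.frame(
        block_id = id, gene_a = a$gene_a, gene_b = a$gene_b,
        evalue = a$evalue, order_a = a$order_a, order_b = a$order_b,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(blocks)) return(synteny_blocks(NULL, NULL))
  bl <- do.call(rbind, blocks)
  pr <- do.call(rbind, pairs)
  # renumber deterministically by chromosome pair then start order
  o <- order(bl$chrom_a, bl$chrom_b,
             vapply(split(pr$order_a, pr$block_id), min, numeric(1))[
               as.character(bl$block_id)])
  remap <- integer(nrow(bl)); remap[bl$block_id[o]] <- seq_len(nrow(bl))
  pr$block_id <- remap[pr$block_id]
  bl <- bl[o, , drop = FALSE]
  bl$block_id <- seq_len(nrow(bl))
  rownames(bl) <- NULL
  pr <- pr[order(pr$block_id, pr$order_a), , drop = FALSE]
  rownames(pr) <- NULL
  synteny_blocks(bl, pr)
}

# Merge or trim chains of one chromosome pair whose genome-A footprints
# overlap by more than overlap_window genes.
.resolve_overlaps <- function(chains, anchors, params) {
  if (length(chains) < 2L) return(chains)
  repeat {
    ranges <- lapply(chains, function(ch) range(anchors$order_a[ch$idx]))
    merged <- FALSE
    for (i in seq_along(chains)) {
      for (j in seq_along(chains)) {
        if (j <= i) next
        ov <- min(ranges[[i]][2L], ranges[[j]][2L]) -
          max(ranges[[i]][1L], ranges[[j]][1L]) + 1L
        if (ov <= params$overlap_window) next
        hi <- if (chains[[i]]$score >= chains[[j]]$score) i else j
        lo <- if (hi == i) j else i
        comb <- union(chains[[hi]]$idx, chains[[lo]]$idx)
        oa <- anchors$order_a[comb]; ob <- anchors$order_b[comb]
        o <- order(oa)
        mono_up <- all(diff(ob[o]) > 0) &&
          all(diff(oa[o]) - 1L <= params$max_gaps) &&
          all(diff(ob[o]) - 1L <= params$max_gaps)
        mono_dn <- all(diff(ob[o]) < 0) &&
          all(diff(oa[o]) - 1L <= params$max_gaps) &&
          all(-diff(ob[o]) - 1L <= params$max_gaps)
        if (mono_up || mono_dn) {
          gaps <- sum(diff(oa[o]) - 1L) + sum(abs(diff(ob[o])) - 1L)
          chains[[hi]] <- list(
            idx = comb[o],
            score = length(comb) * params$match_score + params$gap_penalty * gaps,
            orientation = if (mono_up) "same" else "inverted")
          chains[[lo]] <- NULL
        } else {
          keep <- chains[[lo]]$idx[
            anchors$order_a[chains[[lo]]$idx] < max(ranges[[hi]][1L],
                                                    ranges[[lo]][1L]) |
            anchors$order_a[chains[[lo]]$idx] > min(ranges[[hi]][2L],
                                                    ranges[[lo]][2L])]
          if (length(keep) >= params$match_size) {
            chains[[lo]]$idx <- keep
          } else {
            chains[[lo]] <- NULL
          }
        }
        merged <- TRUE
        break
      }
      if (merged) break
    }
    if (!merged) return(chains)
  }
}

#' Remove false-positive syntenic blocks
#'
#' Applies the two removal criteria used for interspecies blocks:
#' (1) blocks whose block E-value exceeds `block_evalue_max`; (2) blocks with
#' fewer than `min_pairs` gene pairs in which more than `weak_fraction` of
#' pairs have per-pair E-values above `pair_evalue_max`.
#'
#' @param blocks a [synteny_blocks()] object with per-pair E-values.
#' @param block_evalue_max threshold for criterion 1 (default 1e-10).
#' @param pair_evalue_max per-pair E-value defining a weak pair (default 1e-10).
#' @param min_pairs block size below which criterion 2 applies (default 10).
#' @param weak_fraction weak-pair fraction triggering criterion 2 (default 0.5,
#'   strict inequality).
#' @return filtered [synteny_blocks()]; attribute `"removed"` records each
#'   removed block id and the criterion that removed it.
#' @export
filter_blocks <- function(blocks, block_evalue_max = 1e-10,
                          pair_evalue_max = 1e-10, min_pairs = 10L,
                          weak_fraction = 0.5) {
  b <- blocks$blocks
  if (!nrow(b)) {
    out <- blocks
    attr(out, "removed") <- data.frame(block_id = integer(),
                                       criterion = character())
    return(out)
  }
  weak <- vapply(b$block_id, function(id) {
    pe <- blocks$pairs$evalue[blocks$pairs$block_id == id]
    mean(pe > pair_evalue_max)
  }, numeric(1))
  crit1 <- b$block_evalue > block_evalue_max
  crit2 <- b$n_pairs < min_pairs & weak > weak_fraction
  removed <- data.frame(
    block_id = b$block_id[crit1 | crit2],
    criterion = ifelse(crit1[crit1 | crit2], "block_evalue", "weak_pairs"),
    stringsAsFactors = FALSE)
  keep <- !(crit1 | crit2)
  out <- synteny_blocks(b[keep, , drop = FALSE],
                        blocks$pairs[blocks$pairs$block_id %in%
                                       b$block_id[keep], , drop = FALSE])
  attr(out, "removed") <- removed
  out
}

#' Syntenic depth of reference genes
#'
#' For each gene of the reference genome, counts the number of block
#' footprints (order-index intervals on the reference) covering its position;
#' genes are tallied by depth (`0:1`, `1:1`, `2:1`, `3:1`, `4+:1`). A genome
#' that underwent one WGD relative to the reference is expected to be
#' dominated by depth 2. Because the denominator of published depth
#' percentages is ambiguous, percentages over all reference genes
#' (`pct_total`) and over covered genes only (`pct_covered`) are both
#' reported.
#'
#' @param blocks a [synteny_blocks()] object.
#' @param genes_ref the reference genome's [gene_table()].
#' @param reference `"b"` (default) if the reference genome is genome B of
#'   the blocks, `"a"` otherwise.
#' @return data.frame with `ratio`, `gene_count`, `pct_total`, `pct_covered`.
#' @export
syntenic_depth <- function(blocks, genes_ref, reference = c("b", "a")) {
  reference <- match.arg(reference)
  chrom_col <- paste0("chrom_", reference)
  order_col <- paste0("order_", reference)
  depth <- integer(nrow(genes_ref))
  pr <- blocks$pairs
  bl <- blocks$blocks
  for (k in seq_len(nrow(bl))) {
    sel <- pr$block_id == bl$block_id[k]
    rng <- range(pr[[order_col]][sel])
    rows <- which(genes_ref$chromosome == bl[[chrom_col]][k] &
                    genes_ref$order_index >= rng[1L] &
                    genes_ref$order_index <= rng[2L])
    depth[rows] <- depth[rows] + 1L
  }
  cat_depth <- pmin(depth, 4L)
  counts <- vapply(0:4, function(d) sum(cat_depth == d), integer(1))
  covered <- sum(depth > 0L)
  data.frame(
    ratio = c("0:1", "1:1", "2:1", "3:1", "4+:1"),
    gene_count = counts,
    pct_total = round(100 * counts / nrow(genes_ref), 2),
    pct_covered = ifelse(rep(covered > 0, 5),
                         round(100 * counts / covered, 2), NA_real_),
    stringsAsFactors = FALSE)
}

#' Percentage of genes covered by syntenic blocks
#'
#' @param n_in_blocks number of genes participating in blocks.
#' @param n_total total annotated genes.
#' @return percentage, rounded to 2 decimals.
#' @export
coverage_percentage <- function(n_in_blocks, n_total) {
  if (any(n_total <= 0)) stop("n_total must be positive")
  if (any(n_in_blocks < 0) || any(n_in_blocks > n_total)) {
    stop("n_in_blocks must lie in [0, n_total]")
  }
  round(100 * n_in_blocks / n_total, 2)
}

#' Dot-plot export of anchor pairs
#'
#' @param blocks a [synteny_blocks()] object.
#' @return data.frame `(chrom_a, order_a, chrom_b, order_b, block_id)` for
#'   external plotting.
#' @export
dotplot_data <- function(blocks) {
  pr <- blocks$pairs
  bl <- blocks$blocks
  m <- match(pr$block_id, bl$block_id)
  data.frame(chrom_a = bl$chrom_a[m], order_a = pr$order_a,
             chrom_b = bl$chrom_b[m], order_b = pr$order_b,
             block_id = pr$block_id, stringsAsFactors = FALSE)
}
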