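#' Pair duplicated-genome regions over the outgroup
#'
#' Tiles each outgroup chromosome with the footprints (order-index intervals)
#' of the recent syntenic blocks and pairs two blocks whose footprints
#' overlap by at least `min_shared` outgroup genes. Candidate pairs are
#' accepted best-overlap-first; each outgroup gene is claimed by at most one
#' accepted pair, and a candidate with less than `min_overlap` of its
#' overlap segment still unclaimed is logged as a conflict and skipped (this
#' implements "keep the top regions" when more than two blocks contest one
#' interval, and lets one long block pair with several shorter blocks over
#' disjoint segments, as happens after segmental translocations). Blocks
#' left with an unclaimed footprint of at least `min_shared` genes become
#' single-region pairs (`block_2` absent): regions whose duplicate copy was
#' lost entirely.
#'
#' @param blocks recent (ancient-free) [synteny_blocks()] between the
#'   duplicated genome (A) and the outgroup (B).
#' @param genes_out the outgroup [gene_table()].
#' @param min_shared minimum claimed outgroup genes per region pair.
#' @param min_overlap minimum unclaimed fraction of a candidate's overlap
#'   segment for the candidate to be accepted.
#' @return object of class `region_pairs`: `pairs` (data.frame with
#'   `pair_id`, `chromosome`, `block_1`, `block_2`, `start_order`,
#'   `end_order`, `n_claimed`), `claimed` (list of outgroup gene-id vectors
#'   per pair), `conflicts` (data.frame of skipped candidates).
#' @export
pair_homologous_regions <- function(blocks, genes_out, min_shared = 10L,
                                    min_overlap = 0.5) {
  b <- blocks$blocks
  pr <- blocks$pairs
  if (!nrow(b)) stop("no blocks to pair")
  fp <- do.call(rbind, lapply(seq_len(nrow(b)), function(k) {
    sel <- pr$block_id == b$block_id[k]
    data.frame(block_id = b$block_id[k], chromosome = b$chrom_b[k],
               lo = min(pr$order_b[sel]), hi = max(pr$order_b[sel]),
               score = b$score[k], stringsAsFactors = FALSE)
  }))
  claimed_by <- rep(0L, nrow(genes_out))
  pairs <- list(); claimed <- list(); conflicts <- list()
  gene_rows <- function(chr, lo, hi) {
    which(genes_out$chromosome == chr & genes_out$order_index >= lo &
            genes_out$order_index <= hi)
  }
  # candidate block pairs per chromosome, best overlap first
  cand <- list()
  for (chr in unique(fp$chromosome)) {
    f <- fp[fp$chromosome == chr, , drop = FALSE]
    if (nrow(f) < 2L) next
    for (i in seq_len(nrow(f) - 1L)) {
      for (j in seq(i + 1L, nrow(f))) {
        ov <- min(f$hi[i], f$hi[j]) - max(f$lo[i], f$lo[j]) + 1L
        if (ov >= min_shared) {
          cand[[length(cand) + 1L]] <- data.frame(
            chromosome = chr, b1 = f$block_id[i], b2 = f$block_id[j],
            lo = max(f$lo[i], f$lo[j]), hi = min(f$hi[i], f$hi[j]),
            overlap = ov, score = f$score[i] + f$score[j],
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(cand)) {
    cand <- do.call(rbind, cand)
    cand <- cand[order(-cand$overlap, -cand$score, cand$b1), , drop = FALSE]
    for (k in seq_len(nrow(cand))) {
      rows <- gene_rows(cand$chromosome[k], cand$lo[k], cand$hi[k])
      free <- rows[claimed_by[rows] == 0L]
      if (length(free) < max(min_shared, min_overlap * length(rows))) {
        conflicts[[length(conflicts) + 1L]] <- cand[k, , drop = FALSE]
        next
      }
      id <- length(pairs) + 1L
      claimed_by[free] <- id
      pairs[[id]] <- data.frame(
        pair_id = id, chromosome = cand$chromosome[k],
        block_1 = cand$b1[k], block_2 = cand$b2[k],
        start_order = cand$lo[k], end_order = cand$hi[k],
        n_claimed = length(free), stringsAsFactors = FALSE)
      claimed[[id]] <- genes_out$gene_id[free]
    }
  }
  # leftover single regions, strongest blocks first
  for (k in order(-fp$score)) {
    rows <- gene_rows(fp$chromosome[k], fp$lo[k], fp$hi[k])
    free <- rows[claimed_by[rows] == 0L]
    if (length(free) < min_shared) next
    id <- length(pairs) + 1L
    claimed_by[free] <- id
    pairs[[id]] <- data.frame(
      pair_id = id, chromosome = fp$chromosome[k],
      block_1 = fp$block_id[k], block_2 = NA_integer_,
      start_order = fp$lo[k], end_order = fp$hi[k],
      n_claimed = length(free), stringsAsFactors = FALSE)
    claimed[[id]] <- genes_out$gene_id[free]
  }
  structure(list(
    pairs = if (length(pairs)) do.call(rbind, pairs) else
      data.frame(pair_id = integer(), chromosome = character(),
                 block_1 = integer(), block_2 = integer(),
                 start_order = integer(), end_order = integer(),
                 n_claimed = integer()),
    claimed = claimed,
    conflicts = if (length(conflicts)) do.call(rbind, conflicts) else NULL),
    class = "region_pairs")
}

#' @export
print.region_pairs <- function(x, ...) {
  cat(sprintf("region_pairs: %d region pairs (%d with both regions)\n",
              nrow(x$pairs), sum(!is.na(x$pairs$block_2))))
  invisible(x)
}

#' Count singleton genes per homologous region pair
#'
#' For each outgroup gene claimed by a region pair: retained only in region 1
#' increments `n1`; only in region 2 increments `n2`; retained in both makes
#' a homeolog candidate; retained in neither is lost-in-both. The counting
#' identity `n1 + n2 + n_homeolog + n_lost = n_claimed` holds per pair.
#'
#' @param region_pairs a [pair_homologous_regions()] result.
#' @param blocks the [synteny_blocks()] the pairs were built from.
#' @return `region_pairs` with columns `n1`, `n2`, `n_homeolog`, `n_lost`
#'   added to its `pairs` table.
#' @export
count_singletons <- function(region_pairs, blocks) {
  pr <- blocks$pairs
  anchors_of <- function(block_id) unique(pr$gene_b[pr$block_id == block_id])
  p <- region_pairs$pairs
  res <- t(vapply(seq_len(nrow(p)), function(k) {
    g <- region_pairs$claimed[[k]]
    in1 <- g %in% anchors_of(p$block_1[k])
    in2 <- if (is.na(p$block_2[k])) rep(FALSE, length(g)) else
      g %in% anchors_of(p$block_2[k])
    c(n1 = sum(in1 & !in2), n2 = sum(!in1 & in2),
      n_homeolog = sum(in1 & in2), n_lost = sum(!in1 & !in2))
  }, c(n1 = 0L, n2 = 0L, n_homeolog = 0L, n_lost = 0L)))
  region_pairs$pairs <- cbind(p, as.data.frame(res))
  region_pairs
}

#' Assign duplicated-genome genes to the two subgenomes
#'
#' Applies the singleton rule: within each homologous region pair, the region
#' with more singleton genes is subgenome 1 and the other subgenome 2 (ties
#' broken by more total retained genes, then by lexicographic chromosome
#' name of the duplicated-genome region). Outgroup genes retained in both
#' regions yield homeolog pairs with mutual partner links (the best-E-value
#' anchor per region is used when several duplicated-genome genes anchor the
#' same outgroup gene); genes retained in one region only are singletons.
#' Single-region pairs are labelled by the same rule (the surviving region
#' holds all the singletons). Labels are per region pair: "subgenome 1" is
#' not claimed to be one ancestral haplotype genome-wide.
#'
#' @param region_pairs a [pair_homologous_regions()] result (singleton counts
#'   are computed if missing).
#' @param blocks the recent [synteny_blocks()].
#' @param genes_dup the duplicated genome's [gene_table()].
#' @return data.frame of class `subgenome_assignment`, one row per
#'   duplicated-genome gene: `gene_id`, `chromosome`, `subgenome`
#'   (`subgenome1`/`subgenome2`/`unassigned`), `class`
#'   (`singleton`/`homeolog`/`unassigned`), `partner`, `outgroup_anchor`,
#'   `high_confidence` (all `FALSE` until [flag_high_confidence()]).
#'   Attribute `"regions"` carries the per-pair table with the
#'   `subgenome_block1` label.
#' @export
assign_subgenomes <- function(region_pairs, blocks, genes_dup) {
  if (!("n1" %in% names(region_pairs$pairs))) {
    region_pairs <- count_singletons(region_pairs, blocks)
  }
  p <- region_pairs$pairs
  pr <- blocks$pairs
  bl <- blocks$blocks
  n <- nrow(genes_dup)
  sub <- rep("unassigned", n)
  cls <- rep("unassigned", n)
  partner <- rep(NA_character_, n)
  anchor <- rep(NA_character_, n)
  taken <- rep(FALSE, n)
  sg_block1 <- character(nrow(p))
  for (k in seq_len(nrow(p))) {
    b1 <- p$block_1[k]; b2 <- p$block_2[k]
    g <- region_pairs$claimed[[k]]
    pr1 <- pr[pr$block_id == b1 & pr$gene_b %in% g, , drop = FALSE]
    pr2 <- if (is.na(b2)) pr[0, ] else
      pr[pr$block_id == b2 & pr$gene_b %in% g, , drop = FALSE]
    # singleton rule; ties: total retained, then chromosome name
    if (p$n1[k] != p$n2[k]) {
      b1_is_sg1 <- p$n1[k] > p$n2[k]
    } else if (length(unique(pr1$gene_a)) != length(unique(pr2$gene_a))) {
      b1_is_sg1 <- length(unique(pr1$gene_a)) > length(unique(pr2$gene_a))
    } else {
      ca <- bl$chrom_a[match(b1, bl$block_id)]
      cb <- if (is.na(b2)) "" else bl$chrom_a[match(b2, bl$block_id)]
      b1_is_sg1 <- ca <= cb
    }
    lab1 <- if (b1_is_sg1) "subgenome1" else "subgenome2"
    lab2 <- if (b1_is_sg1) "subgenome2" else "subgenome1"
    sg_block1[k] <- lab1
    # best anchor per claimed outgroup gene and region
    m1 <- .best_anchor(pr1)
    m2 <- .best_anchor(pr2)
    d1 <- m1$gene_a[match(g, m1$gene_b)]
    d2 <- m2$gene_a[match(g, m2$gene_b)]
    i1 <- match(d1, genes_dup$gene_id)
    i2 <- match(d2, genes_dup$gene_id)
    ok1 <- !is.na(i1) & !duplicated(i1, incomparables = NA)
    ok1[ok1] <- !taken[i1[ok1]]
    ok2 <- !is.na(i2) & !duplicated(i2, incomparables = NA)
    ok2[ok2] <- !taken[i2[ok2]]
    # one duplicated gene cannot serve both regions
    ok2 <- ok2 & !(i2 %in% i1[ok1])
    homeo <- ok1 & ok2
    s1 <- ok1 & !ok2
    s2 <- ok2 & !ok1
    sub[i1[homeo]] <- lab1; cls[i1[homeo]] <- "homeolog"
    partner[i1[homeo]] <- d2[homeo]; anchor[i1[homeo]] <- g[homeo]
    sub[i2[homeo]] <- lab2; cls[i2[homeo]] <- "homeolog"
    partner[i2[homeo]] <- d1[homeo]; anchor[i2[homeo]] <- g[homeo]
    sub[i1[s1]] <- lab1; cls[i1[s1]] <- "singleton"; anchor[i1[s1]] <- g[s1]
    sub[i2[s2]] <- lab2; cls[i2[s2]] <- "singleton"; anchor[i2[s2]] <- g[s2]
    taken[i1[ok1]] <- TRUE
    taken[i2[ok2]] <- TRUE
  }
  asg <- data.frame(
    gene_id = genes_dup$gene_id,
    chromosome = genes_dup$chromosome,
    subgenome = sub, class = cls,
    partner = partner, outgroup_anchor = anchor,
    high_confidence = FALSE, stringsAsFactors = FALSE)
  regions <- cbind(p, subgenome_block1 = sg_block1)
  attr(asg, "regions") <- regions
  attr(asg, "conflicts") <- region_pairs$conflicts
  class(asg) <- c("subgenome_assignment", "data.frame")
  asg
}

# per outgroup gene, the duplicated-genome anchor with the lowest E-value
.best_anchor <- function(pr_block) {
  if (!nrow(pr_block)) {
    return(data.frame(gene_a = character(), gene_b = character()))
  }
  pr_block <- pr_block[order(pr_block$evalue, pr_block$gene_a), , drop = FALSE]
  pr_block[!duplicated(pr_block$gene_b), c("gene_a", "gene_b"), drop = FALSE]
}

#' @export
print.subgenome_assignment <- function(x, ...) {
  tab <- table(x$subgenome, x$class)
  cat("subgenome_assignment:\n")
  print(tab)
  invisible(x)
}

#' Flag high-confidence genes using a second outgroup
#'
#' A duplicated-genome gene already anchored in the primary outgroup is
#' flagged high-confidence when it also appears as an anchor in at least one
#' filtered block against the second outgroup.
#'
#' @param assignment an [assign_subgenomes()] result.
#' @param second_outgroup_blocks filtered [synteny_blocks()] between the
#'   duplicated genome (A) and the second outgroup (B).
#' @return `assignment` with `high_confidence` updated.
#' @export
flag_high_confidence <- function(assignment, second_outgroup_blocks) {
  anchored2 <- unique(second_outgroup_blocks$pairs$gene_a)
  assignment$high_confidence <- assignment$gene_id %in% anchored2 &
    !is.na(assignment$outgroup_anchor) &
    assignment$subgenome %in% c("subgenome1", "subgenome2")
  assignment
}
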