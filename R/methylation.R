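#' Pool methylation replicates by summing counts
#'
#' Integrates the cytosines of several biological replicates: per
#' (chromosome, position, strand, context), methylated and total read counts
#' are summed, so sites covered in only one replicate are carried through and
#' the pooled level of a shared site lies between the replicate levels.
#'
#' @param tables list of [methylation_table()]s from one genome.
#' @return pooled [methylation_table()].
#' @export
pool_replicates <- function(tables) {
  stopifnot(length(tables) >= 1L)
  all <- data.table::rbindlist(lapply(tables, as.data.frame))
  ctx <- all[, list(nctx = data.table::uniqueN(context)),
             by = c("chromosome", "position", "strand")]
  if (any(ctx$nctx > 1L)) {
    stop("conflicting context calls at ", sum(ctx$nctx > 1L), " site(s)")
  }
  pooled <- all[, list(count_methylated = sum(count_methylated),
                       count_total = sum(count_total)),
                by = c("chromosome", "position", "strand", "context")]
  methylation_table(pooled$chromosome, pooled$position, pooled$strand,
                    pooled$context, pooled$count_methylated,
                    pooled$count_total)
}

#' Weighted methylation level of a genomic region
#'
#' The weighted level is the sum of methylated read counts over the sum of
#' total read counts across the region's cytosines of one context (counting
#' only cytosines with `count_total >= min_total`). A region without covered
#' cytosines yields `NA`, not 0.
#'
#' @param meth a [methylation_table()].
#' @param chromosome chromosome name.
#' @param start,end region interval, 0-based half-open.
#' @param context `"CG"`, `"CHG"` or `"CHH"`.
#' @param min_total minimum reads for a cytosine to count (default 1).
#' @return list with `level`, `covered_cytosines`, `count_methylated`,
#'   `count_total`.
#' @export
weighted_methylation <- function(meth, chromosome, start, end, context,
                                 min_total = 1L) {
  chrom <- chromosome; ctx <- context; mt <- min_total
  sel <- meth[chromosome == chrom & position > start & position <= end &
                context == ctx & count_total >= mt]
  cm <- sum(sel$count_methylated)
  ct <- sum(sel$count_total)
  list(level = if (ct > 0) cm / ct else NA_real_,
       covered_cytosines = nrow(sel),
       count_methylated = cm, count_total = ct)
}

# site-to-gene join: returns data.table of (site columns, gene_id, strand_g,
# gstart, gend) for all sites within gene span +/- flank
.sites_in_genes <- function(meth, genes, context, flank) {
  ctx <- context
  m <- meth[context == ctx]
  gi <- data.table::data.table(
    gene_id = genes$gene_id, chromosome = genes$chromosome,
    istart = genes$start - flank + 1L,   # 1-based inclusive join interval
    iend = genes$end + flank,
    gstart = genes$start, gend = genes$end, strand_g = genes$strand)
  m[, `:=`(istart = position, iend = position)]
  data.table::setkeyv(gi, c("chromosome", "istart", "iend"))
  res <- data.table::foverlaps(m, gi, type = "within", nomatch = NULL,
                               by.x = c("chromosome", "istart", "iend"))
  res[, c("istart", "iend", "i.istart", "i.iend") := NULL]
  res
}

#' Metagene methylation profile
#'
#' Builds the average methylation landscape of a gene set for one context:
#' a fixed-width upstream flank (binned in `flank_bin`-bp steps), a gene body
#' rescaled to `body_bins` equal-width slices, and a fixed-width downstream
#' flank. Bins are transcription-oriented: for minus-strand genes the flanks
#' swap and the bin order is reversed, so bin 1 is always the far upstream
#' end and the last bin the far downstream end. Each bin's level pools read
#' counts over genes (sum of methylated / sum of total, not a mean of
#' per-gene ratios). Genes shorter than `body_bins` bp contribute to body
#' bins by proportional span.
#'
#' @param genes a [gene_table()] (or subset of rows) with strand.
#' @param meth a [methylation_table()].
#' @param context `"CG"`, `"CHG"` or `"CHH"`.
#' @param flank flank length in bp (default 3000).
#' @param flank_bin flank bin width in bp (default 100).
#' @param body_bins number of scaled gene-body bins (default 40).
#' @param min_total minimum reads per cytosine (default 1).
#' @return data.frame of class `metagene_profile`: `bin`, `segment`
#'   (`upstream`/`body`/`downstream`), `level`, `covered_cytosines`;
#'   attributes `context` and `n_genes`.
#' @export
metagene_profile <- function(genes, meth, context, flank = 3000L,
                             flank_bin = 100L, body_bins = 40L,
                             min_total = 1L) {
  nf <- as.integer(flank / flank_bin)
  res <- .sites_in_genes(meth, genes, context, flank)
  res <- res[count_total >= min_total]
  n_bins <- 2L * nf + body_bins
  cm <- numeric(n_bins); ct <- numeric(n_bins); cn <- integer(n_bins)
  if (nrow(res)) {
    pos0 <- res$position - 1L  # back to 0-based
    glen <- res$gend - res$gstart
    plus <- res$strand_g == "+"
    # signed distance from TSS in transcription direction
    in_body <- pos0 >= res$gstart & pos0 < res$gend
    rel_body <- ifelse(plus, (pos0 - res$gstart) / glen,
                       (res$gend - 1L - pos0) / glen)
    upstream <- ifelse(plus, pos0 < res$gstart, pos0 >= res$gend)
    dist_up <- ifelse(plus, res$gstart - 1L - pos0, pos0 - res$gend)
    dist_dn <- ifelse(plus, pos0 - res$gend, res$gstart - 1L - pos0)
    bin <- integer(nrow(res))
    bin[in_body] <- nf + 1L + pmin(body_bins - 1L,
                                   floor(rel_body[in_body] * body_bins))
    up <- !in_body & upstream
    bin[up] <- nf - pmin(nf - 1L, floor(dist_up[up] / flank_bin))
    dn <- !in_body & !upstream
    bin[dn] <- nf + body_bins + 1L + pmin(nf - 1L,
                                          floor(dist_dn[dn] / flank_bin))
    agg <- data.table::data.table(
      bin = bin, cm = res$count_methylated, ct = res$count_total)[
        , list(cm = sum(cm), ct = sum(ct), n = .N), by = "bin"]
    cm[agg$bin] <- agg$cm
    ct[agg$bin] <- agg$ct
    cn[agg$bin] <- agg$n
  }
  out <- data.frame(
    bin = seq_len(n_bins),
    segment = c(rep("upstream", nf), rep("body", body_bins),
                rep("downstream", nf)),
    level = ifelse(ct > 0, cm / ct, NA_real_),
    covered_cytosines = cn, stringsAsFactors = FALSE)
  attr(out, "context") <- context
  attr(out, "n_genes") <- nrow(genes)
  class(out) <- c("metagene_profile", "data.frame")
  out
}

#' Per-gene weighted methylation of one metagene region
#'
#' @param genes a [gene_table()] (or subset).
#' @param meth a [methylation_table()].
#' @param region `"upstream"`, `"body"` or `"downstream"`
#'   (transcription-oriented).
#' @param context `"CG"`, `"CHG"` or `"CHH"`.
#' @param flank flank length in bp (default 3000).
#' @param min_total minimum reads per cytosine.
#' @return data.frame `gene_id`, `level`, `covered_cytosines` (genes without
#'   covered cytosines have `NA` level).
#' @export
region_methylation <- function(genes, meth, region = c("body", "upstream",
                                                       "downstream"),
                               context, flank = 3000L, min_total = 1L) {
  region <- match.arg(region)
  res <- .sites_in_genes(meth, genes, context, flank)
  res <- res[count_total >= min_total]
  pos0 <- res$position - 1L
  plus <- res$strand_g == "+"
  in_body <- pos0 >= res$gstart & pos0 < res$gend
  before <- pos0 < res$gstart   # genome-left of the gene
  keep <- switch(region,
    body = in_body,
    upstream = !in_body & (before == plus),
    downstream = !in_body & (before != plus))
  res <- res[keep]
  agg <- res[, list(cm = sum(count_methylated), ct = sum(count_total),
                    n = .N), by = "gene_id"]
  m <- match(genes$gene_id, agg$gene_id)
  data.frame(gene_id = genes$gene_id,
             level = ifelse(!is.na(m) & agg$ct[m] > 0,
                            agg$cm[m] / agg$ct[m], NA_real_),
             covered_cytosines = ifelse(is.na(m), 0L, agg$n[m]),
             stringsAsFactors = FALSE)
}

#' Compare region methylation between two gene groups
#'
#' Computes per-gene weighted methylation levels for one region and context
#' in both groups (genes without coverage dropped) and applies the two-sided
#' Mann-Whitney U test; the comparison unit is the per-gene region level.
#'
#' @param genes_a,genes_b [gene_table()] subsets for the two groups.
#' @param meth a [methylation_table()].
#' @param region `"body"`, `"upstream"` or `"downstream"`.
#' @param context `"CG"`, `"CHG"` or `"CHH"`.
#' @param flank flank length in bp.
#' @param min_total minimum reads per cytosine.
#' @return data.frame row: `region`, `context`, `n_a`, `n_b`, `median_a`,
#'   `median_b`, `u`, `p`, `stars`.
#' @export
compare_region_methylation <- function(genes_a, genes_b, meth, region,
                                       context, flank = 3000L,
                                       min_total = 1L) {
  la <- region_methylation(genes_a, meth, region, context, flank, min_total)
  lb <- region_methylation(genes_b, meth, region, context, flank, min_total)
  a <- la$level[!is.na(la$level)]
  b <- lb$level[!is.na(lb$level)]
  if (length(a) < 3L || length(b) < 3L) {
    stop("need at least 3 covered genes per group (got ",
         length(a), " and ", length(b), ")")
  }
  row <- .comparison_row(paste(context, region, sep = "_"), a, b)
  cbind(data.frame(region = region, context = context,
                   stringsAsFactors = FALSE), row)
}
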