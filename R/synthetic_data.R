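#' Configuration of the synthetic post-WGD world
#'
#' The generator emulates the data regime the pipeline is designed for: a
#' diploid outgroup of ~8 chromosomes, a genome that duplicated after the
#' split and then fractionated (per-gene Bernoulli retention in each
#' subgenome copy), a more distant second outgroup sharing the ancestral
#' gene order, anchor BLAST hits with spurious contamination, block-age Ks
#' structure with a speciation peak and an older WGD peak, log-normal TPM
#' over seven tissues, and binomially sampled bisulfite counts with
#' context- and region-specific levels.
#'
#' @param seed integer seed driving all randomness.
#' @param n_outgroup_genes total outgroup genes (default 8000).
#' @param n_chromosomes outgroup chromosome count (default 8).
#' @param retention length-2 retention probabilities of the two subgenome
#'   copies (default `c(0.6, 0.6)`, the unbiased regime).
#' @param rearrangement_events segmental translocations applied to the
#'   duplicated genome (default 4; segments of 50-500 genes).
#' @param tandem_fraction fraction of retained genes gaining an adjacent
#'   tandem copy (default 0.02).
#' @param spurious_hit_fraction fraction of spurious anchor hits injected
#'   (default 0.02).
#' @param outgroup2_retention per-gene retention in the second outgroup.
#' @param n_chromosomes_out2 second-outgroup chromosome count.
#' @param ks_components Ks mixture of block ages: weights, means, sds
#'   (defaults 0.55/0.45, 0.404/1.37, 0.08/0.20 — a speciation peak and an
#'   ancient-WGD peak).
#' @param pair_ks_sd within-block spread of pair Ks around the block age.
#' @param ancient_segments,ancient_segment_genes,ancient_density ancient-WGD
#'   remnant blocks: how many, how long (outgroup genes), and the anchor
#'   retention density inside them.
#' @param dnds mean dN/dS of gene pairs (default 0.2, purifying selection).
#' @param out2_ks synonymous divergence to the second outgroup.
#' @param gene_length,intergenic gene span and intergenic spacing in bp
#'   (defaults 1500/6000, so 3-kb flanks never overlap a neighbouring gene).
#' @param tissue_count expression tissues (default 7).
#' @param expr_meanlog,expr_sdlog_gene,expr_sdlog_noise log-normal TPM
#'   parameters: grand mean, between-gene sd, residual (tissue) sd.
#' @param singleton_expr_logfc planted log fold-change of singleton over
#'   homeolog expression (0 in the unbiased regime).
#' @param dominance_fraction fraction of homeolog pairs with a planted
#'   expression-dominance effect (0 in the unbiased regime).
#' @param dominance_fold fold-change of the planted dominance effect.
#' @param dominance_bias probability that the planted dominant member is the
#'   copy-A gene (0.5 = symmetric).
#' @param intergenic_tpm_mean,n_intergenic exponential mean and number of
#'   intergenic control regions for the expression threshold.
#' @param meth_levels per-context, per-region mean methylation levels.
#' @param meth_gene_concentration Beta concentration of per-gene levels
#'   around the region mean.
#' @param meth_depth mean read depth per cytosine and replicate.
#' @param meth_site_spacing spacing of simulated cytosines in bp (per
#'   context).
#' @param meth_body_shift optional planted body-methylation shift:
#'   `list(context =, copy =, delta =)` (empty in the unbiased regime).
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(
    seed = 1L,
    n_outgroup_genes = 8000L,
    n_chromosomes = 8L,
    retention = c(0.6, 0.6),
    rearrangement_events = 4L,
    tandem_fraction = 0.02,
    spurious_hit_fraction = 0.02,
    outgroup2_retention = 0.85,
    n_chromosomes_out2 = 7L,
    ks_components = list(weights = c(0.55, 0.45), means = c(0.404, 1.37),
                         sds = c(0.08, 0.20)),
    pair_ks_sd = 0.05,
    ancient_segments = 30L,
    ancient_segment_genes = 40L,
    ancient_density = 0.3,
    dnds = 0.2,
    out2_ks = 1.0,
    gene_length = 1500L,
    intergenic = 6000L,
    tissue_count = 7L,
    expr_meanlog = 1.5,
    expr_sdlog_gene = 1.0,
    expr_sdlog_noise = 0.15,
    singleton_expr_logfc = 0,
    dominance_fraction = 0,
    dominance_fold = 4,
    dominance_bias = 0.5,
    intergenic_tpm_mean = 0.7,
    n_intergenic = 2000L,
    meth_levels = list(
      CG = c(upstream = 0.35, body = 0.45, downstream = 0.35),
      CHG = c(upstream = 0.15, body = 0.08, downstream = 0.15),
      CHH = c(upstream = 0.05, body = 0.03, downstream = 0.05)),
    meth_gene_concentration = 50,
    meth_depth = 20L,
    meth_site_spacing = 120L,
    meth_body_shift = list()) {
  if (all(retention == 0)) stop("retention of both copies is 0: empty genome")
  stopifnot(all(retention >= 0), all(retention <= 1),
            abs(sum(ks_components$weights) - 1) < 1e-8)
  cfg <- as.list(environment())
  class(cfg) <- "simulation_config"
  cfg
}

#' Preset simulation regimes
#'
#' `"unbiased"` is the default configuration (equal retention, no planted
#' expression or methylation effects). `"biased"` plants subgenome dominance:
#' copy A retains more genes (retention 0.675 vs 0.525, a 0.15 gap), 20% of
#' homeolog pairs carry an expression-dominance effect favouring copy A, and
#' copy-B gene bodies are CHG-overmethylated by 0.10.
#'
#' @param preset `"unbiased"` or `"biased"`.
#' @param seed integer seed.
#' @param ... overrides forwarded to [simulation_config()].
#' @return a [simulation_config()].
#' @export
simulation_preset <- function(preset = c("unbiased", "biased"), seed = 1L,
                              ...) {
  preset <- match.arg(preset)
  if (preset == "unbiased") {
    simulation_config(seed = seed, ...)
  } else {
    simulation_config(seed = seed, retention = c(0.675, 0.525),
                      dominance_fraction = 0.2, dominance_bias = 1,
                      meth_body_shift = list(context = "CHG", copy = "B",
                                             delta = 0.10), ...)
  }
}

.chrom_of <- function(k, n_genes, n_chrom) {
  per <- ceiling(n_genes / n_chrom)
  pmin((k - 1L) %/% per + 1L, n_chrom)
}

# lay genes onto coordinates: order within chromosome -> start/end
.layout_genes <- function(gene_id, chromosome, strand, gene_length,
                          intergenic, genome_id) {
  ord <- stats::ave(seq_along(gene_id), chromosome,
                    FUN = function(i) seq_along(i) - 1L)
  start <- as.integer(ord) * (gene_length + intergenic) + intergenic %/% 2L
  gene_table(gene_id, chromosome, start, start + gene_length, strand,
             genome_id = genome_id)
}

#' Simulate the genome trio with full ground truth
#'
#' Generates the outgroup, second outgroup and duplicated genome (two
#' fractionated subgenome copies plus tandem insertions and segmental
#' translocations), anchor hits with E-values `10^-U(10,100)` and a spurious
#' fraction, sparse ancient-WGD remnant anchors whose Ks sits on the ancient
#' peak, intra-genome hits (tandem and homeolog pairs), and per-pair Ka/Ks
#' tables against both outgroups.
#'
#' @param config a [simulation_config()].
#' @return list of class `wgd_simulation`: gene tables (`genes_out`,
#'   `genes_out2`, `genes_dup`), hit tables (`hits_dup_out`,
#'   `hits_dup_out2`, `hits_dup_intra`), Ka/Ks tables (`kaks_dup_out`,
#'   `kaks_dup_out2`), and `truth` (per duplicated-genome gene: `copy`,
#'   `class`, `partner`, `outgroup_anchor`, `out2_anchor`).
#' @export
simulate_genomes <- function(config = simulation_config()) {
  set.seed(config$seed)
  n <- config$n_outgroup_genes
  anc <- sprintf("g%05d", seq_len(n))
  out_id <- paste0("out_", anc)
  out_chrom <- paste0("oChr", .chrom_of(seq_len(n), n, config$n_chromosomes))
  out_strand <- sample(c("+", "-"), n, replace = TRUE)
  genes_out <- .layout_genes(out_id, out_chrom, out_strand,
                             config$gene_length, config$intergenic, "outgroup")

  keep2 <- stats::runif(n) < config$outgroup2_retention
  out2_id <- paste0("out2_", anc)[keep2]
  out2_chrom <- paste0("sChr", .chrom_of(which(keep2), n,
                                         config$n_chromosomes_out2))
  genes_out2 <- .layout_genes(out2_id, out2_chrom,
                              sample(c("+", "-"), sum(keep2), replace = TRUE),
                              config$gene_length, config$intergenic,
                              "outgroup2")

  # duplicated genome: copy A / copy B retention
  keepA <- stats::runif(n) < config$retention[1L]
  keepB <- stats::runif(n) < config$retention[2L]
  dup <- data.frame(
    gene_id = c(paste0("dupA_", anc)[keepA], paste0("dupB_", anc)[keepB]),
    ancestor = c(which(keepA), which(keepB)),
    copy = c(rep("A", sum(keepA)), rep("B", sum(keepB))),
    stringsAsFactors = FALSE)
  chrom_idx <- .chrom_of(dup$ancestor, n, config$n_chromosomes)
  dup$chromosome <- paste0("pChr",
                           ifelse(dup$copy == "A", 2L * chrom_idx - 1L,
                                  2L * chrom_idx))
  dup <- dup[order(dup$chromosome, dup$ancestor), , drop = FALSE]

  # adjacent tandem copies (inserted right after their template)
  is_tandem <- stats::runif(nrow(dup)) < config$tandem_fraction
  if (any(is_tandem)) {
    tand <- dup[is_tandem, , drop = FALSE]
    tand$gene_id <- paste0(tand$gene_id, "t")
    tand$copy <- paste0(tand$copy, "t")
    key <- c(seq_len(nrow(dup)) * 2L, which(is_tandem) * 2L + 1L)
    dup <- rbind(dup, tand)[order(key), , drop = FALSE]
  }

  # segmental translocations: move a 50-500 gene segment elsewhere
  dup_split <- split(seq_len(nrow(dup)), dup$chromosome)
  ordering <- unlist(dup_split, use.names = FALSE)
  chrom_assign <- rep(names(dup_split), lengths(dup_split))
  for (ev in seq_len(config$rearrangement_events)) {
    src_chrom <- sample(unique(chrom_assign), 1L)
    src_rows <- which(chrom_assign == src_chrom)
    if (length(src_rows) < 60L) next
    seg_len <- sample(50:min(500L, length(src_rows) - 10L), 1L)
    seg_at <- sample(length(src_rows) - seg_len + 1L, 1L)
    seg <- src_rows[seq(seg_at, length.out = seg_len)]
    dst_chrom <- sample(setdiff(unique(chrom_assign), src_chrom), 1L)
    dst_rows <- which(chrom_assign == dst_chrom)
    insert_after <- dst_rows[sample(length(dst_rows), 1L)]
    keep_idx <- setdiff(seq_along(ordering), seg)
    pos <- match(insert_after, keep_idx)
    ordering <- c(ordering[keep_idx[seq_len(pos)]], ordering[seg],
                  ordering[keep_idx[seq(pos + 1L,
                                        length.out = length(keep_idx) - pos)]])
    chrom_assign <- c(chrom_assign[keep_idx[seq_len(pos)]],
                      rep(dst_chrom, seg_len),
                      chrom_assign[keep_idx[seq(pos + 1L,
                                                length.out = length(keep_idx) - pos)]])
  }
  dup <- dup[ordering, , drop = FALSE]
  dup$chromosome <- chrom_assign
  # positions follow the (possibly rearranged) order within each chromosome
  ord_in_chrom <- stats::ave(seq_len(nrow(dup)), dup$chromosome,
                             FUN = seq_along)
  start <- (as.integer(ord_in_chrom) - 1L) *
    (config$gene_length + config$intergenic) + config$intergenic %/% 2L
  genes_dup <- gene_table(dup$gene_id, dup$chromosome, start,
                          start + config$gene_length,
                          sample(c("+", "-"), nrow(dup), replace = TRUE),
                          genome_id = "duplicated")

  # truth table
  m <- match(genes_dup$gene_id, dup$gene_id)
  truth <- data.frame(
    gene_id = genes_dup$gene_id,
    ancestor = dup$ancestor[m],
    copy = dup$copy[m],
    stringsAsFactors = FALSE)
  real <- truth$copy %in% c("A", "B")
  partner_id <- ifelse(truth$copy == "A", paste0("dupB_", anc[truth$ancestor]),
                       paste0("dupA_", anc[truth$ancestor]))
  partner_exists <- partner_id %in% truth$gene_id[real]
  truth$class <- ifelse(!real, "tandem",
                        ifelse(partner_exists, "homeolog", "singleton"))
  truth$partner <- ifelse(real & partner_exists, partner_id, NA_character_)
  truth$outgroup_anchor <- paste0("out_", anc[truth$ancestor])
  truth$out2_anchor <- ifelse(keep2[truth$ancestor],
                              paste0("out2_", anc[truth$ancestor]),
                              NA_character_)

  rnd_ev <- function(k, lo = 10, hi = 100) 10^-stats::runif(k, lo, hi)

  # anchor hits duplicated -> outgroup (tandem copies hit the ancestor too)
  hits_do <- data.frame(query = truth$gene_id,
                        subject = truth$outgroup_anchor,
                        evalue = rnd_ev(nrow(truth)),
                        bitscore = stats::runif(nrow(truth), 200, 2000),
                        stringsAsFactors = FALSE)
  ks_do <- stats::rnorm(nrow(truth), config$ks_components$means[1L],
                        config$pair_ks_sd)
  ks_do <- pmax(ks_do, 0.01)

  # ancient-WGD remnant anchors: sparse collinear runs at the ancient peak
  anc_rows <- list()
  real_idx <- which(real)
  for (s in seq_len(config$ancient_segments)) {
    L <- config$ancient_segment_genes
    o_start <- sample(n - L, 1L)
    d_start <- sample(length(real_idx) - L, 1L)
    t_sel <- which(stats::runif(L) < config$ancient_density)
    if (length(t_sel) < 2L) next
    dgenes <- truth$gene_id[real_idx[d_start + t_sel]]
    ogenes <- paste0("out_", anc[o_start + t_sel])
    anc_rows[[s]] <- data.frame(
      query = dgenes, subject = ogenes,
      evalue = rnd_ev(length(t_sel), 10, 40),
      bitscore = stats::runif(length(t_sel), 100, 500),
      ks = pmax(stats::rnorm(length(t_sel), config$ks_components$means[2L],
                             config$pair_ks_sd), 0.05),
      stringsAsFactors = FALSE)
  }
  ancient_hits <- if (length(anc_rows)) do.call(rbind, anc_rows) else NULL

  # spurious hits
  n_spur <- ceiling(config$spurious_hit_fraction * nrow(hits_do))
  spur <- data.frame(
    query = sample(truth$gene_id, n_spur, replace = TRUE),
    subject = sample(genes_out$gene_id, n_spur, replace = TRUE),
    evalue = rnd_ev(n_spur, 6, 30),
    bitscore = stats::runif(n_spur, 60, 300),
    stringsAsFactors = FALSE)

  hits_dup_out <- rbind(hits_do,
                        if (!is.null(ancient_hits))
                          ancient_hits[, names(hits_do)],
                        spur)
  kaks_dup_out <- data.frame(
    gene_a = hits_dup_out$query, gene_b = hits_dup_out$subject,
    ks = c(ks_do,
           if (!is.null(ancient_hits)) ancient_hits$ks,
           stats::runif(n_spur, 0.1, 3)),
    stringsAsFactors = FALSE)
  kaks_dup_out$ka <- kaks_dup_out$ks *
    pmax(stats::rgamma(nrow(kaks_dup_out), shape = 4,
                       rate = 4 / config$dnds), 0.01)

  # duplicated -> second outgroup
  has2 <- !is.na(truth$out2_anchor)
  hits_dup_out2 <- data.frame(query = truth$gene_id[has2],
                              subject = truth$out2_anchor[has2],
                              evalue = rnd_ev(sum(has2)),
                              bitscore = stats::runif(sum(has2), 200, 2000),
                              stringsAsFactors = FALSE)
  n_spur2 <- ceiling(config$spurious_hit_fraction * nrow(hits_dup_out2))
  hits_dup_out2 <- rbind(hits_dup_out2, data.frame(
    query = sample(truth$gene_id, n_spur2, replace = TRUE),
    subject = sample(genes_out2$gene_id, n_spur2, replace = TRUE),
    evalue = rnd_ev(n_spur2, 6, 30),
    bitscore = stats::runif(n_spur2, 60, 300)))
  dnds_gene <- pmax(stats::rgamma(nrow(hits_dup_out2), shape = 4,
                                  rate = 4 / config$dnds), 0.01)
  kaks_dup_out2 <- data.frame(
    gene_a = hits_dup_out2$query, gene_b = hits_dup_out2$subject,
    ks = pmax(stats::rnorm(nrow(hits_dup_out2), config$out2_ks, 0.15), 0.05),
    stringsAsFactors = FALSE)
  kaks_dup_out2$ka <- kaks_dup_out2$ks * dnds_gene

  # intra-genome hits: tandem pairs + homeolog pairs
  tand_rows <- truth[truth$class == "tandem", , drop = FALSE]
  tandem_hits <- if (nrow(tand_rows)) data.frame(
    query = tand_rows$gene_id,
    subject = sub("t$", "", tand_rows$gene_id),
    evalue = rnd_ev(nrow(tand_rows), 30, 120),
    bitscore = stats::runif(nrow(tand_rows), 500, 2500),
    stringsAsFactors = FALSE) else NULL
  hom_rows <- truth[truth$class == "homeolog" & truth$copy == "A", ,
                    drop = FALSE]
  hom_hits <- if (nrow(hom_rows)) data.frame(
    query = hom_rows$gene_id, subject = hom_rows$partner,
    evalue = rnd_ev(nrow(hom_rows), 10, 80),
    bitscore = stats::runif(nrow(hom_rows), 200, 2000),
    stringsAsFactors = FALSE) else NULL
  hits_dup_intra <- rbind(tandem_hits, hom_hits)

  structure(list(
    config = config, genes_out = genes_out, genes_out2 = genes_out2,
    genes_dup = genes_dup, hits_dup_out = hits_dup_out,
    hits_dup_out2 = hits_dup_out2, hits_dup_intra = hits_dup_intra,
    kaks_dup_out = kaks_dup_out, kaks_dup_out2 = kaks_dup_out2,
    truth = truth), class = "wgd_simulation")
}

#' @export
print.wgd_simulation <- function(x, ...) {
  cat(sprintf(paste0("wgd_simulation: %d outgroup genes, %d duplicated",
                     " genes (%d tandem), %d second-outgroup genes\n"),
              nrow(x$genes_out), nrow(x$genes_dup),
              sum(x$truth$class == "tandem"), nrow(x$genes_out2)))
  invisible(x)
}

#' Draw block Ks values from the configured age mixture
#'
#' @param n number of draws.
#' @param components list with `weights`, `means`, `sds`.
#' @param seed integer seed.
#' @return list with `ks` (positive values) and `component` (true labels).
#' @export
simulate_ks_values <- function(n, components = simulation_config()$ks_components,
                               seed = 1L) {
  set.seed(seed)
  comp <- sample.int(length(components$weights), n, replace = TRUE,
                     prob = components$weights)
  ks <- stats::rnorm(n, components$means[comp], components$sds[comp])
  flip <- ks <= 0
  ks[flip] <- abs(ks[flip]) + 1e-3
  list(ks = ks, component = comp)
}

#' Simulate diverged coding-sequence pairs with known dN/dS
#'
#' An ancestral codon sequence (no stops) evolves along two branches under a
#' simple codon process: single-nucleotide changes are proposed at random
#' positions, synonymous changes are always accepted, nonsynonymous changes
#' are accepted with probability `dnds`, and changes creating stop codons are
#' rejected. Each branch accumulates accepted synonymous events until the
#' branch reaches `ks_target / 2` synonymous events per synonymous site, so
#' the realised pairwise synonymous divergence approaches `ks_target`.
#'
#' @param n_pairs number of sequence pairs.
#' @param length_codons codons per sequence.
#' @param dnds acceptance probability of nonsynonymous changes.
#' @param ks_target target pairwise synonymous divergence.
#' @param seed integer seed.
#' @return list of `n_pairs` lists with elements `a` and `b` (codon strings).
#' @export
simulate_cds_pairs <- function(n_pairs, length_codons, dnds = 0.2,
                               ks_target = 0.4, seed = 1L) {
  stopifnot(dnds > 0)
  set.seed(seed)
  non_stop <- names(.GENETIC_CODE)[.GENETIC_CODE != "*"]
  evolve <- function(seqv, target_events) {
    s_sites <- sum(vapply(.split_codons(seqv), .syn_sites_cached, numeric(1)))
    events <- 0
    needed <- target_events * s_sites
    guard <- 0L
    while (events < needed && guard < 1e6) {
      guard <- guard + 1L
      pos <- sample(length(seqv), 1L)
      codon_i <- (pos - 1L) %/% 3L
      cstart <- codon_i * 3L + 1L
      old_codon <- paste(seqv[cstart:(cstart + 2L)], collapse = "")
      new_base <- sample(setdiff(.BASES, seqv[pos]), 1L)
      new <- seqv
      new[pos] <- new_base
      new_codon <- paste(new[cstart:(cstart + 2L)], collapse = "")
      if (.GENETIC_CODE[[new_codon]] == "*") next
      syn <- .GENETIC_CODE[[new_codon]] == .GENETIC_CODE[[old_codon]]
      if (syn) {
        seqv <- new
        events <- events + 1
      } else if (stats::runif(1) < dnds) {
        seqv <- new
      }
    }
    seqv
  }
  lapply(seq_len(n_pairs), function(i) {
    anc <- unlist(strsplit(sample(non_stop, length_codons, replace = TRUE),
                           ""))
    list(a = paste(evolve(anc, ks_target / 2), collapse = ""),
         b = paste(evolve(anc, ks_target / 2), collapse = ""))
  })
}

#' Simulate gene and intergenic TPM matrices
#'
#' Gene TPM is log-normal with a per-ancestral-gene baseline shared by
#' homeolog partners, independent per-tissue noise, an optional singleton
#' mean shift and an optional dominance effect planted in a configured
#' fraction of homeolog pairs (the affected member is the copy-A gene with
#' probability `dominance_bias`). Intergenic TPM is exponential with low
#' mean, giving the expression threshold its analog of the published value.
#'
#' @param sim a [simulate_genomes()] result.
#' @param config optional [simulation_config()] (defaults to `sim$config`).
#' @return list with `tpm` (genes x tissues), `tpm_intergenic`
#'   (regions x tissues) and `truth` (per-gene planted effect table).
#' @export
simulate_expression <- function(sim, config = sim$config) {
  set.seed(config$seed + 101L)
  tr <- sim$truth
  tissues <- paste0("tissue", seq_len(config$tissue_count))
  baseline <- stats::rnorm(config$n_outgroup_genes, config$expr_meanlog,
                           config$expr_sdlog_gene)
  mu <- baseline[tr$ancestor]
  mu <- mu + ifelse(tr$class == "singleton", config$singleton_expr_logfc, 0)
  # dominance effect per homeolog pair
  pairA <- tr$gene_id[tr$class == "homeolog" & tr$copy == "A"]
  eff_pair <- pairA[stats::runif(length(pairA)) < config$dominance_fraction]
  dom_is_A <- stats::runif(length(eff_pair)) < config$dominance_bias
  dom_gene <- ifelse(dom_is_A, eff_pair,
                     tr$partner[match(eff_pair, tr$gene_id)])
  mu <- mu + ifelse(tr$gene_id %in% dom_gene, log(config$dominance_fold), 0)
  m <- matrix(stats::rlnorm(nrow(tr) * config$tissue_count,
                            meanlog = rep(mu, config$tissue_count),
                            sdlog = config$expr_sdlog_noise),
              nrow = nrow(tr), dimnames = list(tr$gene_id, tissues))
  mi <- matrix(stats::rexp(config$n_intergenic * config$tissue_count,
                           rate = 1 / config$intergenic_tpm_mean),
               nrow = config$n_intergenic,
               dimnames = list(sprintf("ig%05d", seq_len(config$n_intergenic)),
                               tissues))
  list(tpm = m, tpm_intergenic = mi,
       truth = data.frame(gene_id = tr$gene_id,
                          dominant = tr$gene_id %in% dom_gene,
                          stringsAsFactors = FALSE))
}

#' Simulate bisulfite cytosine reports (two replicates)
#'
#' Cytosines are placed at regular spacing through each duplicated-genome
#' gene body and its 3-kb flanks (the intergenic spacing guarantees flanks
#' never overlap a neighbouring gene, so every cytosine has one true level).
#' Each gene draws a per-context, per-region level from a Beta distribution
#' around the configured region mean (plus any planted shift); read totals
#' are Poisson around `meth_depth` and methylated counts Binomial at the
#' site's true level. Both replicates share the same truth.
#'
#' @param sim a [simulate_genomes()] result.
#' @param config optional [simulation_config()].
#' @param contexts contexts to emit (default CG, CHG, CHH).
#' @return list with `replicates` (list of two [methylation_table()]s) and
#'   `truth` (per gene x context x region true levels).
#' @export
simulate_methylation <- function(sim, config = sim$config,
                                 contexts = c("CG", "CHG", "CHH")) {
  set.seed(config$seed + 202L)
  g <- sim$genes_dup
  tr <- sim$truth[match(g$gene_id, sim$truth$gene_id), ]
  flank <- 3000L
  truth_rows <- list()
  site_tabs <- list()
  for (ctx in contexts) {
    lv <- config$meth_levels[[ctx]]
    shift <- config$meth_body_shift
    for (reg in c("upstream", "body", "downstream")) {
      mean_lv <- rep(lv[[reg]], nrow(g))
      if (length(shift) && identical(shift$context, ctx) && reg == "body") {
        mean_lv <- mean_lv + ifelse(tr$copy == shift$copy, shift$delta, 0)
      }
      conc <- config$meth_gene_concentration
      gene_lv <- stats::rbeta(nrow(g), mean_lv * conc, (1 - mean_lv) * conc)
      truth_rows[[paste(ctx, reg)]] <- data.frame(
        gene_id = g$gene_id, context = ctx, region = reg, level = gene_lv,
        stringsAsFactors = FALSE)
      # site positions (0-based) per gene for this region; each gene gets a
      # random phase so pooled bins are all populated
      sp <- config$meth_site_spacing
      reg_len <- if (reg == "body") config$gene_length else flank
      if (reg == "body") {
        base <- g$start
      } else {
        left <- (reg == "upstream") == (g$strand == "+")
        base <- ifelse(left, g$start - flank, g$end)
      }
      n_off <- reg_len %/% sp
      # distinct residue class per context so contexts never collide at a
      # genomic position (one cytosine, one context)
      ctx_res <- match(ctx, contexts) - 1L
      phase <- (sample.int(sp %/% 3L, nrow(g), replace = TRUE) - 1L) * 3L +
        ctx_res
      pos0 <- rep(base + phase, each = n_off) +
        rep(seq_len(n_off) - 1L, nrow(g)) * sp
      keep <- pos0 >= 0L & pos0 < rep(base, each = n_off) + reg_len
      site_tabs[[paste(ctx, reg)]] <- data.table::data.table(
        chromosome = rep(g$chromosome, each = n_off)[keep],
        position = pos0[keep] + 1L,
        strand = sample(c("+", "-"), sum(keep), replace = TRUE),
        context = ctx,
        level = rep(gene_lv, each = n_off)[keep])
    }
  }
  sites <- data.table::rbindlist(site_tabs)
  data.table::setkeyv(sites, c("chromosome", "position"))
  reps <- lapply(1:2, function(r) {
    tot <- stats::rpois(nrow(sites), config$meth_depth)
    met <- stats::rbinom(nrow(sites), tot, sites$level)
    methylation_table(sites$chromosome, sites$position, sites$strand,
                      sites$context, met, tot)
  })
  list(replicates = reps,
       truth = do.call(rbind, truth_rows))
}

#' Write all simulated inputs to a directory
#'
#' Emits the pipeline's external formats: gene positions (GFF3 and BED),
#' BLAST m8 hit tables, TPM TSV matrices, CX methylation reports and a
#' `truth.json` with ground-truth labels.
#'
#' @param sim a [simulate_genomes()] result.
#' @param dir output directory (created if needed).
#' @param expression optional [simulate_expression()] result.
#' @param methylation optional [simulate_methylation()] result.
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir, expression = NULL, methylation = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(x) file.path(dir, x)
  write_gene_positions(sim$genes_out, fp("outgroup.gff3"), "gff3")
  write_gene_positions(sim$genes_out2, fp("outgroup2.gff3"), "gff3")
  write_gene_positions(sim$genes_dup, fp("duplicated.bed"), "bed")
  write_blast_m8(sim$hits_dup_out, fp("dup_vs_outgroup.m8"))
  write_blast_m8(sim$hits_dup_out2, fp("dup_vs_outgroup2.m8"))
  write_blast_m8(sim$hits_dup_intra, fp("dup_intra.m8"))
  utils::write.table(sim$kaks_dup_out, fp("kaks_dup_outgroup.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$kaks_dup_out2, fp("kaks_dup_outgroup2.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(expression)) {
    write_tpm_matrix(expression$tpm, fp("tpm_genes.tsv"))
    write_tpm_matrix(expression$tpm_intergenic, fp("tpm_intergenic.tsv"))
  }
  if (!is.null(methylation)) {
    for (r in seq_along(methylation$replicates)) {
      write_cx_report(methylation$replicates[[r]],
                      fp(sprintf("methylome_rep%d.CX_report.txt", r)))
    }
  }
  jsonlite::write_json(sim$truth, fp("truth.json"), dataframe = "rows")
  invisible(dir)
}
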