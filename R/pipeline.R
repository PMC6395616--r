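#' Run the full subgenome analysis pipeline
#'
#' Orchestrates the stages end-to-end: tandem classification, synteny
#' chaining and block filtering against the outgroup (and optionally a
#' second outgroup), block Ks dating with ancient-block removal, subgenome
#' reconstruction, fractionation statistics, expression comparisons and
#' methylation comparisons. Stages whose inputs are absent are skipped and
#' flagged in the report.
#'
#' @param genes_dup,genes_out [gene_table()]s of the duplicated genome and
#'   the outgroup.
#' @param genes_out2 optional second-outgroup [gene_table()].
#' @param hits_dup_out hit table duplicated genome vs outgroup.
#' @param hits_dup_out2 optional hit table vs the second outgroup.
#' @param hits_dup_intra optional intra-genome hit table (tandem detection).
#' @param kaks_dup_out optional per-pair Ka/Ks vs the outgroup (used for
#'   block dating; needs columns `gene_a`, `gene_b`, `ks`).
#' @param kaks_dup_out2 optional per-pair Ka/Ks vs the second outgroup (used
#'   for evolutionary-rate comparisons; columns `gene_a`, `gene_b`, `ka`,
#'   `ks`).
#' @param tpm optional gene x tissue TPM matrix.
#' @param tpm_intergenic optional intergenic TPM matrix (expression
#'   threshold).
#' @param meth_replicates optional list of [methylation_table()] replicates.
#' @param params a [chain_params()].
#' @param mixture_k Ks mixture components (default 2).
#' @param window,step sliding-window size/step in genes.
#' @param fold dominance fold-change cutoff.
#' @param contexts methylation contexts analysed (default CG and CHG).
#' @param flank metagene flank in bp.
#' @param seed integer seed (mixture fitting).
#' @param outdir optional directory for TSV/JSON outputs.
#' @return list of class `paleofrac_report` (see Details in the vignette):
#'   block counts before/after filtering, Ks mixture table, assignment
#'   counts, loss-rate table, depth-ratio tables, dominance summary, and a
#'   unified `comparisons` table with U, p and significance stars.
#' @export
run_pipeline <- function(genes_dup, genes_out, genes_out2 = NULL,
                         hits_dup_out, hits_dup_out2 = NULL,
                         hits_dup_intra = NULL,
                         kaks_dup_out = NULL, kaks_dup_out2 = NULL,
                         tpm = NULL, tpm_intergenic = NULL,
                         meth_replicates = NULL,
                         params = chain_params(), mixture_k = 2L,
                         window = 100L, step = 1L, fold = 2,
                         contexts = c("CG", "CHG"), flank = 3000L,
                         seed = 1L, outdir = NULL) {
  report <- list(stages = character(), log = character())
  note <- function(...) {
    msg <- sprintf(...)
    report$log <<- c(report$log, msg)
    message(msg)
  }

  # -- tandem classification ------------------------------------------------
  tandem <- character()
  if (!is.null(hits_dup_intra) && nrow(hits_dup_intra)) {
    tandem <- classify_tandem(hits_dup_intra, genes_dup)
  }
  note("tandem: %d duplicated-genome genes in tandem arrays", length(tandem))
  report$n_tandem <- length(tandem)

  drop_tandem <- function(h) {
    h[!(h$query %in% tandem) & !(h$subject %in% tandem), , drop = FALSE]
  }

  # -- synteny vs outgroup --------------------------------------------------
  blocks_raw <- chain_anchors(drop_tandem(hits_dup_out), genes_dup,
                              genes_out, params)
  blocks <- filter_blocks(blocks_raw)
  removed <- attr(blocks, "removed")
  note("synteny: %d blocks chained, %d removed by filters, %d kept",
       nrow(blocks_raw$blocks), nrow(removed), nrow(blocks$blocks))
  report$blocks_before_filter <- nrow(blocks_raw$blocks)
  report$blocks_removed <- nrow(removed)
  report$blocks_after_filter <- nrow(blocks$blocks)
  report$stages <- c(report$stages, "synteny")

  # -- block dating ---------------------------------------------------------
  recent <- blocks
  if (!is.null(kaks_dup_out)) {
    blocks <- block_ks(blocks, kaks_dup_out)
    ksv <- blocks$blocks$median_ks
    ksv <- ksv[is.finite(ksv)]
    if (length(ksv) >= 10L * mixture_k) {
      mix <- fit_ks_mixture(ksv, k = mixture_k, seed = seed)
      cls <- classify_blocks_by_ks(blocks, mix)
      recent <- cls$recent
      report$ks_mixture <- data.frame(
        component = seq_len(mix$k), weight = mix$weights,
        mean = mix$means, sd = mix$sds)
      report$blocks_ancient <- nrow(cls$ancient$blocks)
      note("dating: Ks peaks at %s; %d ancient block(s) removed",
           paste(sprintf("%.3f", mix$means), collapse = ", "),
           nrow(cls$ancient$blocks))
      report$stages <- c(report$stages, "molevol")
    } else {
      note("dating: too few block Ks values, ancient removal skipped")
    }
  } else {
    note("dating: no Ka/Ks input, ancient removal skipped")
  }
  report$blocks_recent <- nrow(recent$blocks)

  # -- second outgroup ------------------------------------------------------
  blocks2 <- NULL
  if (!is.null(hits_dup_out2) && !is.null(genes_out2)) {
    blocks2 <- filter_blocks(chain_anchors(drop_tandem(hits_dup_out2),
                                           genes_dup, genes_out2, params))
    note("synteny: %d blocks vs second outgroup", nrow(blocks2$blocks))
  }

  # -- depth ratios ---------------------------------------------------------
  report$depth_outgroup_ref <- syntenic_depth(recent, genes_out, "b")
  report$depth_duplicated_ref <- syntenic_depth(recent, genes_dup, "a")
  report$coverage <- data.frame(
    genome = c("outgroup", "duplicated"),
    genes_in_blocks = c(length(unique(recent$pairs$gene_b)),
                        length(unique(recent$pairs$gene_a))),
    genes_total = c(nrow(genes_out), nrow(genes_dup)))
  report$coverage$pct <- coverage_percentage(
    report$coverage$genes_in_blocks, report$coverage$genes_total)

  # -- subgenome assignment -------------------------------------------------
  rp <- count_singletons(pair_homologous_regions(recent, genes_out), recent)
  assignment <- assign_subgenomes(rp, recent, genes_dup)
  if (!is.null(blocks2)) {
    assignment <- flag_high_confidence(assignment, blocks2)
  }
  report$stages <- c(report$stages, "subgenome")
  sg <- assignment$subgenome
  cl <- assignment$class
  report$singletons_sg1 <- sum(sg == "subgenome1" & cl == "singleton")
  report$singletons_sg2 <- sum(sg == "subgenome2" & cl == "singleton")
  report$homeolog_pairs <- sum(cl == "homeolog") %/% 2L
  report$high_confidence_genes <- sum(assignment$high_confidence)
  report$region_pairs <- nrow(rp$pairs)
  note("subgenome: %d/%d singletons (sg1/sg2), %d homeolog pairs, %d HC genes",
       report$singletons_sg1, report$singletons_sg2, report$homeolog_pairs,
       report$high_confidence_genes)

  # -- fractionation --------------------------------------------------------
  tandem_out <- character()  # outgroup tandem genes, if intra-outgroup hits existed
  report$retention_profile <- window_retention(genes_out, assignment,
                                               window = window, step = step,
                                               exclude = tandem_out)
  report$loss_rates <- chromosome_loss_rates(genes_out, assignment,
                                             exclude = tandem_out)
  report$loss_rates$dominant <- ifelse(
    report$loss_rates$raw_loss_sg1 < report$loss_rates$raw_loss_sg2,
    "subgenome1",
    ifelse(report$loss_rates$raw_loss_sg1 > report$loss_rates$raw_loss_sg2,
           "subgenome2", "none"))
  report$max_loss_difference <- max(report$loss_rates$difference)
  report$stages <- c(report$stages, "fractionation")
  note("fractionation: max per-chromosome loss-rate difference %.2f",
       report$max_loss_difference)

  comparisons <- list()
  hc <- if (!is.null(blocks2)) assignment$high_confidence else
    rep(TRUE, nrow(assignment))

  # homeolog pair table (each pair once, member1 in subgenome1)
  hp <- assignment[assignment$class == "homeolog" &
                     assignment$subgenome == "subgenome1" & hc, , drop = FALSE]
  hp <- hp[hp$partner %in% assignment$gene_id[hc], , drop = FALSE]

  # -- evolutionary-rate comparisons ---------------------------------------
  if (!is.null(kaks_dup_out2) && !is.null(blocks2)) {
    syn <- merge(blocks2$pairs[, c("gene_a", "gene_b")], kaks_dup_out2,
                 by = c("gene_a", "gene_b"))
    syn <- syn[!duplicated(syn$gene_a), , drop = FALSE]
    idx <- match(assignment$gene_id, syn$gene_a)
    for (stat in c("ka", "ks")) {
      v <- syn[[stat]][idx]
      grp <- function(s, c2 = NULL) {
        keep <- sg == s & hc & !is.na(v)
        if (!is.null(c2)) keep <- keep & cl == c2
        v[keep]
      }
      comparisons[[paste0(stat, "_sg1_vs_sg2")]] <-
        .comparison_row(paste0(stat, ": subgenome1 vs subgenome2"),
                        grp("subgenome1", "homeolog"),
                        grp("subgenome2", "homeolog"))
      for (s in c("subgenome1", "subgenome2")) {
        comparisons[[paste0(stat, "_single_vs_homeo_", s)]] <-
          .comparison_row(paste0(stat, ": singleton vs homeolog (", s, ")"),
                          grp(s, "singleton"), grp(s, "homeolog"))
      }
    }
    v <- ifelse(syn$ks[idx] > 0, syn$ka[idx] / syn$ks[idx], NA)
    comparisons[["kaks_sg1_vs_sg2"]] <- .comparison_row(
      "ka/ks: subgenome1 vs subgenome2",
      v[sg == "subgenome1" & cl == "homeolog" & hc & !is.na(v)],
      v[sg == "subgenome2" & cl == "homeolog" & hc & !is.na(v)])
    for (s in c("subgenome1", "subgenome2")) {
      comparisons[[paste0("kaks_single_vs_homeo_", s)]] <- .comparison_row(
        paste0("ka/ks: singleton vs homeolog (", s, ")"),
        v[sg == s & cl == "singleton" & hc & !is.na(v)],
        v[sg == s & cl == "homeolog" & hc & !is.na(v)])
    }
    report$stages <- c(report$stages, "molevol_comparisons")
  }

  # -- expression -----------------------------------------------------------
  if (!is.null(tpm)) {
    threshold <- if (!is.null(tpm_intergenic)) {
      intergenic_threshold(tpm_intergenic)
    } else {
      structure(list(value = 0.715, per_tissue_medians = NULL),
                class = "expression_threshold")
    }
    report$expression_threshold <- threshold$value
    note("expression: threshold %.4f", threshold$value)
    hp <- hp[hp$gene_id %in% rownames(tpm) & hp$partner %in% rownames(tpm), ,
             drop = FALSE]
    t1 <- tpm[hp$gene_id, , drop = FALSE]
    t2 <- tpm[hp$partner, , drop = FALSE]
    calls <- list()
    for (tis in colnames(tpm)) {
      comparisons[[paste0("tpm_", tis)]] <- .comparison_row(
        paste0("TPM ", tis, ": subgenome1 vs subgenome2 homeologs"),
        t1[, tis], t2[, tis])
      calls[[tis]] <- data.frame(
        gene_sg1 = hp$gene_id, gene_sg2 = hp$partner, tissue = tis,
        class = classify_dominance(t1[, tis], t2[, tis], fold = fold,
                                   threshold = threshold),
        stringsAsFactors = FALSE)
    }
    report$dominance_calls <- do.call(rbind, calls)
    report$dominance_summary <- dominance_summary(report$dominance_calls)
    # singleton vs homeolog: mean TPM and breadth per subgenome
    mean_tpm <- rowMeans(tpm)[assignment$gene_id]
    breadth <- expression_breadth(tpm, threshold)[
      match(assignment$gene_id, rownames(tpm))]
    for (s in c("subgenome1", "subgenome2")) {
      ksel <- sg == s & hc & !is.na(mean_tpm)
      comparisons[[paste0("tpm_single_vs_homeo_", s)]] <- .comparison_row(
        paste0("mean TPM: singleton vs homeolog (", s, ")"),
        mean_tpm[ksel & cl == "singleton"], mean_tpm[ksel & cl == "homeolog"])
      comparisons[[paste0("breadth_single_vs_homeo_", s)]] <- .comparison_row(
        paste0("expression breadth: singleton vs homeolog (", s, ")"),
        breadth[ksel & cl == "singleton"], breadth[ksel & cl == "homeolog"])
    }
    report$stages <- c(report$stages, "expression")
  } else {
    note("expression: no TPM input, stage skipped")
    report$skipped <- c(report$skipped, "expression")
  }

  # -- methylation ----------------------------------------------------------
  if (!is.null(meth_replicates) && length(meth_replicates)) {
    meth <- if (length(meth_replicates) > 1L) {
      pool_replicates(meth_replicates)
    } else {
      meth_replicates[[1L]]
    }
    gsub1 <- genes_dup[genes_dup$gene_id %in% hp$gene_id, , drop = FALSE]
    gsub2 <- genes_dup[genes_dup$gene_id %in% hp$partner, , drop = FALSE]
    profs <- list()
    cmp_cols <- c("comparison", "n_a", "n_b", "median_a", "median_b",
                  "u", "p", "stars")
    for (ctx in contexts) {
      for (reg in c("upstream", "body", "downstream")) {
        cmpr <- compare_region_methylation(gsub1, gsub2, meth, reg, ctx,
                                           flank = flank)
        cmpr$comparison <- paste0("methylation ", ctx, " ", reg,
                                  ": subgenome1 vs subgenome2")
        comparisons[[paste("meth", ctx, reg, sep = "_")]] <- cmpr[, cmp_cols]
        for (s in c("subgenome1", "subgenome2")) {
          gs <- assignment$gene_id[sg == s & hc & cl == "singleton"]
          gh <- assignment$gene_id[sg == s & hc & cl == "homeolog"]
          cmpr <- compare_region_methylation(
            genes_dup[genes_dup$gene_id %in% gs, , drop = FALSE],
            genes_dup[genes_dup$gene_id %in% gh, , drop = FALSE],
            meth, reg, ctx, flank = flank)
          cmpr$comparison <- paste0("methylation ", ctx, " ", reg,
                                    ": singleton vs homeolog (", s, ")")
          comparisons[[paste("meth", ctx, reg, s, sep = "_")]] <-
            cmpr[, cmp_cols]
        }
      }
      profs[[paste0(ctx, "_sg1")]] <- metagene_profile(gsub1, meth, ctx,
                                                       flank = flank)
      profs[[paste0(ctx, "_sg2")]] <- metagene_profile(gsub2, meth, ctx,
                                                       flank = flank)
    }
    report$metagene_profiles <- profs
    report$stages <- c(report$stages, "methylation")
  } else {
    note("methylation: no input, stage skipped")
    report$skipped <- c(report$skipped, "methylation")
  }

  report$comparisons <- do.call(rbind, comparisons)
  if (!is.null(report$comparisons)) rownames(report$comparisons) <- NULL
  report$assignment <- assignment
  report$blocks <- recent
  class(report) <- "paleofrac_report"
  if (!is.null(outdir)) write_report(report, outdir)
  report
}

#' @export
print.paleofrac_report <- function(x, ...) {
  cat("paleofrac pipeline report\n")
  cat(sprintf("  stages run: %s\n", paste(x$stages, collapse = ", ")))
  cat(sprintf("  blocks: %d chained, %d after filtering, %d recent\n",
              x$blocks_before_filter, x$blocks_after_filter,
              x$blocks_recent))
  cat(sprintf("  singletons: %d (sg1) / %d (sg2); homeolog pairs: %d\n",
              x$singletons_sg1, x$singletons_sg2, x$homeolog_pairs))
  cat(sprintf("  max per-chromosome loss-rate difference: %.2f\n",
              x$max_loss_difference))
  if (!is.null(x$comparisons)) {
    cat(sprintf("  comparisons: %d (%d significant at 0.05)\n",
                nrow(x$comparisons), sum(x$comparisons$p < 0.05)))
  }
  invisible(x)
}

#' Run the pipeline from a single configuration list
#'
#' Thin wrapper around [run_pipeline()]: `config` holds the same named
#' elements (data objects or further parameters).
#'
#' @param config named list of [run_pipeline()] arguments.
#' @return a `paleofrac_report`.
#' @export
run_all <- function(config) {
  do.call(run_pipeline, config)
}

#' Write pipeline outputs to a directory
#'
#' Emits the stage TSVs (assignment, loss rates, retention profile,
#' comparisons, dominance summary) and a `report.json` with the scalar
#' summary.
#'
#' @param report a `paleofrac_report`.
#' @param outdir output directory.
#' @return `outdir`, invisibly.
#' @export
write_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) {
    utils::write.table(df, file.path(outdir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  wt(report$assignment, "assignment.tsv")
  wt(report$loss_rates, "loss_rates.tsv")
  wt(report$retention_profile, "retention_profile.tsv")
  if (!is.null(report$comparisons)) wt(report$comparisons, "comparisons.tsv")
  if (!is.null(report$dominance_summary)) {
    wt(report$dominance_summary, "dominance_summary.tsv")
  }
  singles <- report$assignment[report$assignment$class == "singleton", ,
                               drop = FALSE]
  wt(singles[, c("gene_id", "subgenome", "outgroup_anchor")],
     "singletons.tsv")
  homeo <- report$assignment[report$assignment$class == "homeolog" &
                               report$assignment$subgenome == "subgenome1", ,
                             drop = FALSE]
  wt(data.frame(gene1 = homeo$gene_id, gene2 = homeo$partner,
                outgroup_anchor = homeo$outgroup_anchor),
     "homeologs.tsv")
  scalars <- report[vapply(report, function(x) {
    is.atomic(x) && length(x) <= 8L
  }, logical(1))]
  scalars$ks_mixture <- report$ks_mixture
  jsonlite::write_json(scalars, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}
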