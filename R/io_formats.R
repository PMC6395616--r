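#' Construct a gene position table
#'
#' A `gene_table` is the backbone of all coordinate logic in the package:
#' an ordered table of gene models for one genome, with a dense per-chromosome
#' rank (`order_index`) assigned by ascending start coordinate. All internal
#' coordinates are 0-based half-open; format conversions happen in the readers.
#'
#' @param gene_id character vector of unique gene identifiers.
#' @param chromosome character vector of chromosome / scaffold names.
#' @param start,end integer coordinates, 0-based half-open (`start < end`).
#' @param strand character vector, `"+"` or `"-"`.
#' @param genome_id single string naming the genome.
#' @return A `data.frame` of class `gene_table` with columns `gene_id`,
#'   `chromosome`, `start`, `end`, `strand`, `order_index`, sorted by
#'   chromosome then start, with attribute `genome_id`.
#' @export
gene_table <- function(gene_id, chromosome, start, end, strand,
                       genome_id = "genome") {
  if (anyDuplicated(gene_id)) {
    stop("duplicate gene_id in gene table: ",
         paste(utils::head(gene_id[duplicated(gene_id)], 3), collapse = ", "))
  }
  if (any(start >= end)) stop("gene_table requires start < end for all genes")
  if (!all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  df <- data.frame(
    gene_id = as.character(gene_id),
    chromosome = as.character(chromosome),
    start = as.integer(start),
    end = as.integer(end),
    strand = as.character(strand),
    stringsAsFactors = FALSE
  )
  df <- df[order(df$chromosome, df$start, df$gene_id), , drop = FALSE]
  rownames(df) <- NULL
  df$order_index <- stats::ave(seq_len(nrow(df)), df$chromosome,
                               FUN = function(i) seq_along(i) - 1L)
  df$order_index <- as.integer(df$order_index)
  attr(df, "genome_id") <- genome_id
  class(df) <- c("gene_table", "data.frame")
  df
}

#' @export
print.gene_table <- function(x, ...) {
  cat(sprintf("gene_table '%s': %d genes on %d chromosomes\n",
              attr(x, "genome_id"), nrow(x), length(unique(x$chromosome))))
  print(utils::head(as.data.frame(x)), ...)
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' Read gene positions from GFF3 or BED
#'
#' GFF3 is 1-based closed, BED 0-based half-open; both are normalised to the
#' package's internal 0-based half-open convention so that `end - start` is
#' the gene length in bp. Unsorted input is sorted silently (with a message);
#' duplicate gene identifiers are a hard error.
#'
#' @param path file path.
#' @param format `"gff3"` or `"bed"`.
#' @param genome_id genome label recorded in the returned table.
#' @param feature_type for GFF3, the feature type to keep (default `"gene"`;
#'   if no row has that type, all rows are used).
#' @return A [gene_table()].
#' @export
read_gene_positions <- function(path, format = c("gff3", "bed"),
                                genome_id = "genome", feature_type = "gene") {
  format <- match.arg(format)
  gr <- rtracklayer::import(path, format = if (format == "gff3") "gff3" else "bed")
  df <- as.data.frame(gr)
  if (format == "gff3") {
    if ("type" %in% names(df) && any(df$type == feature_type)) {
      df <- df[df$type == feature_type, , drop = FALSE]
    }
    id <- if ("ID" %in% names(df) && !all(is.na(df$ID))) df$ID else df$Name
  } else {
    id <- df$name
  }
  if (is.null(id) || anyNA(id)) stop("missing gene identifiers in ", path)
  # rtracklayer returns 1-based closed coordinates for both dialects
  start0 <- df$start - 1L
  end0 <- df$end
  if (!all(as.character(df$strand) %in% c("+", "-"))) {
    stop("all records must carry an explicit +/- strand: ", path)
  }
  gene_table(id, as.character(df$seqnames), start0, end0,
             as.character(df$strand), genome_id = genome_id)
}

#' Write gene positions to GFF3 or BED
#'
#' Inverse of [read_gene_positions()]; internal 0-based half-open coordinates
#' are converted back to the dialect's convention.
#'
#' @param genes a [gene_table()].
#' @param path output file path.
#' @param format `"gff3"` or `"bed"`.
#' @return `path`, invisibly.
#' @export
write_gene_positions <- function(genes, path, format = c("gff3", "bed")) {
  format <- match.arg(format)
  if (format == "gff3") {
    lines <- c("##gff-version 3",
               sprintf("%s\tpaleofrac\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       genes$chromosome, genes$start + 1L, genes$end,
                       genes$strand, genes$gene_id))
  } else {
    lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s",
                     genes$chromosome, genes$start, genes$end,
                     genes$gene_id, genes$strand)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read tabular BLAST hits (outfmt 6 / m8)
#'
#' Reads 12-column tabular BLAST output, drops self-hits, and applies the
#' E-value cutoff used throughout the pipeline (hits with
#' `evalue >= max_evalue` are excluded).
#'
#' @param path file path to 12-column tabular BLAST output.
#' @param max_evalue E-value cutoff (default `1e-5`).
#' @return `data.frame` with columns `query`, `subject`, `evalue`, `bitscore`.
#' @export
read_blast_m8 <- function(path, max_evalue = 1e-5) {
  dt <- tryCatch(
    data.table::fread(path, header = FALSE, sep = "\t", fill = FALSE),
    error = function(e) stop("malformed BLAST m8 file ", path, ": ",
                             conditionMessage(e))
  )
  if (ncol(dt) != 12L) {
    stop("expected 12 tab-separated columns in ", path, ", found ", ncol(dt))
  }
  ev <- suppressWarnings(as.numeric(dt[[11L]]))
  bs <- suppressWarnings(as.numeric(dt[[12L]]))
  bad <- which(is.na(ev) | is.na(bs) | ev < 0)
  if (length(bad)) {
    stop("malformed BLAST m8 row at line ", bad[1L], " of ", path)
  }
  hits <- data.frame(query = as.character(dt[[1L]]),
                     subject = as.character(dt[[2L]]),
                     evalue = ev, bitscore = bs,
                     stringsAsFactors = FALSE)
  hits <- hits[hits$query != hits$subject & hits$evalue < max_evalue, ,
               drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Write hits in tabular BLAST (m8) layout
#'
#' Only the four columns the pipeline consumes are meaningful; the remaining
#' eight are filled with placeholder alignment statistics.
#'
#' @param hits data.frame with `query`, `subject`, `evalue`, `bitscore`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_blast_m8 <- function(hits, path) {
  lines <- sprintf("%s\t%s\t100.00\t100\t0\t0\t1\t100\t1\t100\t%s\t%.1f",
                   hits$query, hits$subject,
                   format(hits$evalue, scientific = TRUE, digits = 3),
                   hits$bitscore)
  writeLines(lines, path)
  invisible(path)
}

#' Read a collinearity file (MCScanX dialect)
#'
#' Parses `## Alignment` block headers (score, e_value, chromosome pair,
#' orientation) and the aligned gene-pair lines that follow, retaining the
#' block E-value and every per-pair E-value. Headers without any pair lines
#' are skipped with a warning.
#'
#' @param path file path.
#' @return A [synteny_blocks()] object.
#' @export
read_collinearity <- function(path) {
  lines <- readLines(path)
  hdr_idx <- grep("^## Alignment", lines)
  blocks <- list()
  pairs <- list()
  empty <- 0L
  for (h in seq_along(hdr_idx)) {
    i <- hdr_idx[h]
    to <- if (h < length(hdr_idx)) hdr_idx[h + 1L] - 1L else length(lines)
    body <- lines[seq(i + 1L, length.out = max(0L, to - i))]
    body <- body[!grepl("^#", body) & nzchar(trimws(body))]
    hdr <- lines[i]
    score <- as.numeric(sub(".*score=([0-9.eE+-]+).*", "\\1", hdr))
    bev <- as.numeric(sub(".*e_value=([0-9.eE+-]+).*", "\\1", hdr))
    chrs <- sub(".*[ :]([^ :&]+)&([^ :&]+).*", "\\1 \\2", hdr)
    chrs <- strsplit(trimws(chrs), " ")[[1L]]
    orient <- if (grepl("minus", hdr)) "inverted" else "same"
    if (!length(body)) {
      empty <- empty + 1L
      next
    }
    fields <- strsplit(gsub("^ *[0-9]+- *[0-9]+:", "", body), "[ \t]+")
    fields <- lapply(fields, function(f) f[nzchar(f)])
    ga <- vapply(fields, `[`, "", 1L)
    gb <- vapply(fields, `[`, "", 2L)
    pe <- suppressWarnings(as.numeric(vapply(fields, function(f) {
      if (length(f) >= 3L) f[3L] else "0"
    }, "")))
    pe[is.na(pe)] <- 0
    id <- length(blocks) + 1L
    blocks[[id]] <- data.frame(
      block_id = id, chrom_a = chrs[1L], chrom_b = chrs[2L],
      orientation = orient, n_pairs = length(ga), score = score,
      block_evalue = bev, median_ks = NA_real_, stringsAsFactors = FALSE)
    pairs[[id]] <- data.frame(
      block_id = id, gene_a = ga, gene_b = gb, evalue = pe,
      order_a = NA_integer_, order_b = NA_integer_, stringsAsFactors = FALSE)
  }
  if (empty > 0L) warning(empty, " block header(s) without gene pairs skipped")
  synteny_blocks(do.call(rbind, blocks), do.call(rbind, pairs))
}

#' Write blocks in the MCScanX collinearity dialect
#'
#' @param blocks a [synteny_blocks()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_collinearity <- function(blocks, path) {
  out <- c("############### Parameters ###############",
           "# Generated by paleofrac",
           "##########################################")
  b <- blocks$blocks
  for (k in seq_len(nrow(b))) {
    p <- blocks$pairs[blocks$pairs$block_id == b$block_id[k], , drop = FALSE]
    out <- c(out, sprintf(
      "## Alignment %d: score=%.1f e_value=%s N=%d %s&%s %s",
      b$block_id[k], b$score[k],
      format(b$block_evalue[k], scientific = TRUE, digits = 4),
      nrow(p), b$chrom_a[k], b$chrom_b[k],
      if (b$orientation[k] == "inverted") "minus" else "plus"))
    out <- c(out, sprintf("%3d-%3d:\t%s\t%s\t%s",
                          b$block_id[k], seq_len(nrow(p)) - 1L,
                          p$gene_a, p$gene_b,
                          format(p$evalue, scientific = TRUE, digits = 4)))
  }
  writeLines(out, path)
  invisible(path)
}

.normalize_context <- function(x) {
  x <- toupper(x)
  x[x == "CPG"] <- "CG"
  bad <- !(x %in% c("CG", "CHG", "CHH"))
  if (any(bad)) {
    stop("unknown methylation context token(s): ",
         paste(unique(x[bad]), collapse = ", "))
  }
  x
}

#' Construct a per-cytosine methylation table
#'
#' @param chromosome,position,strand,context,count_methylated,count_total
#'   parallel vectors describing one cytosine per row; `position` is 1-based
#'   as in the Bismark cytosine-report dialect, `context` one of
#'   `CG`/`CHG`/`CHH` (`CpG` accepted as a synonym of `CG`).
#' @return A `data.table` of class `methylation_table`. Rows with
#'   `count_total == 0` are retained (uncovered sites).
#' @export
methylation_table <- function(chromosome, position, strand, context,
                              count_methylated, count_total) {
  if (any(count_methylated < 0) || any(count_total < 0)) {
    stop("negative methylation counts")
  }
  if (any(count_methylated > count_total)) {
    stop("count_methylated exceeds count_total")
  }
  dt <- data.table::data.table(
    chromosome = as.character(chromosome),
    position = as.integer(position),
    strand = as.character(strand),
    context = .normalize_context(context),
    count_methylated = as.integer(count_methylated),
    count_total = as.integer(count_total))
  data.table::setkeyv(dt, c("chromosome", "position", "strand", "context"))
  class(dt) <- c("methylation_table", class(dt))
  dt
}

#' Read a Bismark cytosine (CX) report
#'
#' Expects the whitespace-separated columns chromosome, position (1-based),
#' strand, count methylated, count unmethylated, context (and an optional
#' trinucleotide column, ignored). Totals are formed as methylated +
#' unmethylated; uncovered cytosines (total 0) are retained.
#'
#' @param path file path.
#' @return A [methylation_table()].
#' @export
read_cx_report <- function(path) {
  dt <- data.table::fread(path, header = FALSE)
  if (ncol(dt) < 6L) stop("CX report needs at least 6 columns: ", path)
  cm <- as.integer(dt[[4L]])
  cu <- as.integer(dt[[5L]])
  if (anyNA(cm) || anyNA(cu) || any(cm < 0) || any(cu < 0)) {
    stop("negative or non-numeric counts in CX report ", path)
  }
  methylation_table(dt[[1L]], dt[[2L]], dt[[3L]], dt[[6L]], cm, cm + cu)
}

#' Write a methylation table as a Bismark-style CX report
#'
#' @param meth a [methylation_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cx_report <- function(meth, path) {
  lines <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s",
                   meth$chromosome, meth$position, meth$strand,
                   meth$count_methylated,
                   meth$count_total - meth$count_methylated,
                   meth$context, meth$context)
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene-by-tissue TPM matrix
#'
#' The first column must hold gene identifiers and the header row tissue (or
#' replicate) names. When `replicate_map` is supplied, replicate columns are
#' averaged to one column per tissue before analysis.
#'
#' @param path TSV file path.
#' @param replicate_map optional named character vector mapping column name to
#'   tissue name, e.g. `c(leaf_1 = "leaf", leaf_2 = "leaf")`.
#' @return numeric matrix, rownames = gene ids, colnames = tissues.
#' @export
read_tpm_matrix <- function(path, replicate_map = NULL) {
  dt <- data.table::fread(path, header = TRUE)
  genes <- as.character(dt[[1L]])
  m <- as.matrix(dt[, -1L, with = FALSE])
  storage.mode(m) <- "double"
  if (anyNA(m)) stop("non-numeric TPM values in ", path)
  if (any(m < 0)) stop("negative TPM values in ", path)
  rownames(m) <- genes
  if (!is.null(replicate_map)) {
    m <- average_replicates(m, replicate_map)
  }
  m
}

#' Average replicate columns of a TPM matrix per tissue
#'
#' @param m numeric matrix with replicate columns.
#' @param replicate_map named character vector, column name -> tissue.
#' @return matrix with one column per tissue (replicate mean).
#' @export
average_replicates <- function(m, replicate_map) {
  missing_cols <- setdiff(colnames(m), names(replicate_map))
  if (length(missing_cols)) {
    stop("columns without replicate_map entry: ",
         paste(missing_cols, collapse = ", "))
  }
  tissues <- unique(unname(replicate_map[colnames(m)]))
  out <- vapply(tissues, function(t) {
    cols <- colnames(m)[replicate_map[colnames(m)] == t]
    rowMeans(m[, cols, drop = FALSE])
  }, numeric(nrow(m)))
  rownames(out) <- rownames(m)
  out
}

#' Write a TPM matrix as TSV
#'
#' @param m numeric matrix with gene rownames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tpm_matrix <- function(m, path) {
  dt <- data.table::data.table(gene_id = rownames(m))
  for (j in colnames(m)) dt[[j]] <- m[, j]
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}
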