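## Gene models: strand-aware promoters, exon loci with mutability covariates.

#' Construct a gene model
#'
#' A gene model carries everything the annotation and permutation machinery
#' needs: isoform transcription start sites, the strand-aware promoter
#' (the 1,000 nucleotides immediately upstream of each TSS, unioned across
#' isoforms), and exon loci annotated with GC fraction `g`, size `s` and
#' sequencing-coverage fraction `c`.
#'
#' @param gene_id stable identifier.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param tss integer vector of per-isoform TSS positions (0-based position of
#'   the first transcribed base).
#' @param exons optional interval data frame (`start`, `end`, half-open) of
#'   exon blocks on `chrom`.
#' @param g,cov per-exon GC fraction and covered fraction in `[0, 1]`;
#'   recycled. Coverage defaults to 1 when no coverage data exist.
#' @param active logical; promoter carries an active chromatin mark
#'   (H3K27ac/H3K4me3).
#' @param promoter_nt promoter extent upstream of each TSS (default 1000 nt).
#' @return object of class `gene_model` with fields `gene_id`, `chrom`,
#'   `strand`, `tss`, `promoter_intervals` (per-isoform, each `<= promoter_nt`),
#'   `promoter_union` (merged), `promoter_size` (unique nt), `exon_loci`
#'   (data frame `g`, `s`, `c` plus coordinates), `active`.
#' @export
gene_model <- function(gene_id, chrom, strand, tss, exons = NULL,
                       g = 0.5, cov = 1, active = TRUE, promoter_nt = 1000L) {
  stopifnot(length(gene_id) == 1L, length(chrom) == 1L)
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-' for ", gene_id)
  tss <- sort(unique(as.numeric(tss)))
  if (!length(tss)) stop("gene ", gene_id, " has no TSS")
  if (strand == "+") {
    ps <- pmax(0, tss - promoter_nt); pe <- tss
  } else {
    ps <- tss + 1; pe <- tss + 1 + promoter_nt
  }
  keep <- ps < pe
  prom <- data.frame(chrom = chrom, start = ps[keep], end = pe[keep],
                     stringsAsFactors = FALSE)
  prom_union <- merge_intervals(prom)
  exon_loci <- NULL
  if (!is.null(exons) && nrow(exons) > 0) {
    s <- exons$end - exons$start
    exon_loci <- data.frame(chrom = chrom, start = exons$start, end = exons$end,
                            g = rep_len(g, nrow(exons)),
                            s = s,
                            c = rep_len(cov, nrow(exons)),
                            stringsAsFactors = FALSE)
    if (any(exon_loci$g < 0 | exon_loci$g > 1) ||
        any(exon_loci$c < 0 | exon_loci$c > 1))
      stop("gene ", gene_id, ": g and c must lie in [0, 1]")
    if (any(exon_loci$s < 1)) stop("gene ", gene_id, ": exon size must be >= 1")
  }
  structure(list(gene_id = as.character(gene_id), chrom = chrom,
                 strand = strand, tss = tss,
                 promoter_intervals = prom,
                 promoter_union = prom_union,
                 promoter_size = sum(prom_union$end - prom_union$start),
                 exon_loci = exon_loci,
                 active = isTRUE(active)),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model %s %s:%s strand=%s TSSs=%d promoter=%d nt exons=%d active=%s>\n",
              x$gene_id, x$chrom,
              paste(range(x$tss), collapse = "-"), x$strand, length(x$tss),
              x$promoter_size,
              if (is.null(x$exon_loci)) 0L else nrow(x$exon_loci), x$active))
  invisible(x)
}

#' Gene identifiers of a gene-model list
#' @param genes list of [gene_model()] objects.
#' @return character vector of gene ids.
#' @export
gene_ids <- function(genes) vapply(genes, function(g) g$gene_id, character(1))

#' Read and write tabular gene-model files
#'
#' One row per gene; list-valued columns (`tss`, exon blocks, per-exon `g` and
#' `c`) are comma-separated. Columns: `gene_id`, `chrom`, `strand`, `tss`,
#' `exon_start`, `exon_end`, `g`, `c`, `active`.
#'
#' @param path file path.
#' @param genes list of [gene_model()] objects.
#' @return `read_gene_models`: list of `gene_model` objects.
#' @export
read_gene_models <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   quote = "")
  split_num <- function(s) {
    s <- as.character(s) # read.table may have parsed scalar columns as numeric
    if (is.na(s) || !nzchar(s)) numeric(0)
    else as.numeric(strsplit(s, ",", fixed = TRUE)[[1]])
  }
  lapply(seq_len(nrow(df)), function(i) {
    es <- split_num(df$exon_start[i]); ee <- split_num(df$exon_end[i])
    exons <- if (length(es)) data.frame(start = es, end = ee) else NULL
    gene_model(df$gene_id[i], df$chrom[i], df$strand[i],
               tss = split_num(df$tss[i]), exons = exons,
               g = split_num(df$g[i]), cov = split_num(df$c[i]),
               active = as.logical(df$active[i]))
  })
}

#' @rdname read_gene_models
#' @export
write_gene_models <- function(genes, path) {
  join <- function(v) paste(format(v, scientific = FALSE, trim = TRUE),
                            collapse = ",")
  rows <- lapply(genes, function(gm) {
    ex <- gm$exon_loci
    data.frame(gene_id = gm$gene_id, chrom = gm$chrom, strand = gm$strand,
               tss = join(gm$tss),
               exon_start = if (is.null(ex)) "" else join(ex$start),
               exon_end = if (is.null(ex)) "" else join(ex$end),
               g = if (is.null(ex)) "" else join(ex$g),
               c = if (is.null(ex)) "" else join(ex$c),
               active = gm$active, stringsAsFactors = FALSE)
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
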