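## Reproducible-peak annotation: replicate overlap, peak classification,
## cross-context Venn partitioning, ortholog mapping, fragment density.

#' Reproducible regions between two replicates
#'
#' A region is reproducible when a peak from one replicate overlaps a peak
#' from the other by at least one base; the reported coordinates are the
#' merged coordinates of the overlapping cluster.
#'
#' @param rep_a,rep_b interval data frames (`chrom`, `start`, `end`),
#'   0-based half-open.
#' @param min_overlap minimum overlap in bp (default 1, fixed by convention;
#'   exposed for exploration only).
#' @return merged, non-overlapping, sorted interval data frame.
#' @export
reproducible_regions <- function(rep_a, rep_b, min_overlap = 1L) {
  validate_intervals(rep_a, "rep_a")
  validate_intervals(rep_b, "rep_b")
  if (nrow(rep_a) == 0 || nrow(rep_b) == 0) return(empty_intervals())
  chroms <- intersect(unique(rep_a$chrom), unique(rep_b$chrom))
  pieces <- lapply(chroms, function(ch) {
    a <- iv_to_iranges(rep_a[rep_a$chrom == ch, , drop = FALSE])
    b <- iv_to_iranges(rep_b[rep_b$chrom == ch, , drop = FALSE])
    ov <- IRanges::findOverlaps(a, b, minoverlap = min_overlap)
    if (!length(ov)) return(NULL)
    qa <- a[S4Vectors::queryHits(ov)]
    qb <- b[S4Vectors::subjectHits(ov)]
    un <- IRanges::IRanges(start = pmin(IRanges::start(qa), IRanges::start(qb)),
                           end = pmax(IRanges::end(qa), IRanges::end(qb)))
    iranges_to_iv(IRanges::reduce(un), ch)
  })
  pieces <- pieces[!vapply(pieces, is.null, logical(1))]
  if (!length(pieces)) return(empty_intervals())
  sort_intervals(do.call(rbind, pieces))
}

#' Reproducible regions within replicate groups
#'
#' Applies [reproducible_regions()] to every pair of replicates within each
#' group (e.g., cortical vs non-cortical brain regions) and merges the union
#' across groups.
#'
#' @param samples named list of interval data frames, one per replicate label.
#' @param groups named list; each element a character vector of `>= 2`
#'   replicate labels.
#' @return merged, non-overlapping, sorted interval data frame.
#' @export
group_reproducible <- function(samples, groups) {
  stopifnot(is.list(samples), is.list(groups))
  miss <- setdiff(unlist(groups), names(samples))
  if (length(miss)) stop("groups reference unknown replicate label(s): ",
                         paste(miss, collapse = ", "))
  pieces <- lapply(groups, function(labels) {
    if (length(labels) < 2)
      stop("each group needs >= 2 replicate labels", call. = FALSE)
    pr <- utils::combn(labels, 2, simplify = FALSE)
    do.call(rbind, lapply(pr, function(p)
      reproducible_regions(samples[[p[1]]], samples[[p[2]]])))
  })
  out <- do.call(rbind, pieces)
  if (is.null(out) || nrow(out) == 0) return(empty_intervals())
  merge_intervals(out)
}

#' Classify peaks against gene models
#'
#' Precedence: promoter (>= 1 bp overlap with any gene's promoter union) >
#' exon > distal. The assignment lists every gene satisfying the winning
#' class. Peaks on chromosomes absent from all gene models become distal with
#' a warning.
#'
#' @param peaks interval data frame of peaks.
#' @param genes list of [gene_model()] objects.
#' @return data frame with one row per peak: `chrom`, `start`, `end`,
#'   `class` (`promoter`/`exon`/`distal`) and list-column `gene_ids`.
#' @export
classify_peaks <- function(peaks, genes) {
  validate_intervals(peaks, "peaks")
  ids <- gene_ids(genes)
  if (nrow(peaks) == 0)
    return(cbind(empty_intervals(),
                 data.frame(class = character(0)), gene_ids = I(list())))
  prom <- do.call(rbind, lapply(seq_along(genes), function(i) {
    p <- genes[[i]]$promoter_union
    if (nrow(p)) cbind(p, gene = ids[i]) else NULL
  }))
  exon <- do.call(rbind, lapply(seq_along(genes), function(i) {
    e <- genes[[i]]$exon_loci
    if (!is.null(e) && nrow(e))
      data.frame(chrom = e$chrom, start = e$start, end = e$end, gene = ids[i],
                 stringsAsFactors = FALSE) else NULL
  }))
  pk <- iv_to_granges(peaks)
  hit_genes <- function(feat) {
    res <- vector("list", nrow(peaks))
    if (is.null(feat) || nrow(feat) == 0) return(res)
    fg <- iv_to_granges(feat)
    ov <- suppressWarnings(GenomicRanges::findOverlaps(pk, fg, minoverlap = 1L))
    if (length(ov)) {
      sp <- split(feat$gene[S4Vectors::subjectHits(ov)],
                  S4Vectors::queryHits(ov))
      for (k in names(sp)) res[[as.integer(k)]] <- sort(unique(sp[[k]]))
    }
    res
  }
  ph <- hit_genes(prom)
  eh <- hit_genes(exon)
  known_chroms <- unique(vapply(genes, function(g) g$chrom, character(1)))
  unknown <- setdiff(unique(peaks$chrom), known_chroms)
  if (length(unknown))
    warning("peak chromosome(s) not in gene models, classified distal: ",
            paste(unknown, collapse = ", "))
  cls <- character(nrow(peaks))
  gl <- vector("list", nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    if (length(ph[[i]])) { cls[i] <- "promoter"; gl[[i]] <- ph[[i]] }
    else if (length(eh[[i]])) { cls[i] <- "exon"; gl[[i]] <- eh[[i]] }
    else { cls[i] <- "distal"; gl[[i]] <- character(0) }
  }
  out <- peaks[, c("chrom", "start", "end")]
  out$class <- cls
  out$gene_ids <- I(gl)
  out
}

#' @rdname classify_peaks
#' @param peak single-row interval data frame (or list with chrom/start/end).
#' @export
classify_peak <- function(peak, genes) {
  if (is.list(peak) && !is.data.frame(peak))
    peak <- data.frame(chrom = peak$chrom, start = peak$start, end = peak$end)
  res <- classify_peaks(peak[1, , drop = FALSE], genes)
  list(class = res$class[1], gene_ids = res$gene_ids[[1]])
}

#' Peak context set
#'
#' Light container for reproducible peaks of one biological context.
#'
#' @param context label, e.g. `"hNSC"`.
#' @param intervals_df reproducible interval data frame (merged internally).
#' @param provenance replicate labels used.
#' @export
peak_context_set <- function(context, intervals_df, provenance = character()) {
  stopifnot(length(context) == 1L, nzchar(context))
  structure(list(context = context,
                 intervals = sort_intervals(merge_intervals(intervals_df)),
                 provenance = provenance),
            class = "peak_context_set")
}

#' Venn partition of peak context sets
#'
#' Labels every reproducible interval of every context with the exact set of
#' contexts it overlaps (>= 1 bp, itself included), yielding the cells of a
#' Venn diagram. Each input interval lands in exactly one cell. With gene
#' models supplied, the promoter-bound gene set of each cell is derived via
#' [classify_peaks()].
#'
#' @param context_sets list of [peak_context_set()] objects (>= 2, unique
#'   labels).
#' @param genes optional list of [gene_model()] objects.
#' @return list with `cells` (named list, label like `"a+b"`, of interval data
#'   frames carrying a `context` column) and, when `genes` given,
#'   `bound_genes` (named list of gene-id vectors per cell).
#' @export
venn_partition <- function(context_sets, genes = NULL) {
  if (length(context_sets) < 2) stop("need >= 2 context sets")
  labs <- vapply(context_sets, function(s) s$context, character(1))
  if (anyDuplicated(labs)) stop("duplicate context labels: ",
                                paste(labs[duplicated(labs)], collapse = ", "))
  grl <- lapply(context_sets, function(s) iv_to_granges(s$intervals))
  cells <- list()
  for (i in seq_along(context_sets)) {
    iv <- context_sets[[i]]$intervals
    if (nrow(iv) == 0) next
    memb <- matrix(FALSE, nrow(iv), length(labs))
    memb[, i] <- TRUE
    for (j in seq_along(context_sets)) {
      if (j == i) next
      ov <- suppressWarnings(
        GenomicRanges::findOverlaps(grl[[i]], grl[[j]], minoverlap = 1L))
      memb[unique(S4Vectors::queryHits(ov)), j] <- TRUE
    }
    key <- apply(memb, 1, function(m) paste(labs[m], collapse = "+"))
    for (k in unique(key)) {
      sub <- iv[key == k, , drop = FALSE]
      sub$context <- labs[i]
      cells[[k]] <- rbind(cells[[k]], sub)
    }
  }
  cells <- lapply(cells, sort_intervals)
  out <- list(cells = cells)
  if (!is.null(genes)) {
    out$bound_genes <- lapply(cells, function(iv) {
      cl <- classify_peaks(iv[, c("chrom", "start", "end")], genes)
      sort(unique(unlist(cl$gene_ids[cl$class == "promoter"])))
    })
  }
  out
}

#' Map gene identifiers through a one-to-one ortholog table
#'
#' @param ids character vector/set of gene identifiers.
#' @param ortholog_table data frame whose first two columns are the source and
#'   target identifiers; must be one-to-one.
#' @return list with `mapped` (image of `ids`), `dropped` (unmapped inputs)
#'   and `n_dropped`.
#' @export
map_orthologs <- function(ids, ortholog_table) {
  stopifnot(is.data.frame(ortholog_table), ncol(ortholog_table) >= 2)
  from <- as.character(ortholog_table[[1]])
  to <- as.character(ortholog_table[[2]])
  dup <- c(from[duplicated(from)], to[duplicated(to)])
  if (length(dup))
    stop("ortholog table is not one-to-one; offending id(s): ",
         paste(unique(dup), collapse = ", "))
  ids <- unique(as.character(ids))
  hit <- ids %in% from
  list(mapped = unname(to[match(ids[hit], from)]),
       dropped = ids[!hit],
       n_dropped = sum(!hit))
}

#' Fragment density from read starts
#'
#' Extends each aligned read to `extension` bp in its strand direction and
#' reports, per covered base, the fragment count normalized to fragments per
#' million aligned reads.
#'
#' @param read_starts data frame with columns `chrom`, `pos` (0-based
#'   position of the 5' end) and `strand` (`"+"`/`"-"`).
#' @param extension fragment length in nt (>= 1).
#' @param total_reads total aligned reads used for normalization (> 0).
#' @return data frame of constant-density runs: `chrom`, `start`, `end`
#'   (half-open), `density`.
#' @export
fragment_density <- function(read_starts, extension = 300L, total_reads) {
  stopifnot(extension >= 1)
  if (missing(total_reads) || total_reads <= 0)
    stop("total_reads must be a positive count")
  if (nrow(read_starts) > total_reads)
    stop("total_reads smaller than the number of reads supplied")
  if (nrow(read_starts) == 0)
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      density = numeric()))
  plus <- read_starts$strand == "+"
  fs <- ifelse(plus, read_starts$pos, read_starts$pos - extension + 1)
  frag <- data.frame(chrom = read_starts$chrom,
                     start = pmax(0, fs), end = pmax(0, fs) + extension)
  out <- lapply(sort(unique(frag$chrom)), function(ch) {
    cv <- IRanges::coverage(iv_to_iranges(frag[frag$chrom == ch, , drop = FALSE]))
    rl <- S4Vectors::runLength(cv); rv <- S4Vectors::runValue(cv)
    ends <- cumsum(rl); starts <- ends - rl
    keep <- rv > 0
    data.frame(chrom = ch, start = starts[keep], end = ends[keep],
               density = rv[keep] * 1e6 / total_reads,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
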