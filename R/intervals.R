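## Genomic interval primitives.
##
## Intervals are plain data frames with columns (chrom, start, end) in the
## BED convention: 0-based, half-open [start, end).  IRanges does the heavy
## lifting internally (1-based closed), converted at this boundary.

#' Construct an interval table
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer-like vectors; 0-based half-open coordinates.
#' @return data.frame with columns `chrom`, `start`, `end`.
#' @export
intervals <- function(chrom = character(), start = integer(), end = integer()) {
  df <- data.frame(chrom = as.character(chrom),
                   start = as.numeric(start),
                   end = as.numeric(end),
                   stringsAsFactors = FALSE)
  validate_intervals(df)
  df
}

#' @keywords internal
validate_intervals <- function(x, what = "interval") {
  if (!is.data.frame(x) || !all(c("chrom", "start", "end") %in% names(x)))
    stop(what, " table must have columns chrom/start/end", call. = FALSE)
  if (nrow(x) == 0) return(invisible(x))
  if (any(is.na(x$chrom)) || any(!nzchar(x$chrom)))
    stop(what, ": chrom must be non-empty", call. = FALSE)
  bad <- which(!(x$start < x$end))
  if (length(bad))
    stop(what, ": start >= end for record(s) ", paste(head(bad, 5), collapse = ", "),
         call. = FALSE)
  invisible(x)
}

## BED half-open [s, e) -> IRanges 1-based closed [s+1, e]
iv_to_iranges <- function(x) IRanges::IRanges(start = x$start + 1L, end = x$end)

iranges_to_iv <- function(ir, chrom) {
  data.frame(chrom = rep(chrom, length(ir)),
             start = IRanges::start(ir) - 1L,
             end = IRanges::end(ir),
             stringsAsFactors = FALSE)
}

iv_to_granges <- function(x) {
  GenomicRanges::GRanges(seqnames = x$chrom,
                         ranges = IRanges::IRanges(start = x$start + 1L, end = x$end))
}

## merge overlapping/adjacent-by-overlap intervals (>=1 bp); sorted output
merge_intervals <- function(x) {
  validate_intervals(x)
  if (nrow(x) == 0) return(empty_intervals())
  out <- lapply(sort(unique(x$chrom)), function(ch) {
    ir <- IRanges::reduce(iv_to_iranges(x[x$chrom == ch, , drop = FALSE]))
    iranges_to_iv(ir, ch)
  })
  do.call(rbind, out)
}

empty_intervals <- function() {
  data.frame(chrom = character(), start = numeric(), end = numeric(),
             stringsAsFactors = FALSE)
}

sort_intervals <- function(x) {
  x[order(x$chrom, x$start, x$end), , drop = FALSE]
}

#' Read / write BED interval files
#'
#' BED3 (or wider; extra columns ignored on read).  Coordinates are kept in
#' the native BED 0-based half-open convention.
#'
#' @param path file path.
#' @param x interval data frame (`chrom`, `start`, `end`).
#' @param name optional name column for BED4 output.
#' @return `read_bed`: interval data frame.
#' @export
read_bed <- function(path) {
  df <- read.table(path, header = FALSE, sep = "\t", stringsAsFactors = FALSE,
                   comment.char = "#", quote = "")
  out <- data.frame(chrom = as.character(df[[1]]), start = as.numeric(df[[2]]),
                    end = as.numeric(df[[3]]), stringsAsFactors = FALSE)
  validate_intervals(out, what = basename(path))
  out
}

#' @rdname read_bed
#' @export
write_bed <- function(x, path, name = NULL) {
  validate_intervals(x)
  out <- x[, c("chrom", "start", "end")]
  out$start <- format(out$start, scientific = FALSE, trim = TRUE)
  out$end <- format(out$end, scientific = FALSE, trim = TRUE)
  if (!is.null(name)) out$name <- name
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
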