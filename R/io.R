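## Readers/writers for the remaining plain-text formats.

#' Read / write GMT gene-set files
#'
#' Tab-separated: set name, description, then member genes.
#'
#' @param path file path.
#' @param sets named list of gene-id vectors.
#' @param descriptions optional character vector recycled over sets.
#' @return `read_gmt`: named list of gene-id character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("malformed GMT line: ", substr(ln, 1, 50))
    f[-(1:2)]
  })
  names(out) <- vapply(lines, function(ln)
    strsplit(ln, "\t", fixed = TRUE)[[1]][1], character(1))
  out
}

#' @rdname read_gmt
#' @export
write_gmt <- function(sets, path, descriptions = "na") {
  descriptions <- rep_len(descriptions, length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a plain-text gene list (one id per line, `#` comments allowed)
#' @param path file path.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Read a count matrix TSV with its sample-metadata sidecar
#'
#' @param counts_path genes x units TSV (rownames in the first column).
#' @param meta_path TSV with columns `unit`, `treatment`, `batch`.
#' @return [count_dataset()].
#' @export
read_count_dataset <- function(counts_path, meta_path) {
  counts <- as.matrix(read.table(counts_path, header = TRUE, sep = "\t",
                                 row.names = 1, check.names = FALSE))
  storage.mode(counts) <- "integer"
  meta <- read.table(meta_path, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
  count_dataset(counts, meta)
}

#' Read an expression matrix TSV (genes x samples)
#' @param path file path.
#' @export
read_expression <- function(path) {
  as.matrix(read.table(path, header = TRUE, sep = "\t", row.names = 1,
                       check.names = FALSE))
}

#' Read a two-column gene/value TSV into a named vector
#' @param path file path.
#' @param value_col column holding the values (default second column).
#' @export
read_gene_values <- function(path, value_col = 2L) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  setNames(df[[value_col]], df[[1]])
}
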