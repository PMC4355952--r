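## Covariate-weighted permutation tests for risk-gene enrichment among
## bound promoters.

#' Gene mutability weight
#'
#' Combines exon size, GC content and sequencing coverage into a single
#' mutability weight per gene:
#' \deqn{M = \sum_j (1.2754 g_j + 0.7246 (1 - g_j)) \, s_j \, c_j}
#' where, per exon locus \eqn{j}, \eqn{g} is the GC fraction, \eqn{s} the size
#' in nucleotides and \eqn{c} the fraction covered by at least 20 unique
#' reads. The constants are the relative expected mutation rates of GC and AT
#' nucleotides.
#'
#' @param loci data frame with columns `g`, `s`, `c` (one row per exon locus).
#'   `c` defaults to 1 when absent (no coverage data supplied).
#' @return scalar mutability `M >= 0`.
#' @export
mutability <- function(loci) {
  stopifnot(is.data.frame(loci), all(c("g", "s") %in% names(loci)))
  if (is.null(loci$c)) loci$c <- 1
  if (any(loci$g < 0 | loci$g > 1) || any(loci$c < 0 | loci$c > 1))
    stop("g and c must lie in [0, 1]")
  if (any(loci$s < 0)) stop("s must be non-negative")
  sum((1.2754 * loci$g + 0.7246 * (1 - loci$g)) * loci$s * loci$c)
}

#' Mutability records for a list of gene models
#'
#' @param genes list of [gene_model()] objects (genes without exon loci get
#'   `M = 0`).
#' @return data frame `gene_id`, `M`, `promoter_size`, `active`.
#' @export
mutability_table <- function(genes) {
  data.frame(
    gene_id = gene_ids(genes),
    M = vapply(genes, function(g)
      if (is.null(g$exon_loci)) 0 else mutability(g$exon_loci), numeric(1)),
    promoter_size = vapply(genes, function(g) g$promoter_size, numeric(1)),
    active = vapply(genes, function(g) g$active, logical(1)),
    stringsAsFactors = FALSE)
}

#' Weighted sampling without replacement by cumulative-weight inversion
#'
#' Mirrors the literal permutation procedure: a uniform number is drawn
#' between zero and the total weight, the gene at that point of the
#' cumulative weight is selected, and repeats are rejected until `k` distinct
#' genes are obtained (equivalent to successive sampling proportional to the
#' remaining weights). Zero-weight genes are never selected.
#'
#' @param weights named non-negative numeric vector.
#' @param k number of distinct genes to draw (`<=` number of positive
#'   weights).
#' @return character vector of `k` gene names.
#' @export
weighted_sample_wor <- function(weights, k) {
  stopifnot(!is.null(names(weights)), all(weights >= 0))
  w <- weights[weights > 0]
  k <- as.integer(k)
  if (k > length(w))
    stop("k = ", k, " exceeds the ", length(w), " genes with positive weight")
  if (k == 0L) return(character(0))
  cw <- cumsum(as.numeric(w))
  tot <- cw[length(cw)]
  sel <- integer(0)
  while (length(sel) < k) {
    m <- k - length(sel)
    draw <- findInterval(runif(m) * tot, cw) + 1L
    draw <- draw[!duplicated(draw)]
    sel <- c(sel, draw[!(draw %in% sel)])
  }
  names(w)[sel]
}

new_perm_result <- function(observed, null_counts, n_iter) {
  exceed <- sum(null_counts >= observed)
  p <- exceed / n_iter
  structure(list(observed = observed,
                 null_counts = null_counts,
                 p_empirical = p,
                 p_report = if (exceed == 0)
                   paste0("< ", format(1 / n_iter, scientific = FALSE))
                 else format(p, digits = 4),
                 n_iter = n_iter),
            class = "perm_result")
}

#' @export
print.perm_result <- function(x, ...) {
  cat(sprintf("Permutation test: observed = %d, null mean = %.2f, P %s (%d iterations)\n",
              x$observed, mean(x$null_counts),
              if (startsWith(x$p_report, "<")) x$p_report
              else paste0("= ", x$p_report),
              x$n_iter))
  invisible(x)
}

perm_core <- function(draw_k, weights, hit_set, observed, n_iter) {
  null_counts <- integer(n_iter)
  for (i in seq_len(n_iter))
    null_counts[i] <- sum(weighted_sample_wor(weights, draw_k) %in% hit_set)
  new_perm_result(observed, null_counts, n_iter)
}

#' Gene-label permutation test for risk-gene enrichment
#'
#' Permutes the identity of the risk genes: each iteration draws
#' `|risk_genes|` genes from the universe with probability proportional to
#' mutability (controlling for exon size, GC content and coverage) and counts
#' how many land in the target set. The one-sided empirical p-value is the
#' fraction of iterations with a null count greater than or equal to the
#' observed overlap. The universe should be restricted upstream to active
#' promoters on the capture list.
#'
#' @param risk_genes,target_genes character vectors, subsets of
#'   `universe$gene_id`.
#' @param universe data frame with `gene_id` and `M` (see
#'   [mutability_table()]).
#' @param n_iter iterations (default 10,000).
#' @return [`perm_result`][print.perm_result] object.
#' @export
permutation_test_genes <- function(risk_genes, target_genes, universe,
                                   n_iter = 10000L) {
  stopifnot(is.data.frame(universe), all(c("gene_id", "M") %in% names(universe)))
  if (nrow(universe) == 0) stop("empty universe")
  if (!length(risk_genes)) stop("empty risk-gene set")
  chk <- setdiff(c(risk_genes, target_genes), universe$gene_id)
  if (length(chk))
    stop("gene(s) outside the universe: ", paste(head(chk, 5), collapse = ", "))
  w <- setNames(universe$M, universe$gene_id)
  observed <- length(intersect(risk_genes, target_genes))
  perm_core(length(risk_genes), w, target_genes, observed, n_iter)
}

#' Promoter-label permutation test for risk-gene enrichment
#'
#' Alternative strategy permuting the bound-promoter labels instead of the
#' risk labels: each iteration draws `|target_genes|` genes with probability
#' proportional to total promoter size (unique promoter nucleotides across
#' isoforms) and counts overlap with the risk set.
#'
#' @inheritParams permutation_test_genes
#' @param universe data frame with `gene_id` and `promoter_size`.
#' @return [`perm_result`][print.perm_result] object.
#' @export
permutation_test_promoters <- function(target_genes, risk_genes, universe,
                                       n_iter = 10000L) {
  stopifnot(is.data.frame(universe),
            all(c("gene_id", "promoter_size") %in% names(universe)))
  if (nrow(universe) == 0) stop("empty universe")
  if (!length(target_genes)) stop("empty target set")
  chk <- setdiff(c(risk_genes, target_genes), universe$gene_id)
  if (length(chk))
    stop("gene(s) outside the universe: ", paste(head(chk, 5), collapse = ", "))
  w <- setNames(universe$promoter_size, universe$gene_id)
  observed <- length(intersect(risk_genes, target_genes))
  perm_core(length(target_genes), w, risk_genes, observed, n_iter)
}
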