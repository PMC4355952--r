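## Seed-anchored spatiotemporal co-expression networks and seed-permutation
## enrichment tests.

#' Build a seed-anchored co-expression network
#'
#' For each seed gene, every background gene is scored by Pearson correlation
#' across samples; the `k` best-correlated genes with `|r| >= r_min` become
#' its neighbours. Edges carry the signed correlation. Ties at rank `k` are
#' broken by lexicographic gene identifier, making the network deterministic.
#'
#' @param expr genes x samples numeric matrix with rownames.
#' @param seeds character vector of seed gene ids (subset of `background`;
#'   seeds absent from the matrix are skipped with a warning).
#' @param k neighbours retained per seed (default 20).
#' @param r_min minimum correlation magnitude (default 0.7, inclusive).
#' @param background candidate gene universe (default all matrix genes).
#' @param use_abs rank and threshold by `|r|` (default); `FALSE` restricts to
#'   positive correlations.
#' @return object of class `seed_network`: list with `seeds`, `members`
#'   (named list of data frames `gene`, `r` per seed), `edges` (data frame
#'   `seed`, `gene`, `r`) and the parameters used.
#' @export
build_network <- function(expr, seeds, k = 20L, r_min = 0.7,
                          background = rownames(expr), use_abs = TRUE) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)))
  if (ncol(expr) < 3) stop("need >= 3 samples to correlate")
  background <- unique(background)
  bad_bg <- setdiff(background, rownames(expr))
  if (length(bad_bg)) stop("background gene(s) not in matrix: ",
                           paste(head(bad_bg, 5), collapse = ", "))
  missing_seeds <- setdiff(seeds, rownames(expr))
  if (length(missing_seeds)) {
    warning("seed(s) absent from matrix, skipped: ",
            paste(missing_seeds, collapse = ", "))
    seeds <- setdiff(seeds, missing_seeds)
  }
  seeds <- unique(seeds)
  members <- setNames(vector("list", length(seeds)), seeds)
  if (length(seeds)) {
    cmat <- suppressWarnings(
      cor(t(expr[background, , drop = FALSE]), t(expr[seeds, , drop = FALSE])))
    for (s in seeds) {
      r <- cmat[, s]
      r <- r[names(r) != s & !is.na(r)]
      score <- if (use_abs) abs(r) else r
      keep <- score >= r_min
      r <- r[keep]; score <- score[keep]
      ord <- order(-score, names(r))
      top <- head(ord, k)
      members[[s]] <- data.frame(gene = names(r)[top], r = unname(r[top]),
                                 stringsAsFactors = FALSE)
    }
  }
  edges <- do.call(rbind, lapply(seeds, function(s) {
    m <- members[[s]]
    if (nrow(m)) cbind(data.frame(seed = s, stringsAsFactors = FALSE), m)
    else NULL
  }))
  if (is.null(edges))
    edges <- data.frame(seed = character(), gene = character(), r = numeric())
  structure(list(seeds = seeds, members = members, edges = edges,
                 k = k, r_min = r_min, use_abs = use_abs),
            class = "seed_network")
}

#' @export
print.seed_network <- function(x, ...) {
  cat(sprintf("<seed_network: %d seeds, %d members, %d edges (k=%d, |r|>=%g)>\n",
              length(x$seeds), length(network_members(x)), nrow(x$edges),
              x$k, x$r_min))
  invisible(x)
}

#' Non-seed member genes of a seed network
#' @param net `seed_network` object.
#' @export
network_members <- function(net) {
  setdiff(sort(unique(net$edges$gene)), net$seeds)
}

#' Seed-permutation enrichment test for a co-expression network
#'
#' The observed statistic counts non-seed network members that belong to the
#' query set (e.g., bound promoters); genes acting as seeds — observed or
#' permuted — are never counted as hits. Null networks are rebuilt from
#' random seed sets of equal size drawn uniformly from the background, and
#' the one-sided empirical p-value is the fraction of null statistics at or
#' above the observed one.
#'
#' @inheritParams build_network
#' @param observed_seeds seed genes of the observed network.
#' @param query_set gene set tested for enrichment (subset of `background`).
#' @param n_iter permutation iterations (default 10,000).
#' @return [`perm_result`][print.perm_result] object.
#' @export
seed_permutation_enrichment <- function(expr, observed_seeds, query_set,
                                        k = 20L, r_min = 0.7,
                                        background = rownames(expr),
                                        n_iter = 10000L, use_abs = TRUE) {
  if (!length(observed_seeds)) stop("need >= 1 observed seed")
  if (length(background) < length(observed_seeds))
    stop("background smaller than the seed count")
  stat <- function(seeds) {
    net <- suppressWarnings(build_network(expr, seeds, k = k, r_min = r_min,
                                          background = background,
                                          use_abs = use_abs))
    length(intersect(setdiff(network_members(net), seeds), query_set))
  }
  observed <- stat(observed_seeds)
  nseed <- length(observed_seeds)
  null_counts <- integer(n_iter)
  for (i in seq_len(n_iter))
    null_counts[i] <- stat(sample(background, nseed))
  new_perm_result(observed, null_counts, n_iter)
}
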