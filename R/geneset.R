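## Rank-based gene-set dysregulation tests, spline-residual scoring across
## binding subsets, and pathway-level testing.

#' Wilcoxon rank test for a gene set
#'
#' Tests whether the differential-expression p-values of the set members rank
#' differently from those of a disjoint background (two-sided rank-sum test;
#' exact enumeration when both sides have at most `exact_max` untied values,
#' normal approximation with continuity correction otherwise). The test
#' depends on ranks only, so it is invariant to monotone transforms of the
#' per-gene p-values.
#'
#' @param p_values named numeric vector of per-gene DE p-values.
#' @param set_members,background disjoint gene-id vectors; genes missing from
#'   `p_values` are dropped.
#' @param set_label optional label carried into the result.
#' @param exact_max largest per-side n for the exact null distribution.
#' @return list of class `geneset_test`: `set_label`, `n_genes`,
#'   `wilcoxon_p`, `direction` (+1 when the set's median p-value is below the
#'   background's, i.e. the set is more dysregulated), `statistic`.
#' @export
wilcoxon_set_test <- function(p_values, set_members, background,
                              set_label = NA_character_, exact_max = 25L) {
  stopifnot(!is.null(names(p_values)))
  overlap <- intersect(set_members, background)
  if (length(overlap))
    stop("set and background overlap (pre-partition the universe): ",
         paste(head(overlap, 5), collapse = ", "))
  x <- p_values[intersect(set_members, names(p_values))]
  yv <- p_values[intersect(background, names(p_values))]
  if (!length(x) || !length(yv))
    stop("set and background must both be non-empty after matching")
  exact <- length(x) <= exact_max && length(yv) <= exact_max &&
    !anyDuplicated(c(x, yv))
  wt <- suppressWarnings(wilcox.test(x, yv, alternative = "two.sided",
                                     exact = exact, correct = TRUE))
  structure(list(set_label = set_label,
                 n_genes = length(x),
                 wilcoxon_p = max(wt$p.value, .Machine$double.xmin),
                 direction = sign(median(yv) - median(x)),
                 statistic = unname(wt$statistic)),
            class = "geneset_test")
}

#' @export
print.geneset_test <- function(x, ...) {
  cat(sprintf("Wilcoxon set test%s: n = %d, P = %.3g, direction = %+d\n",
              if (is.na(x$set_label)) "" else paste0(" [", x$set_label, "]"),
              x$n_genes, x$wilcoxon_p, x$direction))
  invisible(x)
}

## Penalized quadratic B-spline on equally spaced knots, third-order
## difference penalty (global quadratics unpenalized), GCV over a lambda grid.
pspline_fit <- function(x, y, nbasis = NULL, degree = 2L, penalty_order = 3L,
                        lambdas = 10^seq(-8, 8, length.out = 81)) {
  n <- length(x)
  if (is.null(nbasis)) nbasis <- max(penalty_order + 1L, min(n, 8L))
  xl <- min(x); xr <- max(x)
  if (xr <= xl) stop("x values are all identical")
  ndx <- nbasis - degree
  dx <- (xr - xl) / ndx
  knots <- seq(xl - degree * dx, xr + degree * dx, by = dx)
  B <- splines::splineDesign(knots, x, ord = degree + 1L, outer.ok = TRUE)
  D <- diff(diag(nbasis), differences = penalty_order)
  P <- crossprod(D)
  BtB <- crossprod(B); Bty <- crossprod(B, y)
  best <- NULL
  for (lam in lambdas) {
    Mi <- tryCatch(solve(BtB + lam * P), error = function(e) NULL)
    if (is.null(Mi)) next
    theta <- Mi %*% Bty
    fit <- drop(B %*% theta)
    edf <- sum(diag(Mi %*% BtB))
    denom <- n - edf
    # GCV degenerates when the fit approaches interpolation; cap edf at 0.8n
    if (denom < 0.2 * n) next
    gcv <- n * sum((y - fit)^2) / denom^2
    if (is.null(best) || gcv < best$gcv)
      best <- list(gcv = gcv, fitted = fit, lambda = lam, edf = edf)
  }
  if (is.null(best)) stop("no lambda on the grid gave a solvable fit")
  best
}

#' Spline residuals of set-level p-values against set size
#'
#' The power of a rank test grows with set size, so raw set-level p-values are
#' not comparable across binding subsets of different sizes. A smoothed
#' quadratic spline of p-value against the number of genes captures that
#' trend; the residual (observed minus fitted) scores each subset relative to
#' same-sized expectation — the subset with the extreme residual holds a
#' disproportionate share of dysregulated genes.
#'
#' @param points data frame with columns `set_label`, `n_genes`,
#'   `wilcoxon_p` (>= 4 rows).
#' @param scale `"p"` fits on the raw p scale (as plotted); `"neglog10"`
#'   fits on `-log10(p)` (orientation flips accordingly).
#' @return data frame of class `spline_residuals`: input columns plus
#'   `fitted` and `residual`, and attribute `lambda`.
#' @export
spline_residuals <- function(points, scale = c("p", "neglog10")) {
  scale <- match.arg(scale)
  stopifnot(is.data.frame(points),
            all(c("set_label", "n_genes", "wilcoxon_p") %in% names(points)))
  if (nrow(points) < 4)
    stop("need >= 4 sets for a smoothing spline; fit a plain quadratic instead")
  y <- if (scale == "p") points$wilcoxon_p else -log10(points$wilcoxon_p)
  fit <- pspline_fit(points$n_genes, y)
  out <- points
  out$fitted <- fit$fitted
  out$residual <- y - fit$fitted
  attr(out, "lambda") <- fit$lambda
  attr(out, "scale") <- scale
  class(out) <- c("spline_residuals", class(out))
  out
}

#' Pathway-level dysregulation tests
#'
#' Runs [wilcoxon_set_test()] for every pathway with at least `min_size`
#' members among the tested genes (size counted after intersection with the
#' quality-filtered universe); the background for each pathway is every other
#' tested gene. The significance threshold defaults to the Bonferroni
#' correction for the number of tested pathways across `n_constructs`
#' knockdown constructs (0.00011 for 218 pathways and 2 constructs).
#'
#' @param p_values named per-gene DE p-values.
#' @param pathway_db named list of gene-id vectors (e.g. from [read_gmt()]).
#' @param min_size minimum resolvable pathway size (default 20).
#' @param sig significance threshold; `NULL` (default) computes
#'   `bonferroni_threshold(n_tested, n_constructs)`.
#' @param notable secondary threshold (default 0.001).
#' @param n_constructs number of knockdown constructs sharing the family.
#' @return data frame: `pathway`, `n_genes`, `wilcoxon_p`, `direction`,
#'   `significant`, `notable`; attribute `sig_threshold`.
#' @export
pathway_tests <- function(p_values, pathway_db, min_size = 20L, sig = NULL,
                          notable = 0.001, n_constructs = 2L) {
  if (!length(pathway_db)) stop("empty pathway database")
  sizes <- vapply(pathway_db, function(g)
    length(intersect(g, names(p_values))), integer(1))
  tested <- names(pathway_db)[sizes >= min_size]
  if (is.null(sig))
    sig <- if (length(tested)) bonferroni_threshold(length(tested), n_constructs)
           else NA_real_
  rows <- lapply(tested, function(pw) {
    memb <- intersect(pathway_db[[pw]], names(p_values))
    res <- wilcoxon_set_test(p_values, memb,
                             setdiff(names(p_values), memb), set_label = pw)
    data.frame(pathway = pw, n_genes = res$n_genes,
               wilcoxon_p = res$wilcoxon_p, direction = res$direction,
               significant = res$wilcoxon_p < sig,
               notable = res$wilcoxon_p < notable,
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(pathway = character(), n_genes = integer(),
                         wilcoxon_p = numeric(), direction = numeric(),
                         significant = logical(), notable = logical())
  attr(out, "sig_threshold") <- sig
  attr(out, "n_skipped") <- sum(sizes < min_size)
  out
}

#' Risk-list dysregulation tests across contrasts
#'
#' For each risk-gene list and each knockdown contrast, tests whether the
#' list's DE p-values rank differently from the background (tested genes not
#' in the list). Two tests per list at familywise 0.05 give the per-test
#' level 0.025. Lists can optionally be restricted to bound genes first.
#'
#' @param p_value_sets named list (one element per contrast) of named
#'   per-gene p-value vectors.
#' @param risk_lists named list of gene-id vectors.
#' @param bound_filter optional gene set; lists and background are
#'   intersected with it before testing.
#' @param alpha per-test significance level (default `0.05 / 2`).
#' @return data frame: `list`, `contrast`, `n_genes`, `wilcoxon_p`,
#'   `direction`, `significant`, `testable`.
#' @export
risk_list_tests <- function(p_value_sets, risk_lists, bound_filter = NULL,
                            alpha = 0.05 / 2) {
  stopifnot(is.list(p_value_sets), is.list(risk_lists))
  rows <- list()
  for (ct in names(p_value_sets)) {
    pv <- p_value_sets[[ct]]
    universe <- names(pv)
    if (!is.null(bound_filter)) universe <- intersect(universe, bound_filter)
    for (ln in names(risk_lists)) {
      memb <- intersect(risk_lists[[ln]], universe)
      bg <- setdiff(universe, memb)
      if (!length(memb) || !length(bg)) {
        rows[[length(rows) + 1L]] <- data.frame(
          list = ln, contrast = ct, n_genes = length(memb),
          wilcoxon_p = NA_real_, direction = NA_real_,
          significant = NA, testable = FALSE, stringsAsFactors = FALSE)
        next
      }
      res <- wilcoxon_set_test(pv, memb, bg, set_label = ln)
      rows[[length(rows) + 1L]] <- data.frame(
        list = ln, contrast = ct, n_genes = res$n_genes,
        wilcoxon_p = res$wilcoxon_p, direction = res$direction,
        significant = res$wilcoxon_p < alpha, testable = TRUE,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
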