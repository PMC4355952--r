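## Knockdown RNA-seq pipeline: QC filters, normalization, VMR screening,
## TMM factors, Poisson / negative-binomial GLMs, strong-DE calls.

#' Bundle a count matrix with its sample metadata
#'
#' @param counts genes x units non-negative integer matrix with dimnames.
#' @param meta data frame with one row per unit: `unit`, `treatment`
#'   (e.g. `control`, `kdC`, `kdG`), `batch`.
#' @return list of class `count_dataset`.
#' @export
count_dataset <- function(counts, meta) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)),
            !is.null(colnames(counts)))
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  stopifnot(is.data.frame(meta),
            all(c("unit", "treatment", "batch") %in% names(meta)))
  if (!identical(sort(colnames(counts)), sort(as.character(meta$unit))))
    stop("meta$unit must match the count matrix columns")
  meta <- meta[match(colnames(counts), meta$unit), , drop = FALSE]
  if (anyNA(meta$treatment) || anyNA(meta$batch))
    stop("every unit needs a treatment and a batch label")
  structure(list(counts = counts, meta = meta), class = "count_dataset")
}

#' Low-count and single-unit gene filters
#'
#' Drops genes whose grand total across all units is `<= total_max` (printed
#' rule: 20), then genes whose entire remaining total comes from a single
#' experimental unit.
#'
#' @param counts genes x units count matrix.
#' @param total_max grand-total cutoff (inclusive removal).
#' @return list with the filtered `counts` and a `report`
#'   (`n_removed_lowcount`, `n_removed_single_unit`, `n_retained`).
#' @export
filter_low_counts <- function(counts, total_max = 20) {
  stopifnot(is.matrix(counts), nrow(counts) > 0)
  low <- rowSums(counts) <= total_max
  x <- counts[!low, , drop = FALSE]
  single <- rowSums(x > 0) == 1L
  list(counts = x[!single, , drop = FALSE],
       report = list(n_removed_lowcount = sum(low),
                     n_removed_single_unit = sum(single),
                     n_retained = sum(!single)))
}

#' Library-scale normalization
#'
#' Normalized count = raw count x (mean library size / own library size), so
#' every normalized column sums to the mean library size.
#'
#' @param counts genes x units count matrix (all column sums positive).
#' @return list with `normalized` matrix and `state`
#'   (`s_i`, `s_bar`, `scale_factors`).
#' @export
normalize_library_scale <- function(counts) {
  s_i <- colSums(counts)
  if (any(s_i <= 0)) stop("zero library size in unit(s): ",
                          paste(colnames(counts)[s_i <= 0], collapse = ", "))
  s_bar <- mean(s_i)
  f <- s_bar / s_i
  list(normalized = sweep(counts, 2, f, `*`),
       state = list(s_i = s_i, s_bar = s_bar, scale_factors = f))
}

#' Variance-to-mean ratio of one replicate group
#'
#' Sample variance over sample mean; defined as 0 when the mean is 0 (which,
#' for non-negative data, implies zero variance).
#'
#' @param x numeric vector of (normalized) counts for one gene in one group.
#' @return scalar VMR.
#' @export
vmr_stat <- function(x) {
  m <- mean(x)
  if (m == 0) return(0)
  var(x) / m
}

#' Overdispersion screen by within-group VMR
#'
#' Computes, per gene and treatment group, the variance-to-mean ratio of the
#' normalized counts and removes genes whose maximum group VMR exceeds
#' `threshold`. Under Poisson sampling the VMR is near 1; values above 100
#' indicate counts no count model in the pipeline should be asked to fit.
#'
#' @param normalized genes x units matrix of normalized counts.
#' @param treatment factor/character of length `ncol(normalized)`.
#' @param threshold removal cutoff on the max group VMR (strict; default 100).
#' @return list with filtered `counts`, `removed` (gene ids) and the per-gene
#'   `max_vmr` vector.
#' @export
vmr_filter <- function(normalized, treatment, threshold = 100) {
  stopifnot(length(treatment) == ncol(normalized))
  groups <- split(seq_along(treatment), treatment)
  if (any(vapply(groups, length, integer(1)) < 2))
    stop("every treatment group needs >= 2 units for a variance")
  gv <- vapply(groups, function(idx) {
    sub <- normalized[, idx, drop = FALSE]
    mu <- rowMeans(sub)
    v <- apply(sub, 1, var)
    ifelse(mu == 0, 0, v / mu)
  }, numeric(nrow(normalized)))
  if (is.null(dim(gv))) gv <- matrix(gv, nrow = 1)
  max_vmr <- apply(gv, 1, max)
  drop <- max_vmr > threshold
  list(counts = normalized[!drop, , drop = FALSE],
       removed = rownames(normalized)[drop],
       max_vmr = setNames(max_vmr, rownames(normalized)))
}

## column upper-quartile of count-per-library values, edgeR-style reference pick
tmm_reference <- function(counts, lib_size) {
  f75 <- apply(sweep(counts, 2, lib_size, `/`), 2, quantile, probs = 0.75)
  which.min(abs(f75 - mean(f75)))
}

#' Trimmed-mean (TMM) normalization factors
#'
#' Composition-bias correction: per unit, the weighted mean of gene-wise
#' log2 ratios to a reference unit after trimming the most extreme 30 percent
#' of log-ratios and 5 percent of absolute intensities from each tail,
#' exponentiated, then re-centred so the factors multiply to 1. Weights are
#' the inverse asymptotic variances of the log-ratios. With `recenter =
#' FALSE` the raw per-unit factors are returned.
#'
#' @param counts genes x units count matrix.
#' @param lib_size library sizes (default column sums).
#' @param reference reference column index; default: unit whose
#'   upper-quartile count-per-library value is closest to the mean.
#' @param logratio_trim,sum_trim trim fractions per tail for log-ratios and
#'   absolute intensities.
#' @param recenter divide by the geometric mean so factors multiply to 1.
#' @return named numeric vector of per-unit scale factors.
#' @export
trimmed_mean_factors <- function(counts, lib_size = colSums(counts),
                                 reference = NULL, logratio_trim = 0.3,
                                 sum_trim = 0.05, recenter = TRUE) {
  stopifnot(is.matrix(counts), length(lib_size) == ncol(counts))
  if (is.null(reference)) reference <- tmm_reference(counts, lib_size)
  ref <- counts[, reference]; lib_ref <- lib_size[reference]
  f <- vapply(seq_len(ncol(counts)), function(j) {
    obs <- counts[, j]; lib_obs <- lib_size[j]
    keep <- obs > 0 & ref > 0
    if (!any(keep))
      stop("unit ", colnames(counts)[j],
           " shares no expressed genes with the reference")
    o <- obs[keep]; r <- ref[keep]
    M <- log2((o / lib_obs) / (r / lib_ref))
    A <- 0.5 * log2((o / lib_obs) * (r / lib_ref))
    w <- (lib_obs - o) / (lib_obs * o) + (lib_ref - r) / (lib_ref * r)
    if (max(abs(M)) < 1e-6) return(1)
    n <- length(M)
    loM <- floor(n * logratio_trim) + 1; hiM <- n + 1 - loM
    loA <- floor(n * sum_trim) + 1; hiA <- n + 1 - loA
    rM <- rank(M); rA <- rank(A)
    kp <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
    if (!any(kp)) return(1)
    val <- 2^(sum(M[kp] / w[kp]) / sum(1 / w[kp]))
    if (!is.finite(val) || val <= 0) 1 else val
  }, numeric(1))
  if (recenter) f <- f / exp(mean(log(f)))
  setNames(f, colnames(counts))
}

#' Bonferroni threshold for a two-construct experiment
#'
#' `alpha / (n_tests_1 * n_tests_2)`; e.g. 14,841 genes x 2 knockdown
#' constructs at `alpha = 0.05` gives 1.68e-6.
#'
#' @param n_tests_1,n_tests_2 positive integers.
#' @param alpha familywise error rate in (0, 1).
#' @return the exact threshold (round with `signif()` for reporting).
#' @export
bonferroni_threshold <- function(n_tests_1, n_tests_2 = 1L, alpha = 0.05) {
  stopifnot(n_tests_1 >= 1, n_tests_2 >= 1, alpha > 0, alpha < 1)
  alpha / (n_tests_1 * n_tests_2)
}

## method-of-moments NB dispersion per gene, shrunk toward the global mean
mom_dispersion <- function(normalized, treatment, shrink_weight = 0.5) {
  groups <- split(seq_along(treatment), treatment)
  phi <- vapply(seq_len(nrow(normalized)), function(i) {
    est <- vapply(groups, function(idx) {
      x <- normalized[i, idx]
      m <- mean(x)
      if (m <= 0) return(NA_real_)
      max(0, (var(x) - m) / m^2)
    }, numeric(1))
    if (all(is.na(est))) 0 else mean(est, na.rm = TRUE)
  }, numeric(1))
  global <- mean(phi)
  (1 - shrink_weight) * phi + shrink_weight * global
}

#' Per-gene count GLMs for a knockdown contrast
#'
#' Fits, gene by gene, a log-linear model with batch and knockdown effects on
#' the units of one contrast (knockdown arm vs control), with per-unit
#' offsets equal to the log effective library size (library size x TMM
#' factor). The knockdown coefficient is tested by likelihood-ratio (default)
#' or Wald test. `model = "poisson"` fixes the dispersion at 0; `model =
#' "negbin"` uses a per-gene method-of-moments dispersion shrunk toward the
#' global mean (weight `shrink_weight`).
#'
#' @param dataset [count_dataset()] (quality-filtered counts).
#' @param contrast treatment label tested against `control`.
#' @param model `"poisson"` or `"negbin"`.
#' @param offsets optional per-unit log-offsets (full-length, named by unit);
#'   default `log(lib_size * TMM factor)` computed from the supplied counts.
#' @param test `"lrt"` (default) or `"wald"`.
#' @param control_label treatment label of the reference arm.
#' @param shrink_weight shrinkage weight toward the global mean dispersion.
#' @return data frame of class `de_result`: `gene`, `p_value`,
#'   `log2_fold_change`, `log2_cpm`, `model`, `contrast`.
#' @export
fit_counts_glm <- function(dataset, contrast, model = c("poisson", "negbin"),
                           offsets = NULL, test = c("lrt", "wald"),
                           control_label = "control", shrink_weight = 0.5) {
  model <- match.arg(model)
  test <- match.arg(test)
  stopifnot(inherits(dataset, "count_dataset"))
  counts <- dataset$counts; meta <- dataset$meta
  if (!contrast %in% meta$treatment)
    stop("no units with treatment '", contrast, "'")
  if (is.null(offsets)) {
    lib <- colSums(counts)
    offsets <- log(lib * trimmed_mean_factors(counts, lib_size = lib))
  } else {
    stopifnot(length(offsets) == ncol(counts))
  }
  keep <- meta$treatment %in% c(control_label, contrast)
  y <- counts[, keep, drop = FALSE]
  m <- meta[keep, , drop = FALSE]
  off <- offsets[keep]
  kd <- as.integer(m$treatment == contrast)
  batch <- factor(m$batch)
  X_full <- if (nlevels(batch) > 1) model.matrix(~ batch + kd)
            else model.matrix(~ kd)
  X_red <- X_full[, colnames(X_full) != "kd", drop = FALSE]
  if (qr(X_full)$rank < ncol(X_full)) stop("design matrix is not full rank")
  all_zero <- rowSums(y) == 0
  if (any(all_zero))
    warning(sum(all_zero), " all-zero gene(s) excluded; run filter_low_counts first")
  genes <- rownames(y)[!all_zero]
  phi <- if (model == "negbin") {
    norm <- sweep(y, 2, mean(exp(off)) / exp(off), `*`)
    mom_dispersion(norm[!all_zero, , drop = FALSE], m$treatment, shrink_weight)
  } else rep(0, length(genes))
  cpm <- rowMeans(sweep(y[!all_zero, , drop = FALSE], 2, exp(off), `/`)) * 1e6
  kd_col <- which(colnames(X_full) == "kd")
  res <- vapply(seq_along(genes), function(i) {
    yi <- y[genes[i], ]
    fam <- if (phi[i] > 0) MASS::negative.binomial(theta = 1 / phi[i])
           else poisson()
    # stray non-convergence on pathological genes is tolerated; such genes
    # are expected to be removed upstream by the VMR screen
    full <- suppressWarnings(glm.fit(X_full, yi, family = fam, offset = off,
                                     control = list(maxit = 50)))
    beta <- full$coefficients[kd_col]
    if (test == "lrt") {
      red <- suppressWarnings(glm.fit(X_red, yi, family = fam, offset = off,
                                      control = list(maxit = 50)))
      stat <- max(0, red$deviance - full$deviance)
      p <- pchisq(stat, df = 1, lower.tail = FALSE)
    } else {
      wmat <- full$weights
      XtWX <- crossprod(X_full * sqrt(wmat))
      se <- sqrt(diag(solve(XtWX)))[kd_col]
      p <- 2 * pnorm(abs(beta / se), lower.tail = FALSE)
    }
    c(p = max(p, .Machine$double.xmin), lfc = beta / log(2))
  }, c(p = 0, lfc = 0))
  out <- data.frame(gene = genes,
                    p_value = res["p", ],
                    log2_fold_change = res["lfc", ],
                    log2_cpm = log2(pmax(cpm, .Machine$double.xmin)),
                    model = model, contrast = contrast,
                    stringsAsFactors = FALSE)
  class(out) <- c("de_result", class(out))
  out
}

#' Strongly dysregulated genes
#'
#' Genes passing all three printed criteria: p-value below the Bonferroni
#' threshold, absolute log2 fold change above `lfc_min`, and log2 CPM inside
#' `cpm_range` (the range where the Poisson assumption is trustworthy).
#'
#' @param results `de_result` data frame from [fit_counts_glm()].
#' @param p_max significance cutoff (default 1.68e-6, the Bonferroni
#'   threshold for 14,841 genes x 2 constructs).
#' @param lfc_min minimum `|log2FC|` (strict).
#' @param cpm_range inclusive `log2 CPM` window.
#' @return character vector of gene ids.
#' @export
strong_de <- function(results, p_max = 1.68e-6, lfc_min = 0.1,
                      cpm_range = c(2, 10)) {
  keep <- results$p_value < p_max &
    abs(results$log2_fold_change) > lfc_min &
    results$log2_cpm >= cpm_range[1] & results$log2_cpm <= cpm_range[2]
  results$gene[keep]
}
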