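mk_meta <- function(units) {
  data.frame(unit = units,
             treatment = rep(c("control", "kdC"), each = length(units) / 2),
             batch = rep(c("b1", "b2"), length(units) / 2))
}

test_that("filter_low_counts applies the printed boundary rules in order", {
  m <- rbind(at20 = c(10, 10, 0, 0), at21 = c(10, 11, 0, 0),
             single = c(0, 0, 0, 30), two_units = c(15, 15, 0, 0))
  colnames(m) <- paste0("u", 1:4)
  res <- filter_low_counts(m)
  expect_setequal(rownames(res$counts), c("at21", "two_units"))
  expect_equal(res$report$n_removed_lowcount, 1L)
  expect_equal(res$report$n_removed_single_unit, 1L)
  expect_equal(res$report$n_retained, 2L)
  expect_equal(res$report$n_removed_lowcount + res$report$n_removed_single_unit +
                 res$report$n_retained, nrow(m))
})

test_that("normalize_library_scale equalizes column sums at the mean library", {
  m <- matrix(c(60, 40, 120, 80), 2, dimnames = list(c("g1", "g2"), c("u1", "u2")))
  res <- normalize_library_scale(m)
  expect_equal(unname(res$state$scale_factors), c(1.5, 0.75))
  expect_equal(unname(colSums(res$normalized)), rep(150, 2))
  # equal libraries: identity transform
  eq <- matrix(c(10, 20, 15, 15), 2)
  rownames(eq) <- c("a", "b"); colnames(eq) <- c("x", "y")
  expect_equal(normalize_library_scale(eq)$normalized, eq)
  # random matrix: every normalized column sums to s_bar; grand total conserved
  set.seed(8)
  r <- matrix(rpois(20, 50), 5, 4, dimnames = list(paste0("g", 1:5), paste0("u", 1:4)))
  nr <- normalize_library_scale(r)
  expect_equal(unname(colSums(nr$normalized)), rep(nr$state$s_bar, 4))
  expect_equal(sum(nr$normalized), sum(r))
  z <- r; z[, 2] <- 0
  expect_error(normalize_library_scale(z), "zero library")
})

test_that("vmr_stat and vmr_filter match hand computations", {
  expect_equal(vmr_stat(c(1, 1, 1, 1)), 0)
  expect_equal(vmr_stat(c(0, 0, 0, 40)), 400 / 10) # var 400, mean 10
  expect_equal(vmr_stat(c(0, 0, 0, 0)), 0)
  m <- rbind(flat = rep(5, 8),
             spiky = c(0, 0, 0, 4040, 5, 5, 5, 5),
             mild = c(0, 0, 0, 40, 5, 5, 5, 5))
  colnames(m) <- paste0("u", 1:8)
  tr <- rep(c("A", "B"), each = 4)
  res <- vmr_filter(m, tr)
  expect_equal(res$removed, "spiky") # VMR 4040 in group A
  expect_equal(unname(res$max_vmr["mild"]), 40)
  expect_setequal(rownames(res$counts), c("flat", "mild"))
  expect_error(vmr_filter(m, c(rep("A", 7), "B")), ">= 2 units")
})

test_that("trimmed_mean_factors handles the degenerate designs", {
  set.seed(4)
  base <- rpois(300, 100) + 1
  m <- cbind(u1 = base, u2 = base, u3 = base)
  rownames(m) <- paste0("g", seq_len(nrow(m)))
  expect_equal(unname(trimmed_mean_factors(m)), rep(1, 3))
  # a pure 2x column at equal *supplied* library sizes gives factor 2
  # before re-centering (with library sizes from column sums, standard TMM
  # correctly returns 1)
  d <- cbind(u1 = base, u2 = 2L * base)
  f <- trimmed_mean_factors(d, lib_size = c(1e5, 1e5), reference = 1,
                            recenter = FALSE)
  expect_equal(unname(f), c(1, 2), tolerance = 1e-12)
  f2 <- trimmed_mean_factors(d, reference = 1)
  expect_equal(unname(f2), c(1, 1), tolerance = 1e-12)
})

test_that("trimmed_mean_factors agrees with the edgeR oracle", {
  skip_if_not_installed("edgeR")
  set.seed(12)
  m <- matrix(rnbinom(500 * 6, mu = rlnorm(500, 4, 1), size = 10), 500, 6)
  # plant asymmetric composition bias in column 6
  m[1:25, 6] <- m[1:25, 6] * 8L
  dimnames(m) <- list(paste0("g", 1:500), paste0("u", 1:6))
  ours <- trimmed_mean_factors(m)
  theirs <- edgeR::calcNormFactors(m, method = "TMM")
  expect_equal(unname(ours), unname(theirs), tolerance = 1e-6)
})

test_that("trimmed mean recovers planted composition bias within 5 percent", {
  set.seed(31)
  n <- 200
  mu <- rlnorm(n, 5, 1)
  a <- rpois(n, mu)
  bmu <- mu
  bmu[1:10] <- bmu[1:10] * 30 # 5% of genes grossly up in column b only
  b <- rpois(n, bmu)
  m <- cbind(u1 = a + 1L, u2 = b + 1L)
  rownames(m) <- paste0("g", 1:n)
  f <- trimmed_mean_factors(m, reference = 1, recenter = FALSE)
  # truth: after removing the biased genes, u2 matches u1 except for the
  # library inflation caused by the planted genes
  truth <- sum(bmu) / sum(mu)
  expect_equal(unname(f[2]), 1 / truth, tolerance = 0.05)
})

test_that("bonferroni_threshold reproduces the printed values", {
  expect_equal(signif(bonferroni_threshold(14841, 2), 3), 1.68e-6)
  expect_equal(signif(bonferroni_threshold(218, 2), 2), 0.00011)
  expect_equal(bonferroni_threshold(1, 1, 0.05), 0.05)
  expect_equal(bonferroni_threshold(2, 1, 0.05), 0.025)
})

test_that("fit_counts_glm returns null results on constant counts", {
  m <- matrix(50L, 3, 8, dimnames = list(paste0("g", 1:3), paste0("u", 1:8)))
  ds <- count_dataset(m, mk_meta(colnames(m)))
  res <- fit_counts_glm(ds, "kdC", model = "poisson",
                        offsets = rep(log(1e4), 8))
  expect_s3_class(res, "de_result")
  expect_equal(res$log2_fold_change, rep(0, 3), tolerance = 1e-8)
  expect_true(all(res$p_value > 0.99))
  expect_equal(res$log2_cpm, rep(log2(50 / 1e4 * 1e6), 3), tolerance = 1e-9)
})

test_that("the Poisson LRT matches a direct-optimization oracle", {
  set.seed(44)
  units <- paste0("u", 1:8)
  meta <- mk_meta(units)
  off <- log(runif(8, 0.8, 1.2) * 1e4)
  kd <- as.integer(meta$treatment == "kdC")
  X_full <- model.matrix(~ factor(meta$batch) + kd)
  X_red <- X_full[, 1:2]
  m <- matrix(rpois(10 * 8, lambda = exp(log(80) +
                rep(kd, each = 10) * rnorm(10, 0, 0.3))), 10, 8,
              dimnames = list(paste0("g", 1:10), units))
  ds <- count_dataset(m, meta)
  res <- fit_counts_glm(ds, "kdC", model = "poisson", offsets = off)
  for (i in 1:10) {
    p_or <- oracle_poisson_lrt(m[i, ], X_full, X_red, off)
    expect_lt(abs(res$p_value[i] - p_or), 1e-6)
  }
})

test_that("planted effects are detected and the Wald option works", {
  set.seed(55)
  units <- paste0("u", 1:8)
  meta <- mk_meta(units)
  kd <- as.integer(meta$treatment == "kdC")
  lam <- outer(rep(2000, 200), 0.9 + 0.2 * runif(8))
  lam[1:20, kd == 1] <- lam[1:20, kd == 1] * 1.5 # 10% of genes affected
  m <- matrix(rpois(length(lam), lam), nrow(lam), ncol(lam),
              dimnames = list(paste0("g", 1:200), units))
  ds <- count_dataset(m, meta)
  res <- fit_counts_glm(ds, "kdC", model = "poisson")
  hits <- res$gene[res$p_value < bonferroni_threshold(200, 2)]
  expect_gt(mean(paste0("g", 1:20) %in% hits), 0.9)
  expect_equal(mean(res$log2_fold_change[1:20]), log2(1.5), tolerance = 0.1)
  resw <- fit_counts_glm(ds, "kdC", model = "poisson", test = "wald")
  expect_gt(cor(-log10(res$p_value), -log10(resw$p_value)), 0.99)
  resn <- fit_counts_glm(ds, "kdC", model = "negbin")
  expect_gt(mean(paste0("g", 1:20) %in%
                   resn$gene[resn$p_value < bonferroni_threshold(200, 2)]), 0.8)
})

test_that("strong_de applies all three printed criteria", {
  res <- data.frame(gene = c("in", "weak_lfc", "high_cpm", "weak_p"),
                    p_value = c(1e-7, 1e-7, 1e-7, 1e-5),
                    log2_fold_change = c(0.2, 0.05, 0.5, 0.5),
                    log2_cpm = c(5, 5, 11, 5))
  expect_equal(strong_de(res), "in")
  expect_equal(strong_de(res, p_max = 1e-4), c("in", "weak_p"))
})

test_that("count_dataset validates its inputs", {
  m <- matrix(1L, 2, 2, dimnames = list(c("g1", "g2"), c("u1", "u2")))
  meta <- data.frame(unit = c("u1", "u2"), treatment = c("control", "kdC"),
                     batch = c("b1", "b1"))
  expect_s3_class(count_dataset(m, meta), "count_dataset")
  expect_error(count_dataset(m - 2L, meta), "non-negative")
  expect_error(count_dataset(m, meta[1, ]), "match")
  bad <- meta; bad$batch[1] <- NA
  expect_error(count_dataset(m, bad), "batch")
})
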