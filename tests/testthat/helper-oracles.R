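# Independent brute-force oracles and shared toy fixtures.

# Per-base oracle for reproducible regions: a base belongs to the output iff
# some pair (a in A, b in B) overlaps by >= 1 bp and the base lies inside the
# merged span of that pair.  Coordinates must be small.
bf_reproducible <- function(a, b) {
  out <- list()
  for (ch in union(unique(a$chrom), unique(b$chrom))) {
    ai <- a[a$chrom == ch, , drop = FALSE]
    bi <- b[b$chrom == ch, , drop = FALSE]
    if (!nrow(ai) || !nrow(bi)) next
    hi <- max(ai$end, bi$end)
    cov <- logical(hi)
    for (i in seq_len(nrow(ai))) for (j in seq_len(nrow(bi))) {
      ov <- min(ai$end[i], bi$end[j]) - max(ai$start[i], bi$start[j])
      if (ov >= 1) {
        lo <- min(ai$start[i], bi$start[j]); up <- max(ai$end[i], bi$end[j])
        cov[(lo + 1):up] <- TRUE
      }
    }
    if (any(cov)) {
      r <- rle(cov)
      ends <- cumsum(r$lengths); starts <- ends - r$lengths
      keep <- r$values
      out[[ch]] <- data.frame(chrom = ch, start = starts[keep],
                              end = ends[keep], stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(chd8net::intervals())
  df <- do.call(rbind, out)
  df[order(df$chrom, df$start), , drop = FALSE]
}

rand_intervals <- function(n, max_coord = 10000, chroms = c("chr1", "chr2")) {
  s <- sample.int(max_coord - 50, n, replace = TRUE)
  w <- sample.int(300, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = s, end = pmin(s + w, max_coord),
             stringsAsFactors = FALSE)
}

expect_same_intervals <- function(x, y) {
  rownames(x) <- rownames(y) <- NULL
  expect_equal(x[order(x$chrom, x$start), ], y[order(y$chrom, y$start), ],
               ignore_attr = TRUE)
}

# Exact p-value for the weighted permutation test by enumerating every
# ordered without-replacement draw (successive sampling).  Feasible for
# universes of ~10 genes and k <= 4.
exact_perm_p <- function(weights, k, hit_set, observed) {
  ids <- names(weights)
  total_p <- 0
  recurse <- function(remaining, w_rem, hits, depth, prob) {
    if (depth == k) {
      if (hits >= observed) total_p <<- total_p + prob
      return(invisible(NULL))
    }
    for (g in remaining) {
      pg <- weights[[g]] / w_rem
      recurse(setdiff(remaining, g), w_rem - weights[[g]],
              hits + (g %in% hit_set), depth + 1, prob * pg)
    }
  }
  recurse(ids[weights > 0], sum(weights), 0, 0, 1)
  total_p
}

# Exact two-sided rank-sum p-value by enumerating all group assignments.
exact_ranksum_p <- function(x, y) {
  all_v <- c(x, y)
  n <- length(all_v); nx <- length(x)
  r <- rank(all_v)
  obs <- sum(r[seq_len(nx)])
  combos <- utils::combn(n, nx)
  stats <- apply(combos, 2, function(idx) sum(r[idx]))
  mu <- nx * (n + 1) / 2
  mean(abs(stats - mu) >= abs(obs - mu) - 1e-9)
}

# Toy gene models on one chromosome: plus-strand gene with promoter
# [tss-1000, tss) and two exons, minus-strand gene further along.
make_toy_genes <- function() {
  list(
    gene_model("gA", "chr1", "+", tss = 5000,
               exons = data.frame(start = c(5200, 6000),
                                  end = c(5500, 6400)),
               g = c(0.5, 0.6), cov = 1, active = TRUE),
    gene_model("gB", "chr1", "-", tss = 20000,
               exons = data.frame(start = c(18000, 18800),
                                  end = c(18500, 19300)),
               g = 0.4, cov = 0.9, active = FALSE))
}

# Poisson GLM likelihood-ratio oracle by direct optimization (BFGS with
# analytic gradient), independent of glm.fit's IRLS.
oracle_poisson_lrt <- function(y, X_full, X_red, off) {
  nll <- function(beta, X) {
    eta <- drop(X %*% beta) + off
    -sum(y * eta - exp(eta))
  }
  gr <- function(beta, X) {
    eta <- drop(X %*% beta) + off
    -drop(crossprod(X, y - exp(eta)))
  }
  opt <- function(X) optim(rep(0, ncol(X)), nll, gr, X = X, method = "BFGS",
                           control = list(maxit = 1000, reltol = 1e-15))$value
  stat <- max(0, 2 * (opt(X_red) - opt(X_full)))
  pchisq(stat, df = 1, lower.tail = FALSE)
}
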