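## Synthetic-data generators: every pipeline input with planted ground truth.
##
## The defaults describe one fixed "stated world" (documented in the methods
## vignette): a desk-scale genome of 2,000 genes, three binding contexts with
## a shared conserved core, a 120-gene risk list enriched among bound genes,
## a 3-arm x 4-replicate knockdown count design with two batches, block-
## correlated co-expression around seed genes, and Z-scores from an
## Ising-structured hidden risk state with binding effect d.

#' Simulation configuration
#'
#' All generator knobs with their stated-world defaults. `seed` is mandatory;
#' every generator is a pure function of (config, seed).
#'
#' @param seed integer RNG seed.
#' @param ... overrides for any default field, see `formals(sim_config)`.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed, ...) {
  if (missing(seed)) stop("seed is mandatory")
  cfg <- list(
    seed = as.integer(seed),
    # genome
    n_genes = 2000L, n_chroms = 4L, gene_spacing = 30000L,
    # binding contexts
    context_names = c("hNSC", "brain", "mouse_cortex"),
    binding_rate = 0.25, sharing_rate = 0.6, pair_sharing = 0.15,
    peak_width = 200L, peak_jitter = 30L, noise_peaks = 150L,
    # risk list
    risk_size = 120L, risk_odds = 8,
    # knockdown counts
    arms = c("control", "kdC", "kdG"), reps_per_arm = 4L, n_batches = 2L,
    base_meanlog = log(200), base_sdlog = 1,
    # NB parameterized by success rate: VMR = 1/nb_success = 20 at any mean
    count_model = "negbin", nb_success = 0.05,
    batch_sd = 0.1, libsize_sd = 0.2,
    kd_lfc = 0.5, kd_frac = 0.3, down_frac = 0.8,
    n_qc_lowcount = 30L, n_qc_single = 10L, n_qc_vmr = 10L,
    # co-expression
    coexpr_samples = 30L, block_size = 25L, block_rho = 0.9,
    # hidden risk field
    ising = ising_params(b = -2, eta = 0.5, d = 1.5, mu = 2, sigma = 1),
    graph_model = "scale-free", graph_m = 2L)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  rates <- c(cfg$binding_rate, cfg$sharing_rate, cfg$down_frac, cfg$kd_frac,
             cfg$block_rho)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  structure(cfg, class = "sim_config")
}

maybe_seed <- function(seed) if (!is.null(seed)) set.seed(seed)

#' Generate a toy genome of gene models
#'
#' Genes laid out sequentially on toy chromosomes, each with 1–10 exon loci
#' (GC fraction g ~ Beta(5,5), size s ~ LogNormal, coverage c ~ Beta(20,2)),
#' random strand, 1–3 isoform TSSs within 500 nt, and active promoters for
#' ~70 percent of genes. Exons never overlap the promoter region, so peak
#' classification is unambiguous.
#'
#' @param config [sim_config()].
#' @param seed optional seed (`NULL` uses the current RNG state; callers that
#'   want reproducibility seed here or upstream).
#' @return list of [gene_model()] objects.
#' @export
gen_genome <- function(config, seed = NULL) {
  maybe_seed(seed)
  n <- config$n_genes
  if (n < 10) stop("n_genes must be >= 10")
  chrom_of <- sprintf("chr%d", ((seq_len(n) - 1L) %% config$n_chroms) + 1L)
  slot <- (seq_len(n) - 1L) %/% config$n_chroms
  base <- 5000L + slot * config$gene_spacing
  lapply(seq_len(n), function(i) {
    strand <- sample(c("+", "-"), 1)
    n_tss <- sample(1:3, 1)
    tss0 <- base[i] + 1500L
    tss <- tss0 + c(0L, sample(0:500, n_tss - 1L, replace = TRUE))
    n_ex <- sample(1:10, 1)
    sizes <- pmax(1, round(rlnorm(n_ex, meanlog = log(150), sdlog = 0.8)))
    gaps <- sample(50:200, n_ex, replace = TRUE)
    if (strand == "+") {
      st <- max(tss) + 700L + cumsum(gaps) + cumsum(c(0L, head(sizes, -1)))
    } else {
      tot <- sum(sizes) + sum(gaps)
      st <- min(tss) - 1700L - tot + cumsum(gaps) + cumsum(c(0L, head(sizes, -1)))
    }
    gene_model(sprintf("g%04d", i), chrom_of[i], strand, tss = tss,
               exons = data.frame(start = st, end = st + sizes),
               g = rbeta(n_ex, 5, 5), cov = rbeta(n_ex, 20, 2),
               active = runif(1) < 0.7)
  })
}

#' Generate replicate peak sets per context with planted bound genes
#'
#' A conserved core of bound genes is shared across all contexts
#' (`sharing_rate` of each context's bound set); the remainder is
#' context-specific. Every bound gene gets one true promoter peak, emitted in
#' both replicates with jittered coordinates; each replicate also carries
#' unreproducible noise peaks in gene-free territory.
#'
#' @inheritParams gen_genome
#' @param genome output of [gen_genome()].
#' @return list with `peaks` (context -> list(rep1, rep2) interval data
#'   frames) and `truth` (`core`, per-context `bound` gene sets).
#' @export
gen_peaks <- function(config, genome, seed = NULL) {
  maybe_seed(seed)
  ids <- gene_ids(genome)
  n_bound <- round(config$binding_rate * length(ids))
  n_core <- round(config$sharing_rate * n_bound)
  core <- sample(ids, n_core)
  # graded sharing: the first two contexts (the human ones) share an extra
  # tranche beyond the all-context core
  n_pair <- round(config$pair_sharing * n_bound)
  pair_set <- sample(setdiff(ids, core), n_pair)
  peaks <- list(); bound <- list()
  for (k in seq_along(config$context_names)) {
    ctx <- config$context_names[k]
    shared_here <- c(core, if (k <= 2) pair_set)
    extra <- sample(setdiff(ids, shared_here),
                    max(0, n_bound - length(shared_here)))
    bg <- sort(c(shared_here, extra))
    bound[[ctx]] <- bg
    true_pk <- if (!length(bg)) empty_intervals() else
      do.call(rbind, lapply(bg, function(g) {
      gm <- genome[[match(g, ids)]]
      p <- gm$promoter_union[1, ]
      mid <- floor((p$start + p$end) / 2)
      half <- config$peak_width %/% 2L
      data.frame(chrom = p$chrom, start = max(p$start, mid - half),
                 end = min(p$end, mid + half), stringsAsFactors = FALSE)
    }))
    jitter_pk <- function(pk) {
      if (!nrow(pk)) return(pk)
      j1 <- sample(-config$peak_jitter:config$peak_jitter, nrow(pk), TRUE)
      j2 <- sample(-config$peak_jitter:config$peak_jitter, nrow(pk), TRUE)
      out <- pk
      out$start <- pmax(0, pk$start + j1)
      out$end <- pmax(out$start + 1, pk$end + j2)
      out
    }
    # noise peaks live far beyond any gene, on disjoint slots per replicate
    desert <- max(vapply(genome, function(g) max(g$promoter_union$end),
                         numeric(1))) + 1e6
    noise <- function(parity) {
      k <- config$noise_peaks
      slots <- (seq_len(k) * 2L + parity) * 1000L
      data.frame(chrom = sample(sprintf("chr%d", seq_len(config$n_chroms)),
                                k, TRUE),
                 start = desert + slots, end = desert + slots + 300L,
                 stringsAsFactors = FALSE)
    }
    peaks[[ctx]] <- list(rep1 = sort_intervals(rbind(jitter_pk(true_pk),
                                                     noise(0L))),
                         rep2 = sort_intervals(rbind(jitter_pk(true_pk),
                                                     noise(1L))))
  }
  list(peaks = peaks, truth = list(core = sort(core),
                                   pair = sort(pair_set), bound = bound))
}

#' Generate a risk-gene list enriched among bound genes
#'
#' Risk genes are drawn without replacement with an odds multiplier for bound
#' genes; optionally the base weight follows mutability, to exercise
#' confounder control in the permutation tests.
#'
#' @inheritParams gen_genome
#' @param bound character vector of bound gene ids receiving the odds boost.
#' @param universe candidate gene ids.
#' @param mutability_weights optional named base weights (e.g. `M` from
#'   [mutability_table()]).
#' @return character vector of risk gene ids.
#' @export
gen_risk_list <- function(config, bound, universe, mutability_weights = NULL,
                          seed = NULL) {
  maybe_seed(seed)
  if (config$risk_odds < 1) stop("enrichment odds must be >= 1")
  w <- if (is.null(mutability_weights)) setNames(rep(1, length(universe)),
                                                 universe)
       else mutability_weights[universe]
  w[names(w) %in% bound] <- w[names(w) %in% bound] * config$risk_odds
  sort(weighted_sample_wor(w, min(config$risk_size, sum(w > 0))))
}

#' Generate a knockdown count matrix with planted effects and QC violators
#'
#' Negative-binomial (default) or Poisson counts with lognormal baselines,
#' gene-specific batch effects, library-size variation and knockdown effects
#' (predominantly downregulation) on a fraction of the bound genes, shared by
#' both constructs. Extra genes violating each QC rule (grand total <= 20,
#' single-unit expression, extreme within-group VMR) are appended under
#' `qc_*` identifiers.
#'
#' @inheritParams gen_genome
#' @param gene_ids character vector of gene identifiers.
#' @param bound gene ids eligible for knockdown effects.
#' @return list with `dataset` ([count_dataset()]) and `truth`
#'   (`de_genes`, `lfc` named log2 effects, `qc_lowcount`, `qc_single`,
#'   `qc_vmr`).
#' @export
gen_counts <- function(config, gene_ids, bound, seed = NULL) {
  maybe_seed(seed)
  arms <- config$arms
  reps <- config$reps_per_arm
  stopifnot(length(arms) >= 2, reps >= 2, config$n_batches >= 2)
  units <- paste0(rep(arms, each = reps), "_r", seq_len(reps))
  treatment <- rep(arms, each = reps)
  batch <- paste0("b", rep_len(rep(seq_len(config$n_batches),
                                   each = ceiling(reps / config$n_batches)),
                               reps))
  batch <- rep(batch[seq_len(reps)], times = length(arms))
  n <- length(gene_ids)
  base <- rlnorm(n, config$base_meanlog, config$base_sdlog)
  batch_eff <- matrix(1, n, config$n_batches)
  for (bj in 2:config$n_batches)
    batch_eff[, bj] <- exp(rnorm(n, 0, config$batch_sd))
  lib <- exp(rnorm(length(units), 0, config$libsize_sd))
  kd_arms <- setdiff(arms, "control")
  n_de <- round(config$kd_frac * length(bound))
  de_genes <- sort(sample(bound, n_de))
  sgn <- ifelse(runif(n_de) < config$down_frac, -1, 1)
  lfc <- setNames(sgn * config$kd_lfc * runif(n_de, 0.8, 1.5), de_genes)
  mu <- matrix(base, n, length(units),
               dimnames = list(gene_ids, units))
  for (u in seq_along(units)) {
    bj <- as.integer(sub("b", "", batch[u]))
    mu[, u] <- mu[, u] * batch_eff[, bj] * lib[u]
    if (treatment[u] %in% kd_arms)
      mu[de_genes, u] <- mu[de_genes, u] * 2^lfc
  }
  draw <- function(m) {
    if (config$count_model == "poisson") return(rpois(length(m), m))
    pr <- config$nb_success
    rnbinom(length(m), size = m * pr / (1 - pr), prob = pr)
  }
  counts <- matrix(draw(mu), n, length(units), dimnames = dimnames(mu))
  # planted QC violators
  qc_low <- qc_single <- qc_vmr <- character(0)
  add_rows <- function(counts, block, ids) {
    rownames(block) <- ids
    rbind(counts, block)
  }
  if (config$n_qc_lowcount > 0) {
    qc_low <- sprintf("qc_low%03d", seq_len(config$n_qc_lowcount))
    blk <- matrix(rpois(config$n_qc_lowcount * length(units), 0.2),
                  config$n_qc_lowcount)
    # cap the grand total at the rule boundary
    over <- rowSums(blk) > 20
    blk[over, ] <- 0L
    counts <- add_rows(counts, blk, qc_low)
  }
  if (config$n_qc_single > 0) {
    qc_single <- sprintf("qc_single%03d", seq_len(config$n_qc_single))
    blk <- matrix(0L, config$n_qc_single, length(units))
    blk[cbind(seq_len(config$n_qc_single),
              sample(length(units), config$n_qc_single, TRUE))] <-
      sample(25:80, config$n_qc_single, TRUE)
    counts <- add_rows(counts, blk, qc_single)
  }
  if (config$n_qc_vmr > 0) {
    qc_vmr <- sprintf("qc_vmr%03d", seq_len(config$n_qc_vmr))
    blk <- matrix(rpois(config$n_qc_vmr * length(units), 5),
                  config$n_qc_vmr)
    spike_unit <- sample(length(units), config$n_qc_vmr, TRUE)
    blk[cbind(seq_len(config$n_qc_vmr), spike_unit)] <- 5000L
    counts <- add_rows(counts, blk, qc_vmr)
  }
  storage.mode(counts) <- "integer"
  meta <- data.frame(unit = units, treatment = treatment, batch = batch,
                     stringsAsFactors = FALSE)
  list(dataset = count_dataset(counts, meta),
       truth = list(de_genes = de_genes, lfc = lfc, qc_lowcount = qc_low,
                    qc_single = qc_single, qc_vmr = qc_vmr))
}

#' Generate block-correlated co-expression profiles around seed genes
#'
#' Each seed anchors a block of `block_size` genes (the seed plus partners
#' drawn from the remaining genes) with pairwise correlation `block_rho`
#' (one-factor construction); all other genes are independent standard
#' normals.
#'
#' @inheritParams gen_genome
#' @param gene_ids all gene identifiers in the matrix.
#' @param seeds seed gene ids (blocks must fit: disjoint partner sets).
#' @return list with `expr` (genes x samples matrix) and `blocks` (named
#'   list seed -> member ids including the seed).
#' @export
gen_coexpression <- function(config, gene_ids, seeds, seed = NULL) {
  maybe_seed(seed)
  rho <- config$block_rho
  if (rho <= -1 || rho >= 1) stop("block_rho must lie in (-1, 1)")
  ns <- config$coexpr_samples
  n <- length(gene_ids)
  expr <- matrix(rnorm(n * ns), n, ns, dimnames = list(gene_ids, NULL))
  colnames(expr) <- sprintf("s%02d", seq_len(ns))
  pool <- setdiff(gene_ids, seeds)
  blocks <- list()
  for (s in seeds) {
    partners <- sample(pool, config$block_size - 1L)
    pool <- setdiff(pool, partners)
    memb <- c(s, partners)
    f <- rnorm(ns)
    expr[memb, ] <- sqrt(rho) * matrix(f, length(memb), ns, byrow = TRUE) +
      sqrt(1 - rho) * matrix(rnorm(length(memb) * ns), length(memb), ns)
    blocks[[s]] <- memb
  }
  list(expr = expr, blocks = blocks)
}

#' Generate a gene graph for the hidden risk field
#'
#' @inheritParams gen_genome
#' @param gene_ids node identifiers.
#' @param model `"chain"`, `"scale-free"` (preferential attachment, `graph_m`
#'   edges per new node) or `"erdos-renyi"` (expected degree `2 * graph_m`).
#' @return `sparse_network` object (lambda `NA`).
#' @export
gen_graph <- function(config, gene_ids,
                      model = config$graph_model, seed = NULL) {
  maybe_seed(seed)
  n <- length(gene_ids)
  m <- config$graph_m
  edges <- switch(model,
    "chain" = cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L),
    "scale-free" = {
      deg <- rep(1L, n) # +1 smoothing so isolated nodes stay reachable
      el <- matrix(0L, 0L, 2L)
      for (v in 2:n) {
        k <- min(m, v - 1L)
        tgt <- sample(v - 1L, k, prob = deg[seq_len(v - 1L)])
        el <- rbind(el, cbind(v, tgt))
        deg[tgt] <- deg[tgt] + 1L
        deg[v] <- deg[v] + k
      }
      el
    },
    "erdos-renyi" = {
      pe <- min(1, 2 * m / (n - 1))
      idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
      keep <- runif(nrow(idx)) < pe
      idx[keep, , drop = FALSE]
    },
    stop("unknown graph model: ", model))
  A <- Matrix::sparseMatrix(i = c(edges[, 1], edges[, 2]),
                            j = c(edges[, 2], edges[, 1]),
                            x = 1, dims = c(n, n),
                            dimnames = list(gene_ids, gene_ids))
  A <- Matrix::drop0((A != 0) * 1)
  structure(list(adjacency = A, genes = gene_ids, lambda = NA_real_),
            class = "sparse_network")
}

#' Generate association p-values from the hidden risk field
#'
#' Simulates hidden states from the generalized Ising prior via
#' [simulate_ising()], then Z-scores (N(0,1) for non-risk, N(mu, sigma^2)
#' for risk) and one-sided p-values `p = 1 - pnorm(z)`.
#'
#' @inheritParams gen_graph
#' @param network `sparse_network` over `gene_ids`.
#' @param H binary binding indicator aligned to `gene_ids`.
#' @return list with named `p`, `z` and the true hidden states `I`.
#' @export
gen_zscores <- function(config, network, H, gene_ids = network$genes,
                        seed = NULL) {
  maybe_seed(seed)
  prm <- config$ising
  sim <- simulate_ising(prm, network, H, genes = gene_ids, n_sweeps = 500L)
  I <- sim$state
  z <- rnorm(length(I), mean = I * prm$mu, sd = ifelse(I == 1, prm$sigma, 1))
  names(z) <- gene_ids
  list(p = pnorm(z, lower.tail = FALSE), z = z, I = I)
}

#' Simulate a full synthetic world
#'
#' Runs every generator with seeds derived from `config$seed`, wiring the
#' pieces together: peaks over the genome, a risk list enriched in the
#' conserved bound core, knockdown counts with effects on shared bound genes,
#' co-expression blocks around risk-gene seeds, and Z-scores whose binding
#' indicator H marks the conserved core.
#'
#' @param config [sim_config()].
#' @param n_field_genes genes carried into the hidden-risk-field stage
#'   (subset containing all core genes; keeps HMRF fits desk-scale).
#' @return list with components `genome`, `peaks`, `risk`, `counts`,
#'   `coexpr`, `field` (graph, H, p, z) and `truth`.
#' @export
simulate_world <- function(config, n_field_genes = 500L) {
  stopifnot(inherits(config, "sim_config"))
  s <- config$seed
  genome <- gen_genome(config, seed = s + 1L)
  ids <- gene_ids(genome)
  pk <- gen_peaks(config, genome, seed = s + 2L)
  risk <- gen_risk_list(config, bound = pk$truth$core, universe = ids,
                        seed = s + 3L)
  cnt <- gen_counts(config, ids, bound = pk$truth$core, seed = s + 4L)
  seeds <- sort(sample(risk, min(5L, length(risk))))
  cx <- gen_coexpression(config, ids, seeds, seed = s + 5L)
  field_genes <- sort(unique(c(pk$truth$core,
                               sample(ids, min(n_field_genes, length(ids))))))
  if (length(field_genes) > n_field_genes)
    field_genes <- sort(c(pk$truth$core,
                          sample(setdiff(field_genes, pk$truth$core),
                                 max(0, n_field_genes - length(pk$truth$core)))))
  graph <- gen_graph(config, field_genes, seed = s + 6L)
  H <- setNames(as.integer(field_genes %in% pk$truth$core), field_genes)
  zs <- gen_zscores(config, graph, H, seed = s + 7L)
  list(genome = genome, peaks = pk$peaks, risk = risk,
       counts = cnt$dataset, coexpr = cx,
       field = list(graph = graph, H = H, p = zs$p, z = zs$z),
       truth = list(bound = pk$truth$bound, core = pk$truth$core,
                    de = cnt$truth, blocks = cx$blocks, I = zs$I,
                    seeds = seeds))
}

#' Write a simulated world to plain-text files
#'
#' Emits replicate BEDs per context, the gene-model table, risk/seed gene
#' lists, count + metadata TSVs, the co-expression matrix, TADA-style
#' p-values, the binding indicator, and a ground-truth JSON.
#'
#' @param world output of [simulate_world()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(...) file.path(dir, ...)
  for (ctx in names(world$peaks)) {
    write_bed(world$peaks[[ctx]]$rep1, fp(paste0("peaks_", ctx, "_rep1.bed")))
    write_bed(world$peaks[[ctx]]$rep2, fp(paste0("peaks_", ctx, "_rep2.bed")))
  }
  write_gene_models(world$genome, fp("gene_models.tsv"))
  writeLines(world$risk, fp("risk_genes.txt"))
  writeLines(world$truth$seeds, fp("seed_genes.txt"))
  write.table(world$counts$counts, fp("counts.tsv"), sep = "\t", quote = FALSE)
  write.table(world$counts$meta, fp("meta.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(round(world$coexpr$expr, 6), fp("expression.tsv"), sep = "\t",
              quote = FALSE)
  write.table(data.frame(gene = names(world$field$p),
                         p = world$field$p), fp("tada_pvals.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(gene = names(world$field$H),
                         H = world$field$H), fp("binding.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(world$truth, fp("ground_truth.json"), auto_unbox = TRUE)
  invisible(dir)
}
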