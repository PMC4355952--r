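test_that("generators are pure functions of (config, seed)", {
  cfg <- sim_config(seed = 1, n_genes = 10)
  g1 <- gen_genome(cfg, seed = 5)
  g2 <- gen_genome(cfg, seed = 5)
  expect_identical(g1, g2)
  g3 <- gen_genome(cfg, seed = 6)
  expect_false(identical(g1, g3))
  expect_error(sim_config(), "mandatory")
  expect_error(sim_config(seed = 1, binding_rate = 1.5), "rates")
  expect_error(sim_config(seed = 1, nonsense = 2), "unknown")
})

test_that("genome covariates follow the configured distributions", {
  cfg <- sim_config(seed = 2, n_genes = 800)
  genome <- gen_genome(cfg, seed = 2)
  ex <- do.call(rbind, lapply(genome, function(g) g$exon_loci))
  n <- nrow(ex)
  # g ~ Beta(5,5): mean 0.5; c ~ Beta(20,2): mean 10/11
  expect_lt(abs(mean(ex$g) - 0.5), 3 * sqrt(1 / 44) / sqrt(n))
  expect_lt(abs(mean(ex$c) - 20 / 22), 3 * sd(ex$c) / sqrt(n))
  expect_true(all(ex$s >= 1))
  # exons never overlap the promoter, so classification is unambiguous
  for (gm in genome[1:50]) {
    pr <- gm$promoter_union
    ov <- any(gm$exon_loci$start < max(pr$end) & gm$exon_loci$end > min(pr$start))
    expect_false(ov)
  }
  # forcing g = 0.5 makes every GC weight exactly 1
  loci <- data.frame(g = 0.5, s = c(100, 250), c = c(1, 0.5))
  expect_equal(mutability(loci), 100 + 125)
})

test_that("peak generation plants recoverable bound sets", {
  cfg <- sim_config(seed = 3, n_genes = 120, noise_peaks = 40)
  genome <- gen_genome(cfg, seed = 3)
  pk <- gen_peaks(cfg, genome, seed = 3)
  # sharing rate 1 -> identical bound sets across contexts
  cfg_share <- sim_config(seed = 3, n_genes = 120, sharing_rate = 1,
                          pair_sharing = 0)
  pk_share <- gen_peaks(cfg_share, genome, seed = 4)
  expect_equal(pk_share$truth$bound[[1]], pk_share$truth$bound[[2]])
  expect_equal(pk_share$truth$bound[[1]], sort(pk_share$truth$core))
  # noise-only config: reproducible regions vanish
  cfg_noise <- sim_config(seed = 3, n_genes = 120, binding_rate = 0,
                          noise_peaks = 40)
  pk_noise <- gen_peaks(cfg_noise, genome, seed = 5)
  rr <- reproducible_regions(pk_noise$peaks$hNSC$rep1,
                             pk_noise$peaks$hNSC$rep2)
  expect_equal(nrow(rr), 0L)
  # pipeline recovery: reproducible peaks -> promoter genes == truth
  for (ctx in names(pk$peaks)) {
    rr <- reproducible_regions(pk$peaks[[ctx]]$rep1, pk$peaks[[ctx]]$rep2)
    cl <- classify_peaks(rr, genome)
    found <- sort(unique(unlist(cl$gene_ids[cl$class == "promoter"])))
    truth <- pk$truth$bound[[ctx]]
    jacc <- length(intersect(found, truth)) / length(union(found, truth))
    expect_gt(jacc, 0.95)
  }
})

test_that("risk lists respect the enrichment odds", {
  cfg <- sim_config(seed = 4, n_genes = 400, risk_size = 60, risk_odds = 8)
  uni <- sprintf("g%04d", 1:400)
  bound <- uni[1:100]
  r <- gen_risk_list(cfg, bound, uni, seed = 9)
  expect_length(r, 60)
  # expected bound fraction under odds 8: 100*8 / (100*8 + 300) ~ 0.73
  expect_gt(mean(r %in% bound), 0.5)
  # odds on an empty bound set degrade to a plain sample
  r0 <- gen_risk_list(cfg, character(0), uni, seed = 9)
  expect_length(r0, 60)
  expect_error(gen_risk_list(sim_config(seed = 1, risk_odds = 0.5),
                             bound, uni), ">= 1")
})

test_that("planted QC violators are exactly recovered by the three filters", {
  cfg <- sim_config(seed = 5, n_genes = 300)
  gc <- gen_counts(cfg, sprintf("g%04d", 1:300), bound = sprintf("g%04d", 1:80),
                   seed = 5)
  ds <- gc$dataset
  fl <- filter_low_counts(ds$counts)
  expect_true(all(gc$truth$qc_lowcount %in%
                    setdiff(rownames(ds$counts), rownames(fl$counts))))
  expect_gte(fl$report$n_removed_single_unit, length(gc$truth$qc_single))
  expect_true(!any(gc$truth$qc_single %in% rownames(fl$counts)))
  nm <- normalize_library_scale(fl$counts)
  vf <- vmr_filter(nm$normalized, ds$meta$treatment)
  expect_true(all(gc$truth$qc_vmr %in% vf$removed))
  # regular genes overwhelmingly survive
  regular <- sprintf("g%04d", 1:300)
  expect_gt(mean(regular %in% rownames(vf$counts)), 0.95)
})

test_that("zero knockdown effects yield no strong calls", {
  cfg <- sim_config(seed = 6, n_genes = 250, kd_frac = 0,
                    n_qc_lowcount = 0L, n_qc_single = 0L, n_qc_vmr = 0L)
  gc <- gen_counts(cfg, sprintf("g%04d", 1:250), bound = sprintf("g%04d", 1:60),
                   seed = 6)
  expect_length(gc$truth$de_genes, 0)
  de <- fit_counts_glm(gc$dataset, "kdC", model = "negbin")
  expect_lte(length(strong_de(de)), 1)
})

test_that("planted knockdown effects reach the bound-set Wilcoxon test", {
  cfg <- sim_config(seed = 7, n_genes = 250, kd_lfc = 1)
  bound <- sprintf("g%04d", 1:80)
  gc <- gen_counts(cfg, sprintf("g%04d", 1:250), bound = bound, seed = 7)
  fl <- filter_low_counts(gc$dataset$counts)
  ds <- count_dataset(fl$counts, gc$dataset$meta)
  de <- fit_counts_glm(ds, "kdC", model = "negbin")
  pv <- setNames(de$p_value, de$gene)
  memb <- intersect(bound, names(pv))
  res <- wilcoxon_set_test(pv, memb, setdiff(names(pv), memb))
  expect_lt(res$wilcoxon_p, 0.01)
  # downregulation bias: most planted effects point down
  expect_gt(mean(gc$truth$lfc < 0), 0.6)
})

test_that("co-expression blocks have the configured correlation structure", {
  cfg <- sim_config(seed = 8, n_genes = 200, coexpr_samples = 60)
  ids <- sprintf("g%04d", 1:200)
  seeds <- c("g0001", "g0002")
  cx <- gen_coexpression(cfg, ids, seeds, seed = 8)
  expect_equal(dim(cx$expr), c(200, 60))
  # within-block sample correlation ~ rho
  blk <- cx$blocks[["g0001"]]
  cc <- cor(t(cx$expr[blk, ]))
  offdiag <- cc[upper.tri(cc)]
  expect_lt(abs(mean(offdiag) - cfg$block_rho), 0.05)
  # each seed has exactly k = 20 neighbours from its 25-gene block
  net <- build_network(cx$expr, seeds, k = 20, r_min = 0.7)
  for (s in seeds) {
    expect_equal(nrow(net$members[[s]]), 20L)
    expect_true(all(net$members[[s]]$gene %in% cx$blocks[[s]]))
  }
  # rho = 0: no neighbours at the 0.7 threshold
  cfg0 <- sim_config(seed = 8, n_genes = 200, coexpr_samples = 60,
                     block_rho = 0)
  cx0 <- gen_coexpression(cfg0, ids, seeds, seed = 9)
  net0 <- build_network(cx0$expr, seeds, k = 20, r_min = 0.7)
  expect_equal(nrow(net0$edges), 0L)
  expect_error(gen_coexpression(sim_config(seed = 1, block_rho = 0.999999),
                                ids, seeds),
               NA) # in-range rho is accepted
})

test_that("gen_zscores reproduces the independent-field closed form", {
  cfg <- sim_config(seed = 9, n_genes = 2000,
                    ising = ising_params(b = -2, eta = 0, d = 0,
                                         mu = 2, sigma = 1))
  ids <- sprintf("g%04d", 1:2000)
  zs <- gen_zscores(cfg, NULL, H = rep(0L, 2000), gene_ids = ids, seed = 10)
  prev <- mean(zs$I)
  se <- sqrt(plogis(-2) * (1 - plogis(-2)) / 2000)
  expect_lt(abs(prev - plogis(-2)), 3 * se)
  # degenerate alternative mu=0, sigma=1: z indistinguishable from null
  cfg0 <- sim_config(seed = 9, n_genes = 2000,
                     ising = ising_params(b = -2, eta = 0, d = 0,
                                          mu = 0, sigma = 1))
  zs0 <- gen_zscores(cfg0, NULL, H = rep(0L, 2000), gene_ids = ids, seed = 11)
  expect_gt(ks.test(zs0$z, pnorm)$p.value, 0.01)
  # p = 1 - Phi(z)
  expect_equal(zs$p, pnorm(zs$z, lower.tail = FALSE))
})

test_that("a simulated world writes and round-trips through the readers", {
  cfg <- sim_config(seed = 12, n_genes = 150, noise_peaks = 20,
                    coexpr_samples = 20)
  world <- simulate_world(cfg, n_field_genes = 80)
  dir <- withr::local_tempdir()
  write_world(world, dir)
  expect_true(file.exists(file.path(dir, "peaks_hNSC_rep1.bed")))
  back_counts <- read_count_dataset(file.path(dir, "counts.tsv"),
                                    file.path(dir, "meta.tsv"))
  expect_equal(back_counts$counts, world$counts$counts)
  expect_equal(read_gene_list(file.path(dir, "risk_genes.txt")), world$risk)
  expect_equal(read_gene_values(file.path(dir, "tada_pvals.tsv")),
               world$field$p)
  expr_back <- read_expression(file.path(dir, "expression.tsv"))
  expect_equal(expr_back, round(world$coexpr$expr, 6), ignore_attr = TRUE)
  genome_back <- read_gene_models(file.path(dir, "gene_models.tsv"))
  expect_equal(gene_ids(genome_back), gene_ids(world$genome))
})
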