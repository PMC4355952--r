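test_that("reproducible_regions matches the definitional examples", {
  expect_equal(reproducible_regions(intervals("chr1", 100, 200),
                                    intervals("chr1", 150, 250)),
               intervals("chr1", 100, 250), ignore_attr = TRUE)
  expect_equal(nrow(reproducible_regions(intervals("chr1", 100, 200),
                                         intervals("chr2", 100, 200))), 0L)
  same <- intervals("chr1", 0, 50)
  expect_equal(reproducible_regions(same, same), same, ignore_attr = TRUE)
  # bookended peaks (zero overlap) are not reproducible
  expect_equal(nrow(reproducible_regions(intervals("chr1", 0, 100),
                                         intervals("chr1", 100, 200))), 0L)
})

test_that("reproducible_regions rejects malformed intervals, is symmetric and idempotent", {
  expect_error(reproducible_regions(data.frame(chrom = "chr1", start = 5,
                                               end = 5),
                                    intervals("chr1", 0, 10)),
               "start >= end")
  set.seed(41)
  for (rep in 1:25) {
    a <- rand_intervals(sample(1:8, 1))
    b <- rand_intervals(sample(1:8, 1))
    ab <- reproducible_regions(a, b)
    expect_same_intervals(ab, reproducible_regions(b, a))
    if (nrow(ab)) expect_same_intervals(ab, reproducible_regions(ab, ab))
    # brute-force per-base oracle
    expect_same_intervals(ab, bf_reproducible(a, b))
  }
})

test_that("group_reproducible unions within-group pairs only", {
  s <- list(a1 = intervals("chr1", 100, 200), a2 = intervals("chr1", 150, 260),
            b1 = intervals("chr1", 5000, 5100), b2 = intervals("chr1", 9000, 9100))
  res <- group_reproducible(s, list(A = c("a1", "a2"), B = c("b1", "b2")))
  expect_equal(res, intervals("chr1", 100, 260), ignore_attr = TRUE)

  same <- intervals("chr1", 10, 90)
  res2 <- group_reproducible(list(x1 = same, x2 = same, x3 = same, x4 = same),
                             list(G = c("x1", "x2", "x3", "x4")))
  expect_equal(res2, same, ignore_attr = TRUE)

  disj <- list(y1 = intervals("chr1", 0, 10), y2 = intervals("chr1", 100, 110))
  expect_equal(nrow(group_reproducible(disj, list(G = c("y1", "y2")))), 0L)

  expect_error(group_reproducible(s, list(A = "a1")), ">= 2")
  expect_error(group_reproducible(s, list(A = c("a1", "zz"))), "unknown")
})

test_that("classify_peaks applies promoter > exon > distal precedence", {
  genes <- make_toy_genes()
  # inside [tss-500, tss-400) of the + strand gene
  res <- classify_peak(intervals("chr1", 4500, 4600), genes)
  expect_equal(res$class, "promoter")
  expect_equal(res$gene_ids, "gA")
  # inside an exon, outside all promoters
  res <- classify_peak(intervals("chr1", 6100, 6200), genes)
  expect_equal(res$class, "exon")
  expect_equal(res$gene_ids, "gA")
  # 10 kb away from everything
  res <- classify_peak(intervals("chr1", 50000, 50100), genes)
  expect_equal(res$class, "distal")
  expect_length(res$gene_ids, 0)
  # minus-strand promoter is downstream in coordinates: (tss, tss+1000]
  res <- classify_peak(intervals("chr1", 20500, 20600), genes)
  expect_equal(res$class, "promoter")
  expect_equal(res$gene_ids, "gB")
  # a peak spanning promoter and exon takes the promoter class
  res <- classify_peak(intervals("chr1", 4900, 5300), genes)
  expect_equal(res$class, "promoter")
  # unknown chromosome -> distal with a warning
  expect_warning(res <- classify_peak(intervals("chrUn", 0, 100), genes),
                 "distal")
  expect_equal(res$class, "distal")
  # every peak gets exactly one class
  set.seed(99)
  pk <- rand_intervals(50, max_coord = 30000, chroms = "chr1")
  cl <- classify_peaks(pk, genes)
  expect_true(all(cl$class %in% c("promoter", "exon", "distal")))
  expect_equal(nrow(cl), 50L)
})

test_that("venn_partition assigns each interval to exactly one cell", {
  a <- peak_context_set("a", intervals("chr1", c(100, 1000), c(200, 1100)))
  b <- peak_context_set("b", intervals("chr1", c(150, 5000), c(250, 5100)))
  ct <- peak_context_set("c", intervals("chr1", 120, 260))
  # identical sets in 2 contexts -> everything in the shared cell
  vi <- venn_partition(list(a, peak_context_set("b", a$intervals)))
  expect_equal(names(vi$cells), "a+b")
  # disjoint sets -> only context-specific cells
  vd <- venn_partition(list(peak_context_set("a", intervals("chr1", 0, 10)),
                            peak_context_set("b", intervals("chr1", 100, 110))))
  expect_setequal(names(vd$cells), c("a", "b"))
  # 3-context toy with one triple overlap
  v3 <- venn_partition(list(a, b, ct))
  expect_true("a+b+c" %in% names(v3$cells))
  expect_equal(v3$cells[["a+b+c"]]$start, c(100, 120, 150))
  # membership partition: counts across cells == total input intervals
  n_in <- nrow(a$intervals) + nrow(b$intervals) + nrow(ct$intervals)
  expect_equal(sum(vapply(v3$cells, nrow, integer(1))), n_in)
  expect_error(venn_partition(list(a, peak_context_set("a", b$intervals))),
               "duplicate")
  expect_error(venn_partition(list(a)), ">= 2")
})

test_that("venn_partition derives promoter-bound gene sets per cell", {
  genes <- make_toy_genes()
  a <- peak_context_set("hNSC", intervals("chr1", 4500, 4600))
  b <- peak_context_set("brain", intervals("chr1", c(4550, 20100), c(4650, 20200)))
  v <- venn_partition(list(a, b), genes)
  expect_equal(v$bound_genes[["hNSC+brain"]], "gA")
  expect_equal(v$bound_genes[["brain"]], "gB")
})

test_that("map_orthologs is the image under a one-to-one table", {
  tab <- data.frame(human = c("h1", "h2"), mouse = c("m1", "m2"))
  expect_equal(map_orthologs(character(), tab)$mapped, character(0))
  id_tab <- data.frame(a = c("x", "y"), b = c("x", "y"))
  expect_setequal(map_orthologs(c("x", "y"), id_tab)$mapped, c("x", "y"))
  res <- map_orthologs(c("h1", "h2", "h3"), tab)
  expect_setequal(res$mapped, c("m1", "m2"))
  expect_equal(res$n_dropped, 1L)
  expect_equal(res$dropped, "h3")
  bad <- data.frame(a = c("h1", "h1"), b = c("m1", "m2"))
  expect_error(map_orthologs("h1", bad), "one-to-one.*h1")
})

test_that("fragment_density normalizes to fragments per million", {
  rs <- data.frame(chrom = "chr1", pos = 100, strand = "+")
  d <- fragment_density(rs, extension = 300, total_reads = 1e6)
  expect_equal(d, data.frame(chrom = "chr1", start = 100, end = 400,
                             density = 1), ignore_attr = TRUE)
  # minus-strand read extends leftwards from its 5' end
  rs2 <- data.frame(chrom = "chr1", pos = 500, strand = "-")
  d2 <- fragment_density(rs2, extension = 100, total_reads = 1e6)
  expect_equal(c(d2$start, d2$end), c(401, 501))
  # zero reads -> empty track
  expect_equal(nrow(fragment_density(rs[0, ], total_reads = 10)), 0L)
  # two overlapping reads stack
  rs3 <- data.frame(chrom = "chr1", pos = c(100, 200), strand = "+")
  d3 <- fragment_density(rs3, extension = 300, total_reads = 2e6)
  ov <- d3[d3$start == 200 & d3$end == 400, ]
  expect_equal(ov$density, 2 * 1e6 / 2e6)
  expect_error(fragment_density(rs, total_reads = 0), "positive")
  expect_error(fragment_density(rs3, total_reads = 1), "smaller")
})

test_that("BED and gene-model files round-trip", {
  iv <- intervals(c("chr2", "chr1"), c(10, 0), c(50, 7))
  f <- withr::local_tempfile(fileext = ".bed")
  write_bed(iv, f)
  expect_equal(read_bed(f), iv, ignore_attr = TRUE)
  genes <- make_toy_genes()
  g <- withr::local_tempfile(fileext = ".tsv")
  write_gene_models(genes, g)
  back <- read_gene_models(g)
  expect_equal(gene_ids(back), gene_ids(genes))
  expect_equal(back[[1]]$promoter_union, genes[[1]]$promoter_union)
  expect_equal(back[[2]]$exon_loci, genes[[2]]$exon_loci)
  expect_equal(vapply(back, function(x) x$active, logical(1)), c(TRUE, FALSE))
})

test_that("promoter geometry follows strand and unions across isoforms", {
  gm <- gene_model("g1", "chr1", "+", tss = c(5000, 5400))
  # per-isoform promoters each 1000 nt; union merges the overlap
  expect_true(all(gm$promoter_intervals$end - gm$promoter_intervals$start
                  <= 1000))
  expect_equal(gm$promoter_union,
               data.frame(chrom = "chr1", start = 4000, end = 5400),
               ignore_attr = TRUE)
  expect_equal(gm$promoter_size, 1400)
  gm2 <- gene_model("g2", "chr1", "-", tss = 100)
  expect_equal(gm2$promoter_union$start, 101)
  expect_equal(gm2$promoter_union$end, 1101)
  # promoter clipped at the chromosome start
  gm3 <- gene_model("g3", "chr1", "+", tss = 400)
  expect_equal(gm3$promoter_size, 400)
})
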