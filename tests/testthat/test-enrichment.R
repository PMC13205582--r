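# Lead selection, matched-control sampling, interval overlap, Fisher
# enrichment and gene-set over-representation.

test_that("lead selection applies the documented tie-breaks", {
  tab <- data.frame(
    gene_id = c("g1", "g1", "g2"),
    variant_id = c("vA", "vB", "vC"),
    fdr = c(1e-4, 1e-4, 0.01),
    p = c(1e-6, 1e-6, 1e-4),
    beta_meta = c(0.3, 0.5, 0.2)
  )
  leads <- leadVariants(tab)
  expect_equal(leads$variant_id[leads$gene_id == "g1"], "vB") # max |beta|
  expect_equal(nrow(leads), 2L)
  # lexicographic last resort
  tab$beta_meta <- c(0.3, 0.3, 0.2)
  expect_equal(leadVariants(tab)$variant_id[1], "vA")
})

test_that("lead selection equals a brute-force per-gene scan", {
  set.seed(41)
  tab <- data.frame(
    gene_id = rep(sprintf("g%02d", 1:50), each = 6),
    variant_id = sprintf("v%03d", sample(300)),
    fdr = round(runif(300, 0, 0.2), 2), # rounding forces ties
    p = round(runif(300, 0, 0.01), 3),
    beta_meta = round(rnorm(300), 1)
  )
  leads <- leadVariants(tab)
  brute <- do.call(rbind, lapply(split(tab, tab$gene_id), function(g) {
    g <- g[g$fdr == min(g$fdr), ]
    g <- g[g$p == min(g$p), ]
    g <- g[abs(g$beta_meta) == max(abs(g$beta_meta)), ]
    g[order(g$variant_id)[1], ]
  }))
  expect_equal(
    leads$variant_id[order(leads$gene_id)],
    brute$variant_id[order(brute$gene_id)]
  )
})

test_that("matched controls respect bins, size, and reproducibility", {
  set.seed(42)
  leads <- data.frame(
    variant_id = sprintf("L%02d", 1:40),
    maf = runif(40, 0.05, 0.5),
    tss_distance = sample(c(-1, 1), 40, TRUE) * 10^runif(40, 2, 6)
  )
  pool <- data.frame(
    variant_id = sprintf("P%03d", 1:400),
    maf = runif(400, 0.05, 0.5),
    tss_distance = sample(c(-1, 1), 400, TRUE) * 10^runif(400, 2, 6),
    fdr = runif(400, 0.05, 1)
  )
  spec <- matchSpec(seed = 7)
  ctl <- sampleMatchedControls(leads, pool, spec)
  expect_equal(nrow(ctl), 40L)
  expect_false(any(duplicated(ctl$variant_id)))
  expect_true(all(ctl$fdr >= 0.05))
  # reproducible given the seed
  ctl2 <- sampleMatchedControls(leads, pool, spec)
  expect_identical(ctl$variant_id, ctl2$variant_id)
  # ample pool: per-cell counts match exactly when no borrowing happens
  if (is.null(attr(ctl, "borrows"))) {
    mafBins <- quantile(c(leads$maf, pool$maf), seq(0, 1, 0.1), names = FALSE)
    lb <- cisMetaQTL:::binIndex(leads$maf, mafBins)
    cb <- cisMetaQTL:::binIndex(ctl$maf, mafBins)
    expect_equal(as.vector(table(factor(lb, 1:10))),
      as.vector(table(factor(cb, 1:10))))
  }
  # pool smaller than leads is a hard error
  expect_error(
    sampleMatchedControls(leads, pool[1:10, ], spec),
    "smaller"
  )
})

test_that("forced matching is deterministic across seeds", {
  leads <- data.frame(
    variant_id = c("L1", "L2"),
    maf = c(0.1, 0.4),
    tss_distance = c(500, 5e5)
  )
  pool <- data.frame(
    variant_id = c("P1", "P2"),
    maf = c(0.1, 0.4),
    tss_distance = c(600, 6e5)
  )
  spec1 <- matchSpec(mafBins = c(0, 0.25, 0.5), seed = 1)
  spec2 <- matchSpec(mafBins = c(0, 0.25, 0.5), seed = 999)
  expect_identical(
    sampleMatchedControls(leads, pool, spec1)$variant_id,
    sampleMatchedControls(leads, pool, spec2)$variant_id
  )
})

test_that("matched MAF distributions stay within the binning bound", {
  set.seed(43)
  leads <- data.frame(
    variant_id = sprintf("L%02d", 1:50),
    maf = rbeta(50, 2, 5) * 0.5,
    tss_distance = 10^runif(50, 2, 6)
  )
  pool <- data.frame(
    variant_id = sprintf("P%04d", 1:2000),
    maf = rbeta(2000, 2, 5) * 0.5,
    tss_distance = 10^runif(2000, 2, 6)
  )
  mafBins <- unique(quantile(c(leads$maf, pool$maf), seq(0, 1, 0.1),
    names = FALSE
  ))
  maxWidth <- max(diff(mafBins))
  for (s in 1:20) {
    ctl <- sampleMatchedControls(leads, pool, matchSpec(seed = s))
    ks <- suppressWarnings(ks.test(leads$maf, ctl$maf))$statistic
    expect_lte(unname(ks), maxWidth + 0.25)
  }
})

test_that("overlap follows the BED half-open convention", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t99\t100", "chr1\t100\t200"), bed)
  track <- readBedTrack(bed)
  v <- data.frame(variant_id = "v1", chrom = "chr1", pos = 100L)
  expect_true(annotateOverlap(v, track[1]))
  expect_false(annotateOverlap(v, track[2]))
  expect_equal(annotateOverlap(v, GenomicRanges::GRanges()), FALSE)
  # malformed interval reported with its line number
  bad <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t10\t20", "chr1\t30\t30"), bad)
  expect_error(readBedTrack(bad), "line 2")
})

test_that("interval overlap equals a brute-force scan", {
  set.seed(44)
  v <- data.frame(
    variant_id = sprintf("v%03d", 1:200),
    chrom = "chr1", pos = sample.int(1e5, 200)
  )
  starts <- sort(sample.int(1e5, 30))
  track <- GenomicRanges::GRanges(
    "chr1",
    IRanges::IRanges(start = starts, width = sample(50:500, 30, TRUE))
  )
  fast <- annotateOverlap(v, track)
  brute <- vapply(v$pos, function(p) {
    any(p >= GenomicRanges::start(track) & p <= GenomicRanges::end(track))
  }, logical(1))
  expect_equal(fast, brute)
})

test_that("Fisher enrichment matches the enumeration oracle", {
  rec <- fisherEnrichment(
    c(rep(TRUE, 10), rep(FALSE, 90)),
    c(rep(TRUE, 5), rep(FALSE, 95))
  )
  expect_equal(rec$or_value, (10 * 95) / (90 * 5), tolerance = 1e-12)
  expect_equal(rec$or_value, 2.111, tolerance = 1e-3)
  # frozen from complete hypergeometric enumeration
  expect_equal(rec$p, 0.282763830378, tolerance = 1e-9)
  # equal rates: OR exactly 1
  recNull <- fisherEnrichment(
    rep(c(TRUE, FALSE), c(10, 90)),
    rep(c(TRUE, FALSE), c(20, 180))
  )
  expect_equal(recNull$or_value, 1, tolerance = 1e-12)
})

test_that("Haldane correction applies only on zero cells and not to p", {
  rec <- fisherEnrichment(
    rep(c(TRUE, FALSE), c(0, 10)),
    rep(c(TRUE, FALSE), c(5, 5))
  )
  expect_equal(rec$or_value, (0.5 * 5.5) / (10.5 * 5.5), tolerance = 1e-10)
  expect_equal(rec$or_value, 0.0476, tolerance = 1e-3)
  expect_true(is.finite(rec$ci_low) && is.finite(rec$ci_high))
  # exact p is computed on the uncorrected table
  expect_equal(
    rec$p,
    fisher.test(matrix(c(0, 10, 5, 5), 2, byrow = TRUE))$p.value
  )
})

test_that("enrichment is symmetric under query-control swap", {
  q <- rep(c(TRUE, FALSE), c(12, 38))
  ctl <- rep(c(TRUE, FALSE), c(5, 45))
  a <- fisherEnrichment(q, ctl)
  b <- fisherEnrichment(ctl, q)
  expect_equal(a$p, b$p, tolerance = 1e-12)
  expect_equal(a$or_value, 1 / b$or_value, tolerance = 1e-12)
})

test_that("family-specific adjustment policies are applied", {
  rec <- data.frame(
    category = c("c1", "c2", "c3"),
    p = c(0.01, 0.2, 0.5)
  )
  tf <- adjustCategories(rec, "tf")
  expect_equal(tf$p_adj, c(0.03, 0.6, 1.0))
  expect_equal(tf$adjust_method, rep("bonferroni", 3))
  hm <- adjustCategories(rec, "histone_marks")
  expect_equal(hm$p_adj, bhAdjust(rec$p))
  single <- adjustCategories(rec[1, ], "rbp")
  expect_equal(single$p_adj, single$p)
  expect_error(adjustCategories(rec, "unknown_family"), "unknown")
})

test_that("gene-set over-representation matches the combinatorial oracle", {
  bg <- sprintf("g%02d", 1:10)
  rec <- genesetEnrichment(bg[1:4], bg[1:5], bg)
  expect_equal(rec$p, 5 / 210, tolerance = 1e-12)
  disjoint <- genesetEnrichment(bg[6:9], bg[1:5], bg)
  expect_equal(disjoint$p, 1)
  expect_error(genesetEnrichment(character(0), bg[1:5], bg), "empty")
  expect_error(genesetEnrichment(c("zz"), bg[1:5], bg), "subset")
})

test_that("gene-set p-values are calibrated under random queries", {
  set.seed(45)
  bg <- sprintf("g%03d", 1:200)
  gs <- bg[1:40]
  ps <- replicate(1000, genesetEnrichment(sample(bg, 20), gs, bg)$p)
  # discrete but stochastically >= uniform: check no excess of small p
  expect_lte(mean(ps <= 0.05), 0.05 + 3 * sqrt(0.05 * 0.95 / 1000))
})
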