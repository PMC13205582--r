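# Synthetic-cohort generator: marginal allele frequencies, LD structure,
# Hardy-Weinberg proportions, shared panels, effect planting, phenotype
# calibration, and annotation enrichment.

test_that("empirical allele frequencies converge to target MAFs", {
  cfg <- simConfig(
    nSamples = c(a = 10000L), nVariants = 20L, nGenes = 2L,
    mafRange = c(0.5, 0.5), ldRho = 0, nCausalPairs = 0L,
    nRiskVariants = 0L, seed = 42
  )
  gt <- simulateGenotypes(cfg, "a")
  f <- rowMeans(dosages(gt)) / 2
  se <- sqrt(0.5 * 0.5 / (2 * 10000))
  expect_true(all(abs(f - 0.5) <= 3 * se))
})

test_that("near-unit latent correlation forces near-identical neighbors", {
  cfg <- simConfig(
    nSamples = c(a = 2000L), nVariants = 20L, nGenes = 2L,
    mafRange = c(0.3, 0.3), ldBlockSize = 10L, ldRho = 0.999,
    nCausalPairs = 0L, nRiskVariants = 0L, seed = 7
  )
  dos <- dosages(simulateGenotypes(cfg, "a"))
  # adjacent within-block pairs only (skip block boundaries)
  adj <- setdiff(seq_len(19L), 10L)
  r <- vapply(adj, function(i) cor(dos[i, ], dos[i + 1L, ]), numeric(1))
  expect_true(all(r >= 0.9))
})

test_that("adjacent-pair genotype r2 matches a large-sample copula oracle", {
  # oracle: 1e6 haplotype pairs from the same bivariate threshold model,
  # independent of the generator's block machinery
  maf <- 0.2
  rho <- 0.5
  set.seed(991)
  nOr <- 1e6
  z1 <- rnorm(nOr)
  z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(nOr)
  thr <- qnorm(maf)
  h1 <- cbind(z1 < thr, z2 < thr)
  z1 <- rnorm(nOr)
  z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(nOr)
  g <- h1 + cbind(z1 < thr, z2 < thr)
  r2Oracle <- cor(g[, 1], g[, 2])^2

  cfg <- simConfig(
    nSamples = c(a = 5000L), nVariants = 50L, nGenes = 2L,
    mafRange = c(maf, maf), ldBlockSize = 10L, ldRho = rho,
    nCausalPairs = 0L, nRiskVariants = 0L, seed = 13
  )
  dos <- dosages(simulateGenotypes(cfg, "a"))
  adj <- setdiff(seq_len(49L), seq(10L, 40L, by = 10L))
  r2 <- vapply(adj, function(i) cor(dos[i, ], dos[i + 1L, ])^2, numeric(1))
  # Monte-Carlo error of the mean over 45 pairs x 5000 samples
  expect_lt(abs(mean(r2) - r2Oracle), 0.02)
})

test_that("genotypes are in Hardy-Weinberg proportions when ldRho = 0", {
  cfg <- simConfig(
    nSamples = c(a = 4000L), nVariants = 30L, nGenes = 2L,
    mafRange = c(0.1, 0.5), ldRho = 0, nCausalPairs = 0L,
    nRiskVariants = 0L, seed = 3
  )
  gt <- simulateGenotypes(cfg, "a")
  dos <- dosages(gt)
  p <- variantInfo(gt)$maf
  hetObs <- rowMeans(dos == 1)
  hetExp <- 2 * p * (1 - p)
  se <- sqrt(hetExp * (1 - hetExp) / 4000)
  expect_true(all(abs(hetObs - hetExp) <= 3 * se))
})

test_that("two cohorts from one config share an identical variant panel", {
  cfg <- tinyConfig(seed = 21)
  va <- variantInfo(simulateGenotypes(cfg, "a"))
  vb <- variantInfo(simulateGenotypes(cfg, "b"))
  expect_identical(as.data.frame(va), as.data.frame(vb))
  # but the samples are independent draws
  expect_false(identical(
    dosages(simulateGenotypes(cfg, "a"))[, 1],
    dosages(simulateGenotypes(cfg, "b"))[, 1]
  ))
})

test_that("null model leaves dosage-expression correlations centered at 0", {
  cfg <- simConfig(
    nSamples = c(a = 200L), nVariants = 100L, nGenes = 50L,
    nCausalPairs = 0L, nHiddenFactors = 0L, nRiskVariants = 0L,
    lowExprFraction = 0, chromLength = 5e6, seed = 17
  )
  gt <- simulateGenotypes(cfg, "a")
  genes <- simulateGeneModels(cfg)
  truth <- simulateTruth(cfg, variantInfo(gt), genes)
  fpkm <- simulateExpression(gt, genes, truth, cfg)
  latent <- attr(fpkm, "latent")
  r <- vapply(seq_len(50L), function(i) {
    cor(latent[i, ], dosages(gt)[i, ])
  }, numeric(1))
  expect_lt(abs(mean(r)), 3 / sqrt(200 * 50 / 50) / sqrt(50))
  expect_lt(abs(mean(r)), 0.05)
})

test_that("planted cis effect is recovered by OLS within sampling error", {
  cfg <- simConfig(
    nSamples = c(a = 300L), nVariants = 60L, nGenes = 10L,
    nCausalPairs = 1L, betaCausal = 0.25, nHiddenFactors = 0L,
    noiseSd = 1, nRiskVariants = 0L, lowExprFraction = 0,
    chromLength = 3e6, seed = 29
  )
  gt <- simulateGenotypes(cfg, "a")
  genes <- simulateGeneModels(cfg)
  truth <- simulateTruth(cfg, variantInfo(gt), genes)
  fpkm <- simulateExpression(gt, genes, truth, cfg)
  latent <- attr(fpkm, "latent")
  pair <- causalPairs(truth)
  y <- latent[pair$gene_id[1], ]
  x <- dosages(gt)[pair$variant_id[1], ]
  fit <- fitAssociation(y, x)
  expect_lt(abs(fit$beta - 0.25), 3 * fit$se)
})

test_that("noiseless expression is exactly affine in dosage", {
  cfg <- simConfig(
    nSamples = c(a = 100L), nVariants = 60L, nGenes = 10L,
    nCausalPairs = 1L, betaCausal = 1, nHiddenFactors = 0L,
    noiseSd = 1e-9, nRiskVariants = 0L, lowExprFraction = 0,
    chromLength = 3e6, seed = 31
  )
  gt <- simulateGenotypes(cfg, "a")
  genes <- simulateGeneModels(cfg)
  truth <- simulateTruth(cfg, variantInfo(gt), genes)
  latent <- attr(simulateExpression(gt, genes, truth, cfg), "latent")
  pair <- causalPairs(truth)
  x <- dosages(gt)[pair$variant_id[1], ]
  expect_equal(cor(latent[pair$gene_id[1], ], x), 1, tolerance = 1e-6)
})

test_that("a causal variant outside the cis window is rejected", {
  cfg <- tinyConfig(seed = 4)
  gt <- simulateGenotypes(cfg, "a")
  genes <- makeGenes(start = 1e5, end = 2e5)
  truth <- methods::new("SimTruth",
    causalPairs = data.frame(
      variant_id = variantInfo(gt)$variant_id[1],
      gene_id = "gene0001", beta_a = 1, beta_b = 1
    ),
    riskVariants = data.frame(variant_id = character(), log_or = numeric()),
    factorLoadings = matrix(0, 1, 0)
  )
  # shrink the window so the variant falls outside it
  expect_error(
    simulateExpression(gt, genes, truth, cfg, cisWindow = 1),
    "cis window"
  )
})

test_that("intercept-only disease model hits the target case fraction", {
  cfg <- simConfig(
    nSamples = c(a = 5000L), nVariants = 20L, nGenes = 2L,
    nCausalPairs = 0L, nRiskVariants = 0L, caseFraction = 0.5, seed = 8
  )
  gt <- simulateGenotypes(cfg, "a")
  truth <- simulateTruth(cfg, variantInfo(gt), simulateGeneModels(cfg))
  ph <- simulateCaseControl(gt, truth, cfg, ageEffect = 0, sexEffect = 0)
  se <- sqrt(0.25 / 5000)
  expect_lt(abs(mean(ph$case_status) - 0.5), 3 * se)
  expect_true(all(ph$case_status %in% c(0, 1)))
})

test_that("planted per-allele odds ratio is recovered by logistic fit", {
  cfg <- simConfig(
    nSamples = c(a = 8000L), nVariants = 30L, nGenes = 2L,
    mafRange = c(0.2, 0.2), ldRho = 0, nCausalPairs = 0L,
    nRiskVariants = 1L, riskOR = 1.2, riskOverlapFraction = 0,
    caseFraction = 0.5, seed = 19
  )
  gt <- simulateGenotypes(cfg, "a")
  truth <- simulateTruth(cfg, variantInfo(gt), simulateGeneModels(cfg))
  ph <- simulateCaseControl(gt, truth, cfg, ageEffect = 0, sexEffect = 0)
  rv <- riskVariants(truth)$variant_id[1]
  fit <- logisticAssoc(ph$case_status, dosages(gt)[rv, ])
  expect_lt(abs(fit$log_or - log(1.2)), 3 * fit$se)
})

test_that("unachievable case fractions are reported", {
  expect_error(
    cisMetaQTL:::solveInterceptForFraction(rnorm(10), 1.5),
    "not achievable"
  )
})

test_that("annotation enrichment ratio 1 gives equal coverage rates", {
  cfg <- simConfig(
    nSamples = c(a = 30L), nVariants = 4000L, nGenes = 300L,
    nCausalPairs = 300L, nRiskVariants = 0L, chromLength = 4e7,
    lowExprFraction = 0, seed = 23
  )
  genes <- simulateGeneModels(cfg)
  variants <- cisMetaQTL:::makeVariantTable(cfg)
  truth <- simulateTruth(cfg, variants, genes)
  ann <- simulateAnnotations(variants, truth, cfg,
    baseCoverage = 0.3, enrichmentRatio = 1
  )
  ov <- annotateOverlap(variants, ann$track)
  causal <- variants$variant_id %in% causalPairs(truth)$variant_id
  # equal coverage in expectation; allow 3 binomial SEs on the difference
  seDiff <- sqrt(0.3 * 0.7 * (1 / sum(causal) + 1 / sum(!causal)))
  expect_lt(abs(mean(ov[causal]) - mean(ov[!causal])), 3 * seDiff)
  # causal variants preferentially non-intergenic
  tab <- table(ann$categories$category[causal] == "intergenic")
  expect_gt(
    mean(ann$categories$category[!causal] == "intergenic"),
    mean(ann$categories$category[causal] == "intergenic")
  )
})

test_that("full-coverage track overlaps every variant", {
  cfg <- tinyConfig(seed = 2)
  variants <- cisMetaQTL:::makeVariantTable(cfg)
  track <- GenomicRanges::GRanges(
    "chr1",
    IRanges::IRanges(1, cfg@chromLength)
  )
  expect_true(all(annotateOverlap(variants, track)))
  rec <- fisherEnrichment(
    rep(TRUE, 10), rep(TRUE, 10),
    category = "degenerate"
  )
  # zero cells trigger the Haldane path: OR finite, CI finite
  expect_true(is.finite(rec$or_value) && is.finite(rec$ci_high))
  expect_equal(rec$p, 1)
})

test_that("missingness is injected at the configured rate", {
  cfg <- simConfig(
    nSamples = c(a = 500L), nVariants = 100L, nGenes = 2L,
    nCausalPairs = 0L, nRiskVariants = 0L, missingRate = 0.1, seed = 37
  )
  dos <- dosages(simulateGenotypes(cfg, "a"))
  expect_lt(abs(mean(is.na(dos)) - 0.1), 0.01)
})
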