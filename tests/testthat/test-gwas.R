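# Logistic association, genomic inflation, suggestive selection, locus
# grouping, and analytic trend-test power.

test_that("logistic fit matches the 2x2 closed form on binary dosage", {
  status <- rep(c(1, 1, 0, 0), c(30, 70, 10, 90))
  dosage <- rep(c(1, 0, 1, 0), c(30, 70, 10, 90))
  fit <- logisticAssoc(status, dosage)
  expect_equal(fit$log_or, log(3.857143), tolerance = 1e-6)
  expect_equal(fit$se, 0.3984095, tolerance = 1e-6)
  expect_equal(fit$z, 3.388289, tolerance = 1e-5)
  expect_true(fit$converged)
  expect_equal(fit$n_cases, 100L)
  expect_equal(fit$n_controls, 100L)
})

test_that("closed-form equivalence holds across random 2x2 fixtures", {
  set.seed(51)
  for (i in 1:10) {
    tab <- matrix(sample(10:80, 4), 2) # cases/controls x exposed/unexposed
    status <- rep(c(1, 1, 0, 0), c(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]))
    dosage <- rep(c(1, 0, 1, 0), c(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]))
    fit <- logisticAssoc(status, dosage)
    logOr <- log(tab[1, 1] * tab[2, 2] / (tab[1, 2] * tab[2, 1]))
    se <- sqrt(sum(1 / tab))
    expect_equal(fit$log_or, logOr, tolerance = 1e-6)
    expect_equal(fit$se, se, tolerance = 1e-6)
  }
})

test_that("a covariate orthogonal to dosage leaves the estimate intact", {
  set.seed(52)
  n <- 400L
  dosage <- rbinom(n, 2, 0.3)
  status <- rbinom(n, 1, plogis(-0.5 + 0.3 * dosage))
  base <- logisticAssoc(status, dosage)
  ortho <- residuals(lm(rnorm(n) ~ dosage))
  adj <- logisticAssoc(status, dosage, cbind(ortho))
  # direct refit oracle: a full glm() with the same design agrees exactly
  ref <- glm(status ~ dosage + ortho, family = binomial())
  expect_equal(adj$log_or, unname(coef(ref)["dosage"]), tolerance = 1e-6)
  expect_equal(adj$se, unname(sqrt(diag(vcov(ref)))["dosage"]),
    tolerance = 1e-6
  )
  # an orthogonal nuisance covariate moves the estimate only marginally
  expect_lt(abs(adj$log_or - base$log_or), 0.05)
})

test_that("degenerate inputs raise structured errors", {
  expect_error(logisticAssoc(rep(1, 10), rbinom(10, 2, 0.5)), "classes")
  expect_error(
    logisticAssoc(rbinom(10, 1, 0.5), rep(1, 10)),
    "constant dosage"
  )
  expect_error(logisticAssoc(c(0, 1, 2), c(0, 1, 2)), "0/1")
})

test_that("genomic lambda matches its definition and is monotone", {
  expect_equal(genomicLambda(rep(0.5, 100)), 1, tolerance = 1e-12)
  set.seed(53)
  p <- runif(100000)
  expect_gt(genomicLambda(p), 0.98)
  expect_lt(genomicLambda(p), 1.02)
  expect_gt(genomicLambda(p / 2), genomicLambda(p))
  expect_error(genomicLambda(numeric(0)), "no p-values")
  expect_error(genomicLambda(c(0.5, 0)), "0, 1")
})

test_that("suggestive selection applies all thresholds and concordance", {
  meta <- data.frame(
    variant_id = sprintf("v%d", 1:6),
    beta_meta = c(0.3, 0.3, 0.3, 0.3, -0.3, 0.3),
    p = c(5e-6, 5e-6, 2e-5, 5e-6, 5e-6, 5e-6)
  )
  c1 <- data.frame(
    variant_id = meta$variant_id,
    beta = c(0.3, 0.3, 0.3, 0.3, -0.3, 0.3),
    p = c(0.01, 0.01, 0.01, 0.2, 0.01, 0.01),
    converged = TRUE
  )
  c2 <- data.frame(
    variant_id = meta$variant_id,
    beta = c(0.3, 0.3, 0.3, 0.3, 0.3, -0.3),
    p = c(0.03, 0.2, 0.01, 0.01, 0.01, 0.01),
    converged = TRUE
  )
  # v1 passes; v2 fails cohort2 p; v3 fails meta p; v4 fails cohort1 p;
  # v5 passes thresholds but discordant in sign only for v6
  sel <- selectSuggestive(meta, list(panc4 = c1, chn = c2))
  expect_setequal(sel$variant_id, c("v1"))
  selNoConc <- selectSuggestive(meta, list(panc4 = c1, chn = c2),
    requireConcordant = FALSE
  )
  expect_setequal(selNoConc$variant_id, c("v1", "v5", "v6"))
  expect_true(all(c("p_panc4", "p_chn") %in% colnames(sel)))
})

test_that("toy table crafted so exactly three variants survive", {
  meta <- data.frame(
    variant_id = sprintf("s%d", 1:6),
    beta_meta = rep(0.2, 6),
    p = c(1e-6, 1e-6, 1e-4, 1e-6, 1e-6, 1e-7)
  )
  mk <- function(p) {
    data.frame(
      variant_id = meta$variant_id, beta = 0.2, p = p,
      converged = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE)
    )
  }
  c1 <- mk(c(0.01, 0.03, 0.01, 0.06, 0.01, 0.04))
  c2 <- mk(c(0.02, 0.04, 0.01, 0.01, 0.01, 0.02))
  sel <- selectSuggestive(meta, list(a = c1, b = c2))
  expect_equal(nrow(sel), 3L) # s1, s2, s6 by hand rule application
  expect_setequal(sel$variant_id, c("s1", "s2", "s6"))
})

test_that("greedy locus grouping follows the stated rule", {
  v <- data.frame(
    variant_id = c("a", "b", "c"),
    chrom = "chr1",
    pos = c(1.0e6, 1.2e6, 5.0e6),
    p = c(1e-8, 1e-6, 1e-7)
  )
  loci <- defineLoci(v, gap = 5e5)
  expect_equal(nrow(loci$loci), 2L)
  expect_equal(
    loci$assignments$locus_id[loci$assignments$variant_id == "b"],
    loci$assignments$locus_id[loci$assignments$variant_id == "a"]
  )
  single <- defineLoci(v[1, , drop = FALSE])
  expect_equal(nrow(single$loci), 1L)
})

test_that("locus assignment is row-order invariant and matches brute force", {
  set.seed(54)
  v <- data.frame(
    variant_id = sprintf("v%02d", 1:50),
    chrom = sample(c("chr1", "chr2"), 50, TRUE),
    pos = sample.int(1e7, 50),
    p = runif(50, 1e-10, 1e-5)
  )
  ref <- defineLoci(v, gap = 5e5)
  shuf <- defineLoci(v[sample(50), ], gap = 5e5)
  m <- match(v$variant_id, shuf$assignments$variant_id)
  expect_equal(
    ref$assignments$locus_id,
    shuf$assignments$locus_id[m]
  )
  # brute-force reimplementation of the greedy rule
  ord <- order(v$p, v$chrom, v$pos, v$variant_id)
  idxChrom <- character(0)
  idxPos <- numeric(0)
  lab <- integer(nrow(v))
  for (i in ord) {
    hit <- which(idxChrom == v$chrom[i] & abs(idxPos - v$pos[i]) <= 5e5)
    if (length(hit)) {
      lab[i] <- hit[1]
    } else {
      idxChrom <- c(idxChrom, v$chrom[i])
      idxPos <- c(idxPos, v$pos[i])
      lab[i] <- length(idxPos)
    }
  }
  expect_equal(
    ref$assignments$locus_id[match(v$variant_id, ref$assignments$variant_id)],
    sprintf("locus%03d", lab)
  )
})

test_that("trend-test power equals alpha under the null and is monotone", {
  expect_equal(
    trendTestPower(1000, 1000, 0.2, grr = 1, alpha = 0.05),
    0.05,
    tolerance = 1e-12
  )
  grid <- c(1.05, 1.1, 1.2, 1.3)
  pw <- vapply(grid, function(g) {
    trendTestPower(2000, 2000, 0.2, g, alpha = 1e-5)
  }, numeric(1))
  expect_true(all(diff(pw) > 0))
  pwN <- vapply(c(500, 1000, 2000, 4000), function(n) {
    trendTestPower(n, n, 0.2, 1.2, alpha = 1e-5)
  }, numeric(1))
  expect_true(all(diff(pwN) > 0))
  expect_error(
    trendTestPower(100, 100, 0.4, grr = 3, prevalence = 0.6),
    "penetrance"
  )
})
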