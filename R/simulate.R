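# Synthetic multi-cohort generator: LD-blocked genotypes via a Gaussian
# copula, expression with additive cis effects plus hidden factors,
# liability-model case-control phenotypes, and annotation tracks enriched
# at causal variants. All randomness flows from config@seed through named
# substreams, so the variant panel is shared across cohorts while samples
# are independent.

# haplotype matrix (n x m) under the block-diagonal lag-one Gaussian copula
drawHaplotypes <- function(n, maf, blockSize, rho) {
  m <- length(maf)
  z <- matrix(0, n, m)
  startCol <- seq(1L, m, by = blockSize)
  for (s in startCol) {
    e <- min(s + blockSize - 1L, m)
    z[, s] <- stats::rnorm(n)
    if (e > s) {
      for (j in (s + 1L):e) {
        z[, j] <- rho * z[, j - 1L] + sqrt(1 - rho^2) * stats::rnorm(n)
      }
    }
  }
  # allele present when the latent falls below the MAF quantile
  thr <- stats::qnorm(maf)
  (z < matrix(thr, n, m, byrow = TRUE)) + 0L
}

# variant panel derived from the master seed only: identical across cohorts
makeVariantTable <- function(config) {
  withSubstream(config@seed, "variants", {
    m <- config@nVariants
    pos <- sort(sample.int(as.integer(config@chromLength), m))
    ref <- sample(c("A", "C", "G", "T"), m, replace = TRUE)
    alt <- vapply(ref, function(r) {
      sample(setdiff(c("A", "C", "G", "T"), r), 1L)
    }, character(1L))
    maf <- stats::runif(m, config@mafRange[1L], config@mafRange[2L])
    qual <- round(pmin(1, stats::rbeta(m, 10, 1) + 0.0), 4L)
    S4Vectors::DataFrame(
      variant_id = sprintf("var%05d", seq_len(m)),
      chrom = "chr1",
      pos = pos,
      ref = unname(ref),
      alt = unname(alt),
      maf = maf,
      quality_score = qual
    )
  })
}

#' Simulate genotype dosages for one cohort
#'
#' Draws two haplotypes per sample from a Gaussian copula with
#' block-diagonal lag-one latent correlation (`ldRho` within blocks of
#' `ldBlockSize` variants) and thresholds each latent variable at the
#' allele-frequency quantile, so marginal allele frequencies match the
#' per-variant target MAFs and genotypes are in Hardy-Weinberg
#' proportions. Dosage is the haplotype sum. The variant panel depends
#' only on the configuration seed, so two cohorts simulated from the same
#' config share an identical variant table while their samples are
#' independent.
#'
#' @param config a [SimConfig-class].
#' @param cohortId which cohort to draw (must be a name of
#'   `config@nSamples`).
#' @return A [GenotypeData-class] object.
#' @examples
#' gt <- simulateGenotypes(simConfig(nSamples = c(a = 50), nVariants = 20,
#'                                   nGenes = 5, seed = 1), "a")
#' dim(dosages(gt))
#' @export
simulateGenotypes <- function(config, cohortId) {
  stopifnot(methods::is(config, "SimConfig"))
  if (!cohortId %in% names(config@nSamples)) {
    stop("unknown cohort id: ", cohortId, call. = FALSE)
  }
  variants <- makeVariantTable(config)
  n <- config@nSamples[[cohortId]]
  dos <- withSubstream(config@seed, paste0("genotypes-", cohortId), {
    h1 <- drawHaplotypes(n, variants$maf, config@ldBlockSize, config@ldRho)
    h2 <- drawHaplotypes(n, variants$maf, config@ldBlockSize, config@ldRho)
    d <- t(h1 + h2) # variants x samples
    if (config@missingRate > 0) {
      miss <- stats::runif(length(d)) < config@missingRate
      d[miss] <- NA_real_
    }
    storage.mode(d) <- "double"
    d
  })
  rownames(dos) <- variants$variant_id
  colnames(dos) <- sprintf("%s_s%04d", cohortId, seq_len(n))
  methods::new("GenotypeData",
    dosage = dos, variants = variants,
    cohortId = cohortId
  )
}

#' Simulate gene models on the synthetic chromosome
#'
#' Gene bodies are placed uniformly with lengths between 5 and 100 kb and
#' random strand; the TSS is the start coordinate for plus-strand genes
#' and the end coordinate for minus-strand genes.
#'
#' @param config a [SimConfig-class].
#' @return A [GenomicRanges::GRanges] with `gene_id` and `tss` metadata.
#' @export
simulateGeneModels <- function(config) {
  withSubstream(config@seed, "genes", {
    g <- config@nGenes
    len <- round(stats::runif(g, 5e3, 1e5))
    start <- sort(round(stats::runif(g, 1, config@chromLength - max(len))))
    strand <- sample(c("+", "-"), g, replace = TRUE)
    gr <- GenomicRanges::GRanges(
      seqnames = "chr1",
      ranges = IRanges::IRanges(start = start, end = start + len - 1),
      strand = strand
    )
    gr$gene_id <- sprintf("gene%04d", seq_len(g))
    gr$tss <- ifelse(strand == "+", start, start + len - 1)
    names(gr) <- gr$gene_id
    gr
  })
}

#' Plant simulation ground truth
#'
#' Selects causal variant-gene pairs (each causal variant is drawn from
#' the cis window, within `cisWindow` bp of its gene's TSS), disease risk
#' variants, and hidden-factor loadings. Causal effect sizes come from
#' `config@betaCausal`: a single value is shared by all cohorts; a vector
#' with one entry per cohort plants heterogeneous effects.
#'
#' @param config a [SimConfig-class].
#' @param variants variant DataFrame (as in [variantInfo()]).
#' @param genes gene GRanges from [simulateGeneModels()].
#' @param cisWindow cis-window half-width in bp (default 1e6).
#' @return A [SimTruth-class].
#' @export
simulateTruth <- function(config, variants, genes, cisWindow = 1e6) {
  withSubstream(config@seed, "truth", {
    cohorts <- names(config@nSamples)
    betas <- rep(config@betaCausal, length.out = length(cohorts))
    pairs <- data.frame(
      variant_id = character(), gene_id = character(),
      stringsAsFactors = FALSE
    )
    for (b in cohorts) pairs[[paste0("beta_", b)]] <- numeric()
    if (config@nCausalPairs > 0L) {
      eligible <- vapply(seq_along(genes), function(i) {
        sum(abs(variants$pos - genes$tss[i]) <= cisWindow) > 0
      }, logical(1L))
      gsel <- sample(which(eligible),
        min(config@nCausalPairs, sum(eligible))
      )
      vsel <- vapply(gsel, function(i) {
        inWin <- which(abs(variants$pos - genes$tss[i]) <= cisWindow)
        inWin[sample.int(length(inWin), 1L)]
      }, integer(1L))
      pairs <- data.frame(
        variant_id = variants$variant_id[vsel],
        gene_id = genes$gene_id[gsel],
        stringsAsFactors = FALSE
      )
      for (j in seq_along(cohorts)) {
        pairs[[paste0("beta_", cohorts[j])]] <- betas[j]
      }
    }
    risk <- data.frame(
      variant_id = character(), log_or = numeric(),
      stringsAsFactors = FALSE
    )
    if (config@nRiskVariants > 0L) {
      # a fraction of risk variants coincide with causal eQTL variants
      # (risk mediated through expression), the rest are independent
      nFromCausal <- min(
        round(config@riskOverlapFraction * config@nRiskVariants),
        nrow(pairs)
      )
      fromCausal <- if (nFromCausal > 0L) {
        sample(unique(pairs$variant_id), nFromCausal)
      } else {
        character(0)
      }
      rest <- setdiff(variants$variant_id, fromCausal)
      nFree <- config@nRiskVariants - length(fromCausal)
      free <- if (nFree > 0L) sample(rest, nFree) else character(0)
      risk <- data.frame(
        variant_id = c(fromCausal, free),
        log_or = log(config@riskOR),
        stringsAsFactors = FALSE
      )
    }
    loadings <- matrix(
      stats::rnorm(config@nGenes * config@nHiddenFactors,
        sd = config@factorSd
      ),
      nrow = config@nGenes, ncol = config@nHiddenFactors,
      dimnames = list(genes$gene_id, if (config@nHiddenFactors > 0) {
        paste0("factor", seq_len(config@nHiddenFactors))
      })
    )
    methods::new("SimTruth",
      causalPairs = pairs, riskVariants = risk,
      factorLoadings = loadings
    )
  })
}

#' Simulate expression with additive cis effects
#'
#' Latent expression per gene and sample is
#' baseline + beta * dosage (for planted causal pairs) + hidden-factor
#' term + optional known-covariate term + Gaussian noise, then mapped to a
#' positive FPKM-like scale by exponentiation with a per-gene scale
#' factor. A `lowExprFraction` of genes receives a tiny scale so their
#' mean FPKM falls below 0.1, exercising the downstream expression
#' filter. Because the map is monotone per gene, rank-based
#' transformations of the FPKM matrix recover the latent ranks exactly.
#'
#' @param genotypes a [GenotypeData-class] for the cohort.
#' @param genes gene GRanges.
#' @param truth a [SimTruth-class]; causal variants must lie within
#'   `cisWindow` of their gene's TSS.
#' @param config a [SimConfig-class].
#' @param covariates optional samples x covariates numeric matrix entering
#'   the latent model with N(0, 0.5) coefficients.
#' @param cisWindow cis-window half-width used to validate causal pairs.
#' @return genes x samples matrix of FPKM-like values, with the latent
#'   (pre-transform) matrix attached as attribute `"latent"`.
#' @export
simulateExpression <- function(genotypes, genes, truth, config,
                               covariates = NULL, cisWindow = 1e6) {
  stopifnot(methods::is(genotypes, "GenotypeData"))
  v <- variantInfo(genotypes)
  pairs <- causalPairs(truth)
  if (nrow(pairs)) {
    vi <- match(pairs$variant_id, v$variant_id)
    gi <- match(pairs$gene_id, genes$gene_id)
    if (anyNA(vi) || anyNA(gi)) {
      stop("causal pair references unknown variant or gene ids",
        call. = FALSE
      )
    }
    off <- abs(v$pos[vi] - genes$tss[gi]) > cisWindow
    if (any(off)) {
      stop(
        "causal variant outside its gene's cis window: ",
        paste(pairs$variant_id[off], collapse = ", "),
        call. = FALSE
      )
    }
  }
  n <- ncol(dosages(genotypes))
  g <- length(genes)
  chrt <- cohortId(genotypes)
  withSubstream(config@seed, paste0("expression-", chrt), {
    latent <- matrix(stats::rnorm(g * n, sd = config@noiseSd),
      nrow = g,
      dimnames = list(genes$gene_id, colnames(dosages(genotypes)))
    )
    baseline <- stats::rnorm(g, sd = 0.5)
    latent <- latent + baseline
    if (config@nHiddenFactors > 0L) {
      fs <- matrix(stats::rnorm(config@nHiddenFactors * n),
        nrow = config@nHiddenFactors
      )
      latent <- latent + factorLoadings(truth)[genes$gene_id, ,
        drop = FALSE
      ] %*% fs
    }
    if (!is.null(covariates)) {
      covariates <- as.matrix(covariates)
      cc <- matrix(stats::rnorm(ncol(covariates), sd = 0.5), ncol = 1L)
      latent <- latent + matrix(rep(drop(covariates %*% cc), each = g),
        nrow = g
      )
    }
    if (nrow(pairs)) {
      bcol <- paste0("beta_", chrt)
      if (!bcol %in% colnames(pairs)) {
        stop("truth has no effect column for cohort ", chrt, call. = FALSE)
      }
      dimp <- imputeMissingDosage(dosages(genotypes))
      for (k in seq_len(nrow(pairs))) {
        latent[gi[k], ] <- latent[gi[k], ] + pairs[[bcol]][k] * dimp[vi[k], ]
      }
    }
    scale <- exp(stats::rnorm(g, mean = log(5), sd = 1))
    nLow <- floor(config@lowExprFraction * g)
    if (nLow > 0L) {
      low <- sample.int(g, nLow)
      scale[low] <- 0.1 / (2 * exp(apply(latent[low, , drop = FALSE], 1, max)))
    }
    fpkm <- scale * exp(latent)
    attr(fpkm, "latent") <- latent
    fpkm
  })
}

#' Simulate case-control phenotypes under a liability-threshold-free
#' logistic model
#'
#' Case probability per sample is the inverse logit of an intercept plus
#' the sum of planted per-allele log odds ratios times dosage plus modest
#' age and sex effects. The intercept is solved by bisection (tolerance
#' 1e-6) so that the sample-average case probability equals
#' `config@caseFraction`; statuses are then drawn independently.
#'
#' @param genotypes a [GenotypeData-class].
#' @param truth a [SimTruth-class]; risk variants must exist in the panel.
#' @param config a [SimConfig-class].
#' @param ageEffect,sexEffect covariate log-odds coefficients.
#' @return data.frame with sample_id, case_status (0/1), age (standardized
#'   units), sex (0/1), cohort_id.
#' @export
simulateCaseControl <- function(genotypes, truth, config,
                                ageEffect = 0.2, sexEffect = 0.1) {
  stopifnot(methods::is(genotypes, "GenotypeData"))
  v <- variantInfo(genotypes)
  risk <- riskVariants(truth)
  if (nrow(risk) && !all(risk$variant_id %in% v$variant_id)) {
    stop("risk variant not present in variant table", call. = FALSE)
  }
  n <- ncol(dosages(genotypes))
  chrt <- cohortId(genotypes)
  withSubstream(config@seed, paste0("phenotype-", chrt), {
    age <- stats::rnorm(n)
    sex <- stats::rbinom(n, 1L, 0.5)
    eta <- ageEffect * age + sexEffect * sex
    if (nrow(risk)) {
      dimp <- imputeMissingDosage(dosages(genotypes))
      ridx <- match(risk$variant_id, v$variant_id)
      eta <- eta + drop(crossprod(
        dimp[ridx, , drop = FALSE],
        risk$log_or
      ))
    }
    alpha <- solveInterceptForFraction(eta, config@caseFraction)
    pr <- stats::plogis(alpha + eta)
    for (try in seq_len(100L)) {
      status <- stats::rbinom(n, 1L, pr)
      if (any(status == 1L) && any(status == 0L)) break
    }
    if (all(status == status[1L])) {
      stop("could not draw both cases and controls; increase n or adjust ",
        "caseFraction",
        call. = FALSE
      )
    }
    data.frame(
      sample_id = colnames(dosages(genotypes)),
      case_status = status, age = age, sex = sex,
      cohort_id = chrt, stringsAsFactors = FALSE
    )
  })
}

# bisection for the logistic intercept achieving a target mean probability
solveInterceptForFraction <- function(eta, target, tol = 1e-6) {
  f <- function(a) mean(stats::plogis(a + eta)) - target
  lo <- -50
  hi <- 50
  if (f(lo) > 0 || f(hi) < 0) {
    stop("case fraction ", target, " not achievable for these effects",
      call. = FALSE
    )
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Simulate annotation tracks enriched at causal variants
#'
#' Builds an interval track (an open-chromatin analog) covering each
#' variant independently with probability `baseCoverage` for non-causal
#' variants and `min(1, enrichmentRatio * baseCoverage)` for causal
#' variants, plus a categorical label per variant (intergenic / intronic /
#' UTR / exonic analog) with causal variants preferentially non-intergenic.
#'
#' @param variants variant DataFrame.
#' @param truth a [SimTruth-class]; its causal-pair variants are the
#'   enriched set.
#' @param config a [SimConfig-class] (supplies the seed).
#' @param baseCoverage coverage probability for non-causal variants.
#' @param enrichmentRatio ratio of causal to background coverage
#'   probability; 1 means no enrichment.
#' @param featureHalfWidth half-width in bp of the interval drawn around a
#'   covered variant.
#' @return list with `track` (reduced GRanges) and `categories`
#'   (data.frame variant_id, category).
#' @export
simulateAnnotations <- function(variants, truth, config,
                                baseCoverage = 0.1, enrichmentRatio = 5,
                                featureHalfWidth = 100) {
  causal <- variants$variant_id %in% causalPairs(truth)$variant_id
  withSubstream(config@seed, "annotations", {
    pCov <- ifelse(causal, min(1, enrichmentRatio * baseCoverage),
      baseCoverage
    )
    covered <- stats::runif(nrow(variants)) < pCov
    track <- GenomicRanges::GRanges(seqnames = character(0), IRanges::IRanges())
    if (any(covered)) {
      start <- pmax(1, variants$pos[covered] - featureHalfWidth)
      end <- variants$pos[covered] + featureHalfWidth
      track <- GenomicRanges::reduce(GenomicRanges::GRanges(
        "chr1", IRanges::IRanges(start = start, end = end)
      ))
    }
    cats <- c("intergenic", "intronic", "UTR", "exonic")
    pCausal <- c(0.15, 0.50, 0.20, 0.15)
    pOther <- c(0.60, 0.25, 0.10, 0.05)
    lab <- character(nrow(variants))
    lab[causal] <- sample(cats, sum(causal), TRUE, prob = pCausal)
    lab[!causal] <- sample(cats, sum(!causal), TRUE, prob = pOther)
    list(
      track = track,
      categories = data.frame(
        variant_id = variants$variant_id,
        category = lab, stringsAsFactors = FALSE
      )
    )
  })
}

#' Simulate a complete multi-cohort study
#'
#' Convenience driver: shared variant panel and gene models, ground truth,
#' then per-cohort genotypes, expression and phenotypes, plus annotation
#' fixtures. See the component simulators for model details.
#'
#' @param config a [SimConfig-class].
#' @param cisWindow cis-window half-width in bp.
#' @param annotationArgs list of extra arguments for
#'   [simulateAnnotations()].
#' @return A [SimStudy-class].
#' @examples
#' study <- simulateStudy(simConfig(nSamples = c(a = 40, b = 40),
#'                                  nVariants = 60, nGenes = 8,
#'                                  nCausalPairs = 2, seed = 3))
#' study
#' @export
simulateStudy <- function(config, cisWindow = 1e6, annotationArgs = list()) {
  genes <- simulateGeneModels(config)
  variants <- makeVariantTable(config)
  truth <- simulateTruth(config, variants, genes, cisWindow = cisWindow)
  cohorts <- lapply(names(config@nSamples), function(cid) {
    gt <- simulateGenotypes(config, cid)
    ph <- simulateCaseControl(gt, truth, config)
    covs <- cbind(age = ph$age, sex = ph$sex)
    fpkm <- simulateExpression(gt, genes, truth, config,
      covariates = covs, cisWindow = cisWindow
    )
    latent <- attr(fpkm, "latent")
    attr(fpkm, "latent") <- NULL
    list(genotypes = gt, fpkm = fpkm, latent = latent, phenotype = ph)
  })
  names(cohorts) <- names(config@nSamples)
  ann <- do.call(simulateAnnotations, c(
    list(variants = variants, truth = truth, config = config),
    annotationArgs
  ))
  methods::new("SimStudy",
    config = config, genes = genes, truth = truth,
    cohorts = cohorts, annotations = ann
  )
}
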