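#' Simulation configuration for synthetic cohort studies
#'
#' Holds every parameter of the synthetic-cohort generator: cohort sample
#' sizes, variant and gene counts, the LD model (block size and latent
#' within-block correlation of the Gaussian copula), cis effect sizes,
#' hidden-factor structure, disease-model parameters, and the master seed
#' from which all per-operation random substreams are derived.
#'
#' @slot nSamples named integer vector; samples per cohort (names are
#'   cohort ids).
#' @slot nVariants,nGenes number of variants / genes on the synthetic
#'   chromosome.
#' @slot mafRange numeric length-2 interval within (0, 0.5] from which
#'   per-variant minor allele frequencies are drawn.
#' @slot ldBlockSize variants per LD block.
#' @slot ldRho lag-one latent correlation within an LD block, in [0, 1).
#' @slot nCausalPairs number of variant-gene pairs with a true cis effect.
#' @slot betaCausal per-allele effect on the latent expression scale
#'   (expression SD units); length 1 (shared) or one value per cohort
#'   (heterogeneous effects).
#' @slot nHiddenFactors,factorSd hidden confounder count and loading SD.
#' @slot noiseSd residual SD of latent expression.
#' @slot nRiskVariants,riskOR disease risk variants and their per-allele
#'   odds ratio.
#' @slot riskOverlapFraction fraction of risk variants drawn from the
#'   causal eQTL variants (risk acting through expression), in [0, 1].
#' @slot caseFraction expected case fraction in each cohort, in (0, 1).
#' @slot chromLength bp span of the synthetic chromosome.
#' @slot missingRate completely-at-random dosage missingness rate.
#' @slot lowExprFraction fraction of genes forced to mean FPKM below the
#'   expression filter floor (exercises the filter).
#' @slot seed master RNG seed.
#'
#' @seealso [simConfig()] for the user-facing constructor with defaults,
#'   [simulateStudy()] for the generator driven by this configuration.
#' @export
setClass("SimConfig", representation(
  nSamples = "integer",
  nVariants = "integer",
  nGenes = "integer",
  mafRange = "numeric",
  ldBlockSize = "integer",
  ldRho = "numeric",
  nCausalPairs = "integer",
  betaCausal = "numeric",
  nHiddenFactors = "integer",
  factorSd = "numeric",
  noiseSd = "numeric",
  nRiskVariants = "integer",
  riskOR = "numeric",
  riskOverlapFraction = "numeric",
  caseFraction = "numeric",
  chromLength = "numeric",
  missingRate = "numeric",
  lowExprFraction = "numeric",
  seed = "integer"
))

setValidity("SimConfig", function(object) {
  msg <- character()
  if (length(object@nSamples) < 1L || any(object@nSamples < 1L)) {
    msg <- c(msg, "nSamples must contain positive counts")
  }
  if (is.null(names(object@nSamples)) || anyDuplicated(names(object@nSamples))) {
    msg <- c(msg, "nSamples must carry unique cohort names")
  }
  if (object@nVariants < 1L) msg <- c(msg, "nVariants must be positive")
  if (object@nGenes < 1L) msg <- c(msg, "nGenes must be positive")
  if (length(object@mafRange) != 2L ||
    object@mafRange[1L] <= 0 || object@mafRange[2L] > 0.5 ||
    object@mafRange[1L] > object@mafRange[2L]) {
    msg <- c(msg, "mafRange must be an interval within (0, 0.5]")
  }
  if (object@ldBlockSize < 1L) msg <- c(msg, "ldBlockSize must be positive")
  if (object@ldRho < 0 || object@ldRho >= 1) {
    msg <- c(msg, "ldRho must lie in [0, 1)")
  }
  if (object@nCausalPairs < 0L) msg <- c(msg, "nCausalPairs must be >= 0")
  nc <- length(object@nSamples)
  if (!length(object@betaCausal) %in% c(1L, nc)) {
    msg <- c(msg, "betaCausal must have length 1 or one value per cohort")
  }
  if (object@nHiddenFactors < 0L) msg <- c(msg, "nHiddenFactors must be >= 0")
  if (object@factorSd < 0) msg <- c(msg, "factorSd must be >= 0")
  if (object@noiseSd <= 0) msg <- c(msg, "noiseSd must be positive")
  if (object@nRiskVariants < 0L) msg <- c(msg, "nRiskVariants must be >= 0")
  if (object@riskOR <= 0) msg <- c(msg, "riskOR must be positive")
  if (object@riskOverlapFraction < 0 || object@riskOverlapFraction > 1) {
    msg <- c(msg, "riskOverlapFraction must lie in [0, 1]")
  }
  if (object@caseFraction <= 0 || object@caseFraction >= 1) {
    msg <- c(msg, "caseFraction must lie in (0, 1)")
  }
  if (object@chromLength < object@nVariants) {
    msg <- c(msg, "chromLength too short for nVariants distinct positions")
  }
  if (object@missingRate < 0 || object@missingRate >= 1) {
    msg <- c(msg, "missingRate must lie in [0, 1)")
  }
  if (object@lowExprFraction < 0 || object@lowExprFraction >= 1) {
    msg <- c(msg, "lowExprFraction must lie in [0, 1)")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a simulation configuration
#'
#' Defaults mirror a two-cohort pancreatic-tissue eQTL design: cohort sizes
#' 177 and 305 (a tumor-cohort/normal-cohort split), per-allele cis effect
#' 0.25 expression SD units, risk-variant odds ratio 1.20, and a case
#' fraction matching a roughly balanced case-control collection.
#'
#' @param nSamples named integer vector of per-cohort sample sizes.
#' @param nVariants,nGenes variant and gene counts.
#' @param mafRange interval for per-variant MAFs, within (0, 0.5].
#' @param ldBlockSize,ldRho LD block size and within-block latent
#'   lag-one correlation of the Gaussian copula.
#' @param nCausalPairs,betaCausal number of causal variant-gene pairs and
#'   per-allele effect (length 1, or one per cohort for heterogeneous
#'   effects).
#' @param nHiddenFactors,factorSd,noiseSd hidden-factor count, loading SD
#'   and residual SD of the latent expression model.
#' @param nRiskVariants,riskOR,caseFraction disease-model parameters.
#' @param riskOverlapFraction fraction of risk variants drawn from the
#'   causal eQTL variant set, so that risk can act through expression and
#'   the GWAS-eQTL intersection has true positives.
#' @param chromLength synthetic chromosome length in bp.
#' @param missingRate completely-at-random dosage missingness rate.
#' @param lowExprFraction fraction of genes forced below the FPKM filter
#'   floor.
#' @param seed master seed; all substreams derive from it.
#' @return A [SimConfig-class] object.
#' @examples
#' cfg <- simConfig(nSamples = c(tcga = 60, gtex = 80), nVariants = 50,
#'                  nGenes = 10, seed = 7)
#' cfg
#' @export
simConfig <- function(nSamples = c(cohort1 = 177L, cohort2 = 305L),
                      nVariants = 1000L,
                      nGenes = 200L,
                      mafRange = c(0.05, 0.5),
                      ldBlockSize = 10L,
                      ldRho = 0.5,
                      nCausalPairs = 20L,
                      betaCausal = 0.25,
                      nHiddenFactors = 3L,
                      factorSd = 0.5,
                      noiseSd = 1,
                      nRiskVariants = 5L,
                      riskOR = 1.2,
                      riskOverlapFraction = 0.5,
                      caseFraction = 0.47,
                      chromLength = 1e7,
                      missingRate = 0,
                      lowExprFraction = 0.1,
                      seed = 1L) {
  if (length(mafRange) == 1L) mafRange <- rep(mafRange, 2L)
  ns <- as.integer(round(nSamples))
  names(ns) <- names(nSamples) %||% paste0("cohort", seq_along(nSamples))
  methods::new("SimConfig",
    nSamples = ns,
    nVariants = as.integer(nVariants),
    nGenes = as.integer(nGenes),
    mafRange = as.numeric(mafRange),
    ldBlockSize = as.integer(ldBlockSize),
    ldRho = as.numeric(ldRho),
    nCausalPairs = as.integer(nCausalPairs),
    betaCausal = as.numeric(betaCausal),
    nHiddenFactors = as.integer(nHiddenFactors),
    factorSd = as.numeric(factorSd),
    noiseSd = as.numeric(noiseSd),
    nRiskVariants = as.integer(nRiskVariants),
    riskOR = as.numeric(riskOR),
    riskOverlapFraction = as.numeric(riskOverlapFraction),
    caseFraction = as.numeric(caseFraction),
    chromLength = as.numeric(chromLength),
    missingRate = as.numeric(missingRate),
    lowExprFraction = as.numeric(lowExprFraction),
    seed = as.integer(seed)
  )
}

#' Per-cohort genotype dosages with variant metadata
#'
#' Variants are rows, samples are columns (the Bioconductor
#' features-by-samples convention). Dosages are expected alternative-allele
#' counts in [0, 2]; missing genotypes are `NA`. Variant metadata (position,
#' alleles, target MAF, imputation-quality analog) live in a parallel
#' [S4Vectors::DataFrame].
#'
#' @slot dosage numeric matrix, variants x samples, entries in [0, 2] or NA.
#' @slot variants DataFrame with columns variant_id, chrom, pos, ref, alt,
#'   maf, quality_score; rows aligned to the dosage matrix.
#' @slot cohortId cohort identifier.
#' @seealso [simulateGenotypes()], [dosages()], [variantInfo()]
#' @export
setClass("GenotypeData", representation(
  dosage = "matrix",
  variants = "DataFrame",
  cohortId = "character"
))

setValidity("GenotypeData", function(object) {
  msg <- character()
  v <- object@variants
  need <- c("variant_id", "chrom", "pos", "ref", "alt", "maf", "quality_score")
  if (!all(need %in% colnames(v))) {
    msg <- c(msg, paste(
      "variants must have columns:",
      paste(need, collapse = ", ")
    ))
  } else {
    if (anyDuplicated(v$variant_id)) msg <- c(msg, "variant ids must be unique")
    if (nrow(v) && any(v$pos < 1)) msg <- c(msg, "positions must be >= 1")
    if (nrow(v) && any(v$maf <= 0 | v$maf > 0.5)) {
      msg <- c(msg, "maf must lie in (0, 0.5]")
    }
  }
  if (nrow(object@dosage) != nrow(v)) {
    msg <- c(msg, "dosage rows must match variant table rows")
  }
  rng <- suppressWarnings(range(object@dosage, na.rm = TRUE))
  if (is.finite(rng[1L]) && (rng[1L] < 0 || rng[2L] > 2)) {
    msg <- c(msg, "non-missing dosages must lie in [0, 2]")
  }
  if (length(object@cohortId) != 1L) msg <- c(msg, "cohortId must be scalar")
  if (length(msg)) msg else TRUE
})

#' Simulator ground truth
#'
#' Records the planted structure of a synthetic study: causal variant-gene
#' pairs with their per-cohort effect sizes, disease risk variants with
#' per-allele log odds ratios, and the hidden-factor loading matrix.
#' Used by recovery and calibration tests downstream.
#'
#' @slot causalPairs data.frame with variant_id, gene_id and one
#'   `beta_<cohort>` column per cohort.
#' @slot riskVariants data.frame with variant_id and log_or.
#' @slot factorLoadings genes x factors numeric matrix.
#' @seealso [simulateTruth()]
#' @export
setClass("SimTruth", representation(
  causalPairs = "data.frame",
  riskVariants = "data.frame",
  factorLoadings = "matrix"
))

setValidity("SimTruth", function(object) {
  msg <- character()
  if (!all(c("variant_id", "gene_id") %in% colnames(object@causalPairs))) {
    msg <- c(msg, "causalPairs needs variant_id and gene_id columns")
  }
  if (!all(c("variant_id", "log_or") %in% colnames(object@riskVariants))) {
    msg <- c(msg, "riskVariants needs variant_id and log_or columns")
  }
  if (length(msg)) msg else TRUE
})

#' A complete synthetic multi-cohort study
#'
#' Container returned by [simulateStudy()]: the configuration, the shared
#' gene models and variant-level annotation fixtures, the ground truth,
#' and one genotype/expression/phenotype triple per cohort.
#'
#' @slot config the [SimConfig-class] used.
#' @slot genes [GenomicRanges::GRanges] gene models with `gene_id` and
#'   `tss` metadata columns.
#' @slot truth the [SimTruth-class] ground truth.
#' @slot cohorts named list; each element has `genotypes`
#'   ([GenotypeData-class]), `fpkm` (genes x samples matrix on the raw
#'   FPKM-like scale), `latent` (the pre-transform latent expression),
#'   and `phenotype` (data.frame with case_status, age, sex, cohort_id).
#' @slot annotations list with `track` (GRanges intervals) and
#'   `categories` (variant_id, category data.frame).
#' @export
setClass("SimStudy", representation(
  config = "SimConfig",
  genes = "GRanges",
  truth = "SimTruth",
  cohorts = "list",
  annotations = "list"
))

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", length(object@nSamples), "cohort(s) [",
    paste(sprintf("%s=%d", names(object@nSamples), object@nSamples),
      collapse = ", "
    ), "]\n",
    sep = " "
  )
  cat(sprintf(
    "  %d variants (MAF %.3g-%.3g, LD blocks of %d, rho %.2f), %d genes\n",
    object@nVariants, object@mafRange[1L], object@mafRange[2L],
    object@ldBlockSize, object@ldRho, object@nGenes
  ))
  cat(sprintf(
    "  %d causal pairs (beta %s), %d risk variants (OR %.2f), seed %d\n",
    object@nCausalPairs, paste(format(object@betaCausal), collapse = "/"),
    object@nRiskVariants, object@riskOR, object@seed
  ))
})

setMethod("show", "GenotypeData", function(object) {
  cat(sprintf(
    "GenotypeData '%s': %d variants x %d samples (%.2f%% missing)\n",
    object@cohortId, nrow(object@dosage), ncol(object@dosage),
    100 * mean(is.na(object@dosage))
  ))
})

setMethod("show", "SimTruth", function(object) {
  cat(sprintf(
    "SimTruth: %d causal pairs, %d risk variants, %d hidden factors\n",
    nrow(object@causalPairs), nrow(object@riskVariants),
    ncol(object@factorLoadings)
  ))
})

setMethod("show", "SimStudy", function(object) {
  cat(sprintf(
    "SimStudy: %d cohort(s), %d variants, %d genes\n",
    length(object@cohorts), object@config@nVariants, object@config@nGenes
  ))
  for (nm in names(object@cohorts)) {
    cat(sprintf("  %s: %d samples\n", nm, ncol(object@cohorts[[nm]]$fpkm)))
  }
})
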