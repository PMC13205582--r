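# Genotype QC, expression filtering/normalization, and covariate
# construction (ancestry PCs, hidden expression factors).

#' Default genotype and expression QC thresholds
#'
#' Cut-offs follow standard post-imputation practice: MAF >= 1%, genotype
#' missing rate < 5%, Hardy-Weinberg exact-test P > 1e-5, imputation
#' quality >= 0.3, and a mean-FPKM expression floor of 0.1.
#'
#' @param maf_min minimum folded allele frequency.
#' @param missing_max maximum missing-genotype fraction (exclusive).
#' @param hwe_p_min minimum Hardy-Weinberg exact p (exclusive).
#' @param quality_min minimum imputation-quality score.
#' @param fpkm_mean_min expression floor on the raw FPKM scale.
#' @return named list of thresholds.
#' @export
qcThresholds <- function(maf_min = 0.01, missing_max = 0.05,
                         hwe_p_min = 1e-5, quality_min = 0.3,
                         fpkm_mean_min = 0.1) {
  stopifnot(
    maf_min >= 0, maf_min <= 0.5, missing_max >= 0, missing_max <= 1,
    hwe_p_min >= 0, hwe_p_min <= 1, quality_min >= 0, quality_min <= 1,
    fpkm_mean_min >= 0
  )
  list(
    maf_min = maf_min, missing_max = missing_max, hwe_p_min = hwe_p_min,
    quality_min = quality_min, fpkm_mean_min = fpkm_mean_min
  )
}

#' Folded minor allele frequency of a dosage vector
#'
#' Allele frequency is mean(dosage)/2 over non-missing entries, folded to
#' `min(f, 1 - f)` so the result is always the minor allele's frequency.
#'
#' @param x numeric dosage vector in [0, 2], NA for missing.
#' @return folded allele frequency in [0, 0.5].
#' @examples
#' computeMAF(c(0, 1, 2, 1)) # 0.5
#' computeMAF(c(2, 2, 2, 2)) # 0, folded
#' @export
computeMAF <- function(x) {
  if (all(is.na(x))) {
    stop("all dosages missing; MAF undefined", call. = FALSE)
  }
  f <- mean(x, na.rm = TRUE) / 2
  min(f, 1 - f)
}

#' Hardy-Weinberg exact test
#'
#' Exact conditional test of the heterozygote count given the allele
#' counts under random mating. The two-sided p-value sums the
#' probabilities of all admissible heterozygote configurations whose
#' probability does not exceed that of the observed configuration
#' (minimum-likelihood rule). Computed by complete enumeration in log
#' space, so it is accurate for rare variants where chi-square
#' asymptotics fail.
#'
#' @param n_hom_major,n_het,n_hom_minor genotype counts.
#' @return two-sided exact p-value.
#' @examples
#' hweExactTest(100, 0, 0) # monomorphic: 1
#' hweExactTest(1, 0, 1) # 1/3
#' @export
hweExactTest <- function(n_hom_major, n_het, n_hom_minor) {
  counts <- c(n_hom_major, n_het, n_hom_minor)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("genotype counts must be non-negative integers", call. = FALSE)
  }
  n <- sum(counts)
  if (n < 1L) stop("at least one genotype required", call. = FALSE)
  # fold so 'minor' really is the rarer allele; the test is symmetric
  nMinor <- 2 * min(n_hom_minor, n_hom_major) + n_het
  hets <- seq.int(nMinor %% 2, nMinor, by = 2L)
  hets <- hets[(nMinor - hets) / 2 + hets <= n]
  logp <- vapply(hets, function(h) {
    b <- (nMinor - h) / 2
    a <- n - h - b
    lgamma(n + 1) - lgamma(a + 1) - lgamma(h + 1) - lgamma(b + 1) +
      h * log(2)
  }, numeric(1L))
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  obs <- pr[match(n_het, hets)]
  min(1, sum(pr[pr <= obs * (1 + 1e-10)]))
}

# all admissible heterozygote probabilities (for the enumeration invariant)
hweConfigProbs <- function(n, nMinor) {
  hets <- seq.int(nMinor %% 2, nMinor, by = 2L)
  hets <- hets[(nMinor - hets) / 2 + hets <= n]
  logp <- vapply(hets, function(h) {
    b <- (nMinor - h) / 2
    a <- n - h - b
    lgamma(n + 1) - lgamma(a + 1) - lgamma(h + 1) - lgamma(b + 1) +
      h * log(2)
  }, numeric(1L))
  pr <- exp(logp - max(logp))
  stats::setNames(pr / sum(pr), hets)
}

#' Variant quality control
#'
#' Applies the four post-imputation filters in a fixed order -- MAF,
#' missingness, Hardy-Weinberg, imputation quality -- and reports, per
#' excluded variant, the first criterion it failed. Hardy-Weinberg counts
#' are taken from dosages rounded to the nearest hard genotype.
#'
#' @param genotypes a [GenotypeData-class].
#' @param thresholds a list from [qcThresholds()].
#' @return list with `genotypes` (filtered [GenotypeData-class]) and
#'   `report` (data.frame: variant_id, maf, missing_rate, hwe_p,
#'   quality_score, pass, first_fail_reason).
#' @export
variantQC <- function(genotypes, thresholds = qcThresholds()) {
  stopifnot(methods::is(genotypes, "GenotypeData"))
  dos <- dosages(genotypes)
  v <- variantInfo(genotypes)
  m <- nrow(dos)
  maf <- apply(dos, 1L, function(x) {
    if (all(is.na(x))) NA_real_ else computeMAF(x)
  })
  missRate <- rowMeans(is.na(dos))
  hweP <- vapply(seq_len(m), function(i) {
    g <- round(dos[i, ])
    g <- g[!is.na(g)]
    if (!length(g)) {
      return(NA_real_)
    }
    hweExactTest(sum(g == 0), sum(g == 1), sum(g == 2))
  }, numeric(1L))
  qual <- v$quality_score
  reason <- rep(NA_character_, m)
  reason[is.na(reason) & (is.na(maf) | maf < thresholds$maf_min)] <- "maf"
  reason[is.na(reason) & missRate >= thresholds$missing_max] <- "missingness"
  reason[is.na(reason) & hweP <= thresholds$hwe_p_min] <- "hwe"
  reason[is.na(reason) & qual < thresholds$quality_min] <- "quality"
  pass <- is.na(reason)
  if (!any(pass)) {
    warning("no variants survive QC", call. = FALSE)
  }
  report <- data.frame(
    variant_id = v$variant_id, maf = maf, missing_rate = missRate,
    hwe_p = hweP, quality_score = qual, pass = pass,
    first_fail_reason = reason, stringsAsFactors = FALSE
  )
  filtered <- methods::new("GenotypeData",
    dosage = dos[pass, , drop = FALSE],
    variants = v[pass, , drop = FALSE],
    cohortId = cohortId(genotypes)
  )
  list(genotypes = filtered, report = report)
}

#' Drop lowly expressed genes
#'
#' Removes genes whose across-sample mean on the raw FPKM scale is
#' strictly below the floor; a gene exactly at the floor is kept.
#'
#' @param fpkm genes x samples matrix on the raw scale.
#' @param fpkm_mean_min expression floor (default 0.1).
#' @return the filtered matrix.
#' @export
filterGenesByExpression <- function(fpkm, fpkm_mean_min = 0.1) {
  keep <- rowMeans(fpkm) >= fpkm_mean_min
  if (!any(keep)) {
    warning("all genes fall below the expression floor", call. = FALSE)
  }
  fpkm[keep, , drop = FALSE]
}

#' Rank-based inverse-normal transform
#'
#' Maps a vector to standard-normal quantiles of (rank - 0.5)/n with
#' average ranks for ties. The output depends only on the ranks, so any
#' strictly monotone transform of the input yields identical output. A
#' constant vector maps to all zeros with a warning.
#'
#' @param x numeric vector (NA allowed; NAs propagate).
#' @return transformed vector of the same length.
#' @examples
#' inverseNormalTransform(c(5, 1, 9))
#' @export
inverseNormalTransform <- function(x) {
  ok <- !is.na(x)
  if (sum(ok) < 2L) {
    stop("need at least 2 non-missing values", call. = FALSE)
  }
  out <- rep(NA_real_, length(x))
  v <- x[ok]
  if (length(unique(v)) == 1L) {
    warning("constant vector: all ranks tied, output all zero",
      call. = FALSE
    )
    out[ok] <- 0
    return(out)
  }
  r <- rank(v, ties.method = "average")
  out[ok] <- stats::qnorm((r - 0.5) / length(v))
  out
}

# row-wise INT for a genes x samples matrix
intByGene <- function(mat) {
  out <- t(apply(mat, 1L, inverseNormalTransform))
  dimnames(out) <- dimnames(mat)
  out
}

#' Ancestry principal components from genotype dosages
#'
#' Mean-imputes missing dosages per variant, standardizes each variant to
#' zero mean and unit variance, and returns the top-k sample scores of the
#' singular value decomposition, ordered by decreasing variance explained.
#' Used as population-structure covariates in association models.
#'
#' @param genotypes a [GenotypeData-class] (post-QC).
#' @param k number of components.
#' @return samples x k matrix of PC scores (columns PC1..PCk) with the
#'   variance explained attached as attribute `"varexp"`.
#' @export
ancestryPCs <- function(genotypes, k = 5L) {
  stopifnot(methods::is(genotypes, "GenotypeData"))
  dos <- imputeMissingDosage(dosages(genotypes))
  n <- ncol(dos)
  if (k == 0L) {
    out <- matrix(numeric(0), nrow = n, ncol = 0L)
    rownames(out) <- colnames(dos)
    return(out)
  }
  sds <- apply(dos, 1L, stats::sd)
  keep <- sds > 0
  z <- (dos[keep, , drop = FALSE] - rowMeans(dos[keep, , drop = FALSE])) /
    sds[keep]
  maxRank <- min(dim(z)) - 1L
  if (k > maxRank) {
    stop("k = ", k, " exceeds admissible rank ", maxRank, call. = FALSE)
  }
  sv <- svd(t(z), nu = k, nv = 0L)
  scores <- sv$u %*% diag(sv$d[seq_len(k)], nrow = k)
  dimnames(scores) <- list(colnames(dos), paste0("PC", seq_len(k)))
  attr(scores, "varexp") <- sv$d[seq_len(k)]^2 / sum(sv$d^2)
  scores
}

#' Hidden expression factors
#'
#' Deterministic latent-confounder estimator for expression data:
#' residualizes the (inverse-normal transformed) expression matrix
#' gene-wise on the known covariates, then returns the top-k sample-score
#' singular vectors of the residual matrix. These play the role that
#' probabilistic expression-residual factors play in large eQTL studies;
#' the default count of 15 matches common practice for cohorts of a few
#' hundred samples.
#'
#' @param expr genes x samples matrix, already inverse-normal transformed.
#' @param knownCovariates samples x covariates matrix (may be NULL); an
#'   intercept is always included in the residualization.
#' @param k number of factors (default 15).
#' @return samples x k matrix of factor scores (factor1..factork).
#' @export
hiddenFactors <- function(expr, knownCovariates = NULL, k = 15L) {
  n <- ncol(expr)
  if (k >= min(dim(expr))) {
    stop("k must be smaller than min(genes, samples)", call. = FALSE)
  }
  if (k == 0L) {
    out <- matrix(numeric(0), nrow = n, ncol = 0L)
    rownames(out) <- colnames(expr)
    return(out)
  }
  design <- cbind(intercept = rep(1, n), knownCovariates)
  qrD <- qr(design)
  q <- qr.Q(qrD)[, seq_len(qrD$rank), drop = FALSE]
  resid <- expr - (expr %*% q) %*% t(q)
  sv <- svd(t(resid), nu = k, nv = 0L)
  scores <- sv$u
  dimnames(scores) <- list(colnames(expr), paste0("factor", seq_len(k)))
  scores
}

#' Assemble a covariate matrix
#'
#' Column-binds known covariates, ancestry PCs and hidden factors into a
#' single samples x covariates matrix with a provenance attribute, the
#' form expected by the association fitters.
#'
#' @param known samples x covariates matrix or data.frame of measured
#'   covariates (e.g. age, sex); may be NULL.
#' @param pcs ancestry PC scores from [ancestryPCs()]; may be NULL.
#' @param factors hidden-factor scores from [hiddenFactors()]; may be NULL.
#' @return numeric matrix with attribute `"provenance"` labelling each
#'   column as known / ancestry_pc / hidden_factor.
#' @export
buildCovariates <- function(known = NULL, pcs = NULL, factors = NULL) {
  parts <- list(known = known, ancestry_pc = pcs, hidden_factor = factors)
  parts <- parts[!vapply(parts, is.null, logical(1L))]
  parts <- parts[vapply(parts, function(p) ncol(as.matrix(p)) > 0, logical(1L))]
  if (!length(parts)) {
    return(NULL)
  }
  mats <- lapply(parts, as.matrix)
  out <- do.call(cbind, mats)
  if (anyNA(out)) {
    stop("covariates must not contain missing values", call. = FALSE)
  }
  attr(out, "provenance") <- rep(names(parts), vapply(mats, ncol, integer(1L)))
  out
}
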