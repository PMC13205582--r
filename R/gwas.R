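# Case-control association under an additive model, genomic-inflation
# diagnostics, suggestive-variant selection, distance-based locus
# grouping, and analytic power for the Cochran-Armitage trend test.

#' Logistic association of case status with allele dosage
#'
#' Maximum-likelihood logistic regression (iteratively reweighted least
#' squares, convergence when the deviance change is below 1e-8, at most
#' 100 iterations) of case status on dosage and covariates. Reports the
#' per-allele log odds ratio with its Wald standard error, z and
#' two-sided normal p. Fits that do not converge or give |log OR| > 10
#' (separation) are marked `converged = FALSE` so callers can exclude
#' them.
#'
#' @param status 0/1 outcome vector with both classes present.
#' @param dosage numeric dosage vector (non-constant; missing values are
#'   mean-imputed).
#' @param covariates samples x covariates matrix or NULL.
#' @return one-row data.frame: log_or, se, z, p, n_cases, n_controls,
#'   converged.
#' @export
logisticAssoc <- function(status, dosage, covariates = NULL) {
  stopifnot(length(status) == length(dosage))
  if (!all(status %in% c(0, 1))) {
    stop("status must be a 0/1 vector", call. = FALSE)
  }
  if (length(unique(status)) < 2L) {
    stop("both outcome classes must be present", call. = FALSE)
  }
  if (anyNA(dosage)) dosage[is.na(dosage)] <- mean(dosage, na.rm = TRUE)
  if (stats::var(dosage) == 0) {
    stop("constant dosage: association undefined", call. = FALSE)
  }
  design <- cbind(intercept = 1, dosage = dosage, covariates)
  fit <- suppressWarnings(stats::glm.fit(
    x = design, y = status, family = stats::binomial(),
    control = stats::glm.control(epsilon = 1e-12, maxit = 100L)
  ))
  j <- which(colnames(design) == "dosage")
  rank <- fit$rank
  qrR <- fit$qr$qr[seq_len(rank), seq_len(rank), drop = FALSE]
  covmat <- chol2inv(qrR)
  # map back through pivoting
  piv <- fit$qr$pivot[seq_len(rank)]
  se <- rep(NA_real_, ncol(design))
  se[piv] <- sqrt(diag(covmat))
  logOr <- unname(fit$coefficients[j])
  seJ <- se[j]
  z <- logOr / seJ
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(
    log_or = logOr, se = seJ, z = z, p = p,
    n_cases = sum(status == 1), n_controls = sum(status == 0),
    converged = isTRUE(fit$converged) && is.finite(logOr) &&
      abs(logOr) <= 10
  )
}

#' Scan all variants for case-control association
#'
#' Runs [logisticAssoc()] per variant; non-converged or degenerate fits
#' are retained in the table with `converged = FALSE` and a message, so
#' downstream selection can exclude them.
#'
#' @param genotypes a [GenotypeData-class].
#' @param phenotype data.frame with case_status aligned to the genotype
#'   samples.
#' @param covariates samples x covariates matrix or NULL.
#' @return data.frame: variant_id, effect_allele, other_allele, beta
#'   (log OR), se, z, p, n_cases, n_controls, converged.
#' @export
gwasScan <- function(genotypes, phenotype, covariates = NULL) {
  stopifnot(methods::is(genotypes, "GenotypeData"))
  v <- variantInfo(genotypes)
  dos <- imputeMissingDosage(dosages(genotypes))
  status <- phenotype$case_status
  rows <- lapply(seq_len(nrow(v)), function(i) {
    res <- tryCatch(
      logisticAssoc(status, dos[i, ], covariates),
      error = function(e) {
        data.frame(
          log_or = NA_real_, se = NA_real_, z = NA_real_, p = NA_real_,
          n_cases = sum(status == 1), n_controls = sum(status == 0),
          converged = FALSE
        )
      }
    )
    res
  })
  stat <- do.call(rbind, rows)
  nBad <- sum(!stat$converged)
  if (nBad > 0L) {
    message(nBad, " variant(s) flagged non-converged or degenerate")
  }
  data.frame(
    variant_id = v$variant_id,
    effect_allele = v$alt, other_allele = v$ref,
    beta = stat$log_or, se = stat$se, z = stat$z, p = stat$p,
    n_cases = stat$n_cases, n_controls = stat$n_controls,
    converged = stat$converged, stringsAsFactors = FALSE
  )
}

#' Genomic inflation factor
#'
#' Converts two-sided p-values to 1-df chi-square quantiles and divides
#' their median by the 1-df chi-square median (about 0.4549); a
#' well-calibrated null gives lambda close to 1.
#'
#' @param p vector of p-values in (0, 1].
#' @return lambda.
#' @examples
#' genomicLambda(rep(0.5, 10)) # exactly 1
#' @export
genomicLambda <- function(p) {
  p <- p[!is.na(p)]
  if (!length(p)) stop("no p-values supplied", call. = FALSE)
  if (any(p <= 0 | p > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  chisq <- stats::qchisq(p, df = 1, lower.tail = FALSE)
  stats::median(chisq) / stats::qchisq(0.5, df = 1)
}

#' Select suggestive GWAS variants
#'
#' Keeps variants with meta-analysis p below `p_meta_max`, nominal
#' association in every cohort (p below `p_cohort_max`), and -- by
#' default -- a concordant effect direction across cohorts (implied by
#' fixed-effects pooling and made explicit here). Non-converged cohort
#' fits disqualify a variant.
#'
#' @param metaTable meta data.frame with variant_id and p.
#' @param cohortTables named list of per-cohort tables (variant_id, beta,
#'   p, optionally converged).
#' @param p_meta_max meta-analysis threshold (default 1e-5).
#' @param p_cohort_max per-cohort threshold (default 0.05).
#' @param requireConcordant require a shared effect sign across cohorts.
#' @return the qualifying subset of `metaTable`, with per-cohort p-value
#'   columns `p_<cohort>` appended.
#' @export
selectSuggestive <- function(metaTable, cohortTables, p_meta_max = 1e-5,
                             p_cohort_max = 0.05,
                             requireConcordant = TRUE) {
  keep <- metaTable$p < p_meta_max
  signs <- NULL
  for (nm in names(cohortTables)) {
    tb <- cohortTables[[nm]]
    i <- match(metaTable$variant_id, tb$variant_id)
    pC <- tb$p[i]
    ok <- !is.na(pC) & pC < p_cohort_max
    if ("converged" %in% colnames(tb)) {
      ok <- ok & !is.na(tb$converged[i]) & tb$converged[i]
    }
    keep <- keep & ok
    metaTable[[paste0("p_", nm)]] <- pC
    s <- sign(tb$beta[i])
    signs <- if (is.null(signs)) s else cbind(signs, s)
  }
  if (requireConcordant && !is.null(signs)) {
    signs <- cbind(signs)
    conc <- apply(signs, 1L, function(s) {
      s <- s[!is.na(s)]
      length(s) == 0L || all(s == s[1L])
    })
    keep <- keep & conc
  }
  out <- metaTable[which(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Group selected variants into loci
#'
#' Greedy distance clumping: variants are processed by ascending p; each
#' unassigned variant within `gap` bp of an existing index variant (on
#' the same chromosome) joins that locus, otherwise it founds a new one.
#' The result is deterministic and invariant to input row order.
#'
#' @param variants data.frame with variant_id, chrom, pos and p.
#' @param gap clumping distance in bp (default 500 kb).
#' @return list with `assignments` (input plus locus_id, is_index) and
#'   `loci` (locus_id, chrom, span_start, span_end, index_variant,
#'   n_variants, min_p).
#' @export
defineLoci <- function(variants, gap = 5e5) {
  if (!nrow(variants)) {
    return(list(
      assignments = cbind(variants,
        locus_id = character(0),
        is_index = logical(0)
      ),
      loci = data.frame()
    ))
  }
  ord <- order(variants$p, variants$chrom, variants$pos, variants$variant_id)
  v <- variants[ord, , drop = FALSE]
  locus <- integer(nrow(v))
  idxChrom <- character(0)
  idxPos <- numeric(0)
  for (i in seq_len(nrow(v))) {
    hit <- which(idxChrom == v$chrom[i] & abs(idxPos - v$pos[i]) <= gap)
    if (length(hit)) {
      locus[i] <- hit[1L]
    } else {
      idxChrom <- c(idxChrom, v$chrom[i])
      idxPos <- c(idxPos, v$pos[i])
      locus[i] <- length(idxPos)
    }
  }
  v$locus_id <- sprintf("locus%03d", locus)
  v$is_index <- !duplicated(locus)
  loci <- do.call(rbind, lapply(split(v, v$locus_id), function(g) {
    data.frame(
      locus_id = g$locus_id[1L], chrom = g$chrom[1L],
      span_start = min(g$pos), span_end = max(g$pos),
      index_variant = g$variant_id[which.min(g$p)],
      n_variants = nrow(g), min_p = min(g$p),
      stringsAsFactors = FALSE
    )
  }))
  rownames(loci) <- NULL
  assignments <- v[match(variants$variant_id, v$variant_id), , drop = FALSE]
  rownames(assignments) <- NULL
  list(assignments = assignments, loci = loci)
}

#' Analytic power of the Cochran-Armitage trend test
#'
#' Additive-on-risk disease model: with baseline penetrance f0 solved
#' from the prevalence under Hardy-Weinberg genotype frequencies,
#' heterozygote penetrance is grr * f0 and risk-homozygote penetrance is
#' (2 * grr - 1) * f0. Case and control genotype distributions follow by
#' Bayes' rule; the trend statistic (scores 0, 1, 2, null-variance
#' standardization) has a 1-df noncentral chi-square distribution under
#' the alternative, and power is its upper tail beyond the central
#' critical value at `alpha`.
#'
#' @param n_cases,n_controls sample sizes.
#' @param maf risk-allele frequency in (0, 0.5].
#' @param grr per-allele genotype relative risk (> 0).
#' @param alpha two-sided significance level.
#' @param prevalence disease prevalence in (0, 1).
#' @return power in [0, 1].
#' @examples
#' trendTestPower(5130, 5776, maf = 0.2, grr = 1.2, alpha = 1e-5)
#' @export
trendTestPower <- function(n_cases, n_controls, maf, grr, alpha = 1e-5,
                           prevalence = 0.01) {
  stopifnot(
    n_cases > 0, n_controls > 0, maf > 0, maf <= 0.5, grr > 0,
    alpha > 0, alpha < 1, prevalence > 0, prevalence < 1
  )
  q <- maf
  g <- c((1 - q)^2, 2 * q * (1 - q), q^2)
  rr <- c(1, grr, 2 * grr - 1)
  if (any(rr < 0)) {
    stop("grr too small: negative homozygote relative risk", call. = FALSE)
  }
  f0 <- prevalence / sum(g * rr)
  f <- f0 * rr
  if (any(f > 1) || any(f < 0)) {
    stop("implied penetrances fall outside [0, 1]; reduce grr or ",
      "prevalence",
      call. = FALSE
    )
  }
  pCase <- g * f / prevalence
  pCtrl <- g * (1 - f) / (1 - prevalence)
  scores <- c(0, 1, 2)
  mu1 <- sum(scores * pCase)
  mu0 <- sum(scores * pCtrl)
  wCase <- n_cases / (n_cases + n_controls)
  pBar <- wCase * pCase + (1 - wCase) * pCtrl
  varBar <- sum(scores^2 * pBar) - sum(scores * pBar)^2
  seNull <- sqrt(varBar * (1 / n_cases + 1 / n_controls))
  ncp <- ((mu1 - mu0) / seNull)^2
  crit <- stats::qchisq(1 - alpha, df = 1)
  stats::pchisq(crit, df = 1, ncp = ncp, lower.tail = FALSE)
}
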