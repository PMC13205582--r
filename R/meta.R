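# Fixed-effects inverse-variance meta-analysis with Cochran's Q and I2,
# odds-ratio/CI conversion for stage-level combination, and the
# substantial-heterogeneity triage rule (I2 >= 75% and P_Het < 0.05).

#' Fixed-effects inverse-variance meta-analysis
#'
#' Pools per-study effects with weights 1/se^2. Returns the pooled effect
#' and SE, the normal-approximation z and two-sided p (the fixed-effects
#' convention), Cochran's Q with its chi-square heterogeneity p at k - 1
#' degrees of freedom, and I2 = max(0, (Q - df)/Q) * 100 (0 when Q = 0).
#' The heterogeneity flag marks I2 >= 75% together with P_Het < 0.05.
#' A single study passes through unchanged with Q = 0, P_Het = 1, I2 = 0.
#'
#' @param beta numeric vector of per-study effects (k >= 1).
#' @param se matching vector of positive standard errors.
#' @param i2_min,p_het_max triage thresholds for the heterogeneity flag.
#' @return one-row data.frame: beta_meta, se_meta, z, p, q, df, p_het,
#'   i2, k, het_flag.
#' @examples
#' ivwMeta(c(0.2, 0.4), c(0.1, 0.2)) # beta_meta 0.24
#' @export
ivwMeta <- function(beta, se, i2_min = 75, p_het_max = 0.05) {
  k <- length(beta)
  stopifnot(k >= 1L, length(se) == k)
  bad <- which(!(se > 0))
  if (length(bad)) {
    stop("non-positive standard error at index ",
      paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  w <- 1 / se^2
  betaMeta <- sum(w * beta) / sum(w)
  seMeta <- 1 / sqrt(sum(w))
  z <- betaMeta / seMeta
  p <- 2 * stats::pnorm(-abs(z))
  df <- k - 1L
  q <- sum(w * (beta - betaMeta)^2)
  pHet <- if (df == 0L) 1 else stats::pchisq(q, df, lower.tail = FALSE)
  i2 <- if (q <= 0) 0 else max(0, (q - df) / q) * 100
  data.frame(
    beta_meta = betaMeta, se_meta = seMeta, z = z, p = p,
    q = q, df = df, p_het = pHet, i2 = i2, k = k,
    het_flag = (i2 >= i2_min && pHet < p_het_max)
  )
}

# strand-ambiguous allele pair (A/T or C/G)?
isAmbiguous <- function(a1, a2) {
  p <- paste0(toupper(a1), toupper(a2))
  p %in% c("AT", "TA", "CG", "GC")
}

#' Harmonize effect alleles across study summary tables
#'
#' Aligns every study to the first study's effect/other alleles before
#' pooling: a study whose alleles are swapped relative to the reference
#' has its beta sign flipped; rows whose alleles cannot be reconciled, or
#' whose mismatch involves a strand-ambiguous (A/T, C/G) pair, are
#' dropped with a warning.
#'
#' @param tables named list of summary data.frames, each with columns in
#'   `by` plus effect_allele, other_allele, beta.
#' @param by key columns (e.g. "variant_id", or variant and gene ids).
#' @return the list with betas aligned and irreconcilable rows removed.
#' @export
harmonizeAlleles <- function(tables, by = "variant_id") {
  ref <- tables[[1L]]
  key <- function(df) do.call(paste, c(df[by], sep = "\r"))
  refKey <- key(ref)
  for (nm in names(tables)[-1L]) {
    tb <- tables[[nm]]
    idx <- match(key(tb), refKey)
    has <- !is.na(idx)
    ea <- toupper(tb$effect_allele)
    oa <- toupper(tb$other_allele)
    rea <- toupper(ref$effect_allele[idx])
    roa <- toupper(ref$other_allele[idx])
    same <- has & ea == rea & oa == roa
    swapped <- has & ea == roa & oa == rea & !same
    mismatch <- has & !same & !swapped
    ambig <- swapped & isAmbiguous(ea, oa)
    drop <- mismatch | ambig
    if (any(drop)) {
      warning(
        sum(drop), " row(s) dropped in study '", nm,
        "' (irreconcilable or strand-ambiguous alleles)",
        call. = FALSE
      )
    }
    flip <- swapped & !ambig
    tb$beta[flip] <- -tb$beta[flip]
    tmp <- tb$effect_allele[flip]
    tb$effect_allele[flip] <- tb$other_allele[flip]
    tb$other_allele[flip] <- tmp
    tables[[nm]] <- tb[!drop, , drop = FALSE]
  }
  tables
}

#' Meta-analyze per-study association tables
#'
#' Joins per-study summary tables on the key columns and pools each
#' shared test with [ivwMeta()]. When allele columns are present, effect
#' alleles are harmonized first (see [harmonizeAlleles()]). Tests present
#' in only one study are pooled as k = 1 pass-through rows and labelled
#' `single_cohort` unless `requireAll` is set, in which case they are
#' dropped.
#'
#' @param tables named list of data.frames with the key columns plus
#'   beta, se (and optionally p, effect_allele, other_allele).
#' @param by key columns; use c("variant_id", "gene_id") for eQTL tables.
#' @param requireAll drop tests absent from any study.
#' @param i2_min,p_het_max triage thresholds passed to [ivwMeta()].
#' @return data.frame: key columns, beta_meta, se_meta, z, p, q, df,
#'   p_het, i2, k, het_flag, single_cohort.
#' @export
metaAnalyzePairs <- function(tables, by = c("variant_id", "gene_id"),
                             requireAll = FALSE, i2_min = 75,
                             p_het_max = 0.05) {
  stopifnot(length(tables) >= 1L)
  hasAlleles <- all(vapply(
    tables,
    function(t) all(c("effect_allele", "other_allele") %in% colnames(t)),
    logical(1L)
  ))
  if (hasAlleles && length(tables) > 1L) {
    tables <- harmonizeAlleles(tables, by = by)
  }
  tables <- lapply(tables, function(t) {
    t <- t[!is.na(t$beta) & !is.na(t$se) & t$se > 0, , drop = FALSE]
    t
  })
  key <- function(df) do.call(paste, c(df[by], sep = "\r"))
  allKeys <- unique(unlist(lapply(tables, key)))
  idx <- lapply(tables, function(t) match(allKeys, key(t)))
  k <- Reduce(`+`, lapply(idx, function(i) !is.na(i)))
  if (requireAll) {
    keep <- k == length(tables)
    allKeys <- allKeys[keep]
    idx <- lapply(idx, function(i) i[keep])
    k <- k[keep]
  }
  # vectorized IVW across the key set (same arithmetic as ivwMeta)
  nk <- length(allKeys)
  B <- S <- matrix(NA_real_, nrow = nk, ncol = length(tables))
  for (t in seq_along(tables)) {
    i <- idx[[t]]
    has <- !is.na(i)
    B[has, t] <- tables[[t]]$beta[i[has]]
    S[has, t] <- tables[[t]]$se[i[has]]
  }
  w <- 1 / S^2
  sw <- rowSums(w, na.rm = TRUE)
  betaMeta <- rowSums(w * B, na.rm = TRUE) / sw
  seMeta <- 1 / sqrt(sw)
  z <- betaMeta / seMeta
  q <- rowSums(w * (B - betaMeta)^2, na.rm = TRUE)
  df <- k - 1L
  pHet <- ifelse(df == 0L, 1, stats::pchisq(q, pmax(df, 1L),
    lower.tail = FALSE
  ))
  i2 <- ifelse(q <= 0, 0, pmax(0, (q - df) / q) * 100)
  meta <- data.frame(
    beta_meta = betaMeta, se_meta = seMeta, z = z,
    p = 2 * stats::pnorm(-abs(z)), q = q, df = df, p_het = pHet,
    i2 = i2, k = k, het_flag = (i2 >= i2_min & pHet < p_het_max)
  )
  keyParts <- strsplit(allKeys, "\r", fixed = TRUE)
  keyDf <- as.data.frame(
    do.call(rbind, keyParts),
    stringsAsFactors = FALSE
  )
  colnames(keyDf) <- by
  # carry tss_distance through when every contributing table agrees on it
  extra <- NULL
  if (all(vapply(tables, function(t) "tss_distance" %in% colnames(t),
    logical(1L)
  ))) {
    d <- rep(NA_real_, length(allKeys))
    for (t in seq_along(tables)) {
      i <- idx[[t]]
      d[is.na(d) & !is.na(i)] <-
        tables[[t]]$tss_distance[i[is.na(d) & !is.na(i)]]
    }
    extra <- data.frame(tss_distance = d)
  }
  out <- if (is.null(extra)) cbind(keyDf, meta) else cbind(keyDf, extra, meta)
  out$single_cohort <- out$k == 1L & length(tables) > 1L
  rownames(out) <- NULL
  out
}

#' Convert a printed odds ratio and confidence interval to log scale
#'
#' Recovers the log odds ratio and its standard error from a published
#' OR with a Wald confidence interval:
#' se = (ln(upper) - ln(lower)) / (2 * z), with z the standard-normal
#' quantile at (1 + level)/2.
#'
#' @param or_value odds ratio.
#' @param ci_low,ci_high confidence bounds (0 < ci_low <= or <= ci_high).
#' @param level confidence level of the interval (default 0.95).
#' @return named numeric: log_or, se.
#' @examples
#' ciToLogScale(0.86, 0.80, 0.92)
#' @export
ciToLogScale <- function(or_value, ci_low, ci_high, level = 0.95) {
  stopifnot(level > 0, level < 1)
  if (!(ci_low > 0 && ci_low <= or_value && or_value <= ci_high)) {
    stop("require 0 < ci_low <= or_value <= ci_high", call. = FALSE)
  }
  if (ci_low == ci_high) {
    stop("degenerate interval: ci_low equals ci_high", call. = FALSE)
  }
  z <- stats::qnorm((1 + level) / 2)
  c(
    log_or = log(or_value),
    se = (log(ci_high) - log(ci_low)) / (2 * z)
  )
}

#' Combine study stages reported as odds ratios with confidence intervals
#'
#' Converts each stage's printed OR and 95% CI to the log scale, pools by
#' fixed-effects inverse-variance weighting, and exponentiates the pooled
#' effect and its Wald interval. This is the standard way to combine a
#' discovery and a replication stage from their published summaries.
#'
#' @param stages data.frame (or matrix) with columns or_value, ci_low,
#'   ci_high; one row per stage, at least two stages.
#' @param level confidence level of the stage intervals.
#' @return one-row data.frame: or_meta, ci_low, ci_high, p, z, q, i2, k.
#' @examples
#' combineORStages(data.frame(
#'   or_value = c(0.86, 0.81),
#'   ci_low = c(0.80, 0.71), ci_high = c(0.92, 0.92)
#' ))
#' @export
combineORStages <- function(stages, level = 0.95) {
  stages <- as.data.frame(stages)
  stopifnot(nrow(stages) >= 2L)
  conv <- t(mapply(
    ciToLogScale, stages$or_value, stages$ci_low, stages$ci_high,
    MoreArgs = list(level = level)
  ))
  m <- ivwMeta(conv[, "log_or"], conv[, "se"])
  z <- stats::qnorm((1 + level) / 2)
  data.frame(
    or_meta = exp(m$beta_meta),
    ci_low = exp(m$beta_meta - z * m$se_meta),
    ci_high = exp(m$beta_meta + z * m$se_meta),
    p = m$p, z = m$z, q = m$q, i2 = m$i2, k = m$k
  )
}

#' Flag meta-analysis rows with substantial heterogeneity
#'
#' Applies the triage rule I2 >= `i2_min` (percent) and P_Het <
#' `p_het_max` to a meta-analysis table and reports the flagged subset
#' and its proportion.
#'
#' @param metaTable data.frame with i2 and p_het columns (as produced by
#'   [metaAnalyzePairs()]).
#' @param i2_min I2 threshold in percent (default 75).
#' @param p_het_max heterogeneity-p threshold (default 0.05).
#' @return list with `table` (input plus het_flag), `flagged` (subset),
#'   and `proportion`.
#' @export
heterogeneityTriage <- function(metaTable, i2_min = 75, p_het_max = 0.05) {
  stopifnot(nrow(metaTable) > 0L)
  flag <- metaTable$i2 >= i2_min & metaTable$p_het < p_het_max
  metaTable$het_flag <- flag
  list(
    table = metaTable,
    flagged = metaTable[flag, , drop = FALSE],
    proportion = mean(flag)
  )
}
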