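# Per-cohort cis-eQTL mapping: cis-pair enumeration around the TSS and
# covariate-adjusted linear association, with a residualization fast path
# that reproduces full multiple regression exactly (Frisch-Waugh).

#' Enumerate cis variant-gene pairs
#'
#' Pairs every variant with every gene on the same chromosome whose TSS
#' lies within `window` bp (inclusive at both boundaries). The signed TSS
#' distance is pos - tss, with the sign flipped for minus-strand genes so
#' that positive always means downstream of transcription.
#'
#' @param variants variant DataFrame (as in [variantInfo()]) or a
#'   [GenotypeData-class].
#' @param genes gene GRanges with `gene_id` and `tss` metadata.
#' @param window cis-window half-width in bp (default 1e6).
#' @return data.frame with variant_id, gene_id, tss_distance.
#' @examples
#' # a variant exactly at the window edge is kept
#' @export
cisPairs <- function(variants, genes, window = 1e6) {
  stopifnot(window > 0)
  if (methods::is(variants, "GenotypeData")) variants <- variantInfo(variants)
  if (!nrow(variants) || !length(genes)) {
    return(data.frame(
      variant_id = character(), gene_id = character(),
      tss_distance = numeric(), stringsAsFactors = FALSE
    ))
  }
  vgr <- GenomicRanges::GRanges(
    seqnames = variants$chrom,
    ranges = IRanges::IRanges(start = variants$pos, width = 1L)
  )
  wins <- GenomicRanges::GRanges(
    seqnames = GenomicRanges::seqnames(genes),
    ranges = IRanges::IRanges(
      start = pmax(1, genes$tss - window),
      end = genes$tss + window
    )
  )
  hits <- GenomicRanges::findOverlaps(vgr, wins, ignore.strand = TRUE)
  vi <- S4Vectors::queryHits(hits)
  gi <- S4Vectors::subjectHits(hits)
  d <- variants$pos[vi] - genes$tss[gi]
  minus <- as.character(GenomicRanges::strand(genes))[gi] == "-"
  d[minus] <- -d[minus]
  out <- data.frame(
    variant_id = variants$variant_id[vi],
    gene_id = genes$gene_id[gi],
    tss_distance = d,
    stringsAsFactors = FALSE
  )
  out[order(out$gene_id, out$variant_id), , drop = FALSE]
}

#' Covariate-adjusted linear association for one variant-gene pair
#'
#' Ordinary least squares of the (inverse-normal transformed) expression
#' vector on intercept, dosage and covariates; returns the dosage
#' coefficient with its standard error, t statistic and two-sided p from
#' the t distribution at the residual degrees of freedom. Missing dosages
#' are mean-imputed; collinear covariate columns are dropped with a
#' warning. A zero-variance dosage or expression vector yields a flagged
#' record with missing statistics; a perfect fit reports p at the
#' smallest positive representable value with a degeneracy flag, never 0.
#'
#' @param y expression vector.
#' @param x dosage vector.
#' @param covariates samples x covariates matrix or NULL.
#' @return one-row data.frame: beta, se, statistic, p, n, df, flag.
#' @examples
#' fitAssociation(c(1, 2, 4), c(0, 1, 2)) # beta 1.5
#' @export
fitAssociation <- function(y, x, covariates = NULL) {
  stopifnot(length(y) == length(x))
  if (anyNA(x)) x[is.na(x)] <- mean(x, na.rm = TRUE)
  ok <- !is.na(y)
  y <- y[ok]
  x <- x[ok]
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)[ok, , drop = FALSE]
  }
  n <- length(y)
  rec <- function(beta, se, stat, p, df, flag) {
    data.frame(
      beta = beta, se = se, statistic = stat, p = p, n = n, df = df,
      flag = flag, stringsAsFactors = FALSE
    )
  }
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    return(rec(NA_real_, NA_real_, NA_real_, NA_real_, NA_integer_,
      "degenerate"))
  }
  design <- cbind(intercept = 1, dosage = x, covariates)
  qrD <- qr(design)
  if (qrD$rank < ncol(design)) {
    keep <- qrD$pivot[seq_len(qrD$rank)]
    if (!2L %in% keep) {
      return(rec(NA_real_, NA_real_, NA_real_, NA_real_, NA_integer_,
        "degenerate"))
    }
    warning("dropping ", ncol(design) - qrD$rank,
      " collinear covariate column(s)",
      call. = FALSE
    )
    design <- design[, sort(keep), drop = FALSE]
    qrD <- qr(design)
  }
  p_pred <- ncol(design)
  df <- n - p_pred
  if (df < 1L) stop("not enough samples for the model", call. = FALSE)
  coefs <- qr.coef(qrD, y)
  res <- y - design %*% coefs
  rss <- sum(res^2)
  xtxInv <- chol2inv(qr.R(qrD))
  j <- which(colnames(design) == "dosage")
  beta <- unname(coefs[j])
  if (rss <= 1e-12 * sum(y^2)) {
    return(rec(beta, 0, Inf, .Machine$double.xmin, df, "perfect_fit"))
  }
  sigma2 <- rss / df
  se <- sqrt(sigma2 * xtxInv[j, j])
  tval <- beta / se
  pval <- 2 * stats::pt(-abs(tval), df)
  rec(beta, se, tval, pval, df, NA_character_)
}

#' Map all cis pairs in one cohort
#'
#' Fits the covariate-adjusted linear model for every enumerated pair.
#' Uses the residualization fast path: expression and dosages are
#' residualized on the covariates once, then each pair reduces to a
#' simple regression whose degrees of freedom are corrected for the
#' covariate count -- numerically identical to direct multiple
#' regression. Genes with per-gene covariates fall back to the direct
#' fit. Pairs referencing variants or genes absent from the matrices are
#' skipped with a message.
#'
#' @param expr genes x samples matrix, inverse-normal transformed.
#' @param genotypes a [GenotypeData-class] (samples aligned to `expr`
#'   columns).
#' @param covariates samples x covariates matrix or NULL.
#' @param pairs data.frame from [cisPairs()].
#' @param perGeneCovariates optional named list (gene_id -> samples x
#'   covariates matrix) of gene-specific covariates.
#' @return data.frame with variant_id, gene_id, tss_distance, beta, se,
#'   statistic, p, n, df, flag -- one row per mapped pair.
#' @export
mapCohort <- function(expr, genotypes, covariates = NULL, pairs,
                      perGeneCovariates = NULL) {
  stopifnot(methods::is(genotypes, "GenotypeData"))
  dos <- imputeMissingDosage(dosages(genotypes))
  stopifnot(ncol(expr) == ncol(dos))
  n <- ncol(expr)
  keep <- pairs$variant_id %in% rownames(dos) &
    pairs$gene_id %in% rownames(expr)
  if (any(!keep)) {
    message(sum(!keep), " pair(s) reference filtered-out variants/genes; skipped")
    pairs <- pairs[keep, , drop = FALSE]
  }
  if (!nrow(pairs)) {
    return(cbind(pairs, data.frame(
      beta = numeric(), se = numeric(), statistic = numeric(),
      p = numeric(), n = integer(), df = integer(), flag = character(),
      stringsAsFactors = FALSE
    )))
  }
  design <- cbind(intercept = rep(1, n), covariates)
  qrD <- qr(design)
  q <- qr.Q(qrD)[, seq_len(qrD$rank), drop = FALSE]
  nCov <- qrD$rank # includes the intercept
  df <- n - nCov - 1L
  if (df < 1L) stop("not enough samples for the model", call. = FALSE)
  slowGenes <- intersect(names(perGeneCovariates %||% list()), pairs$gene_id)
  fast <- !(pairs$gene_id %in% slowGenes)

  out <- data.frame(
    pairs,
    beta = NA_real_, se = NA_real_, statistic = NA_real_, p = NA_real_,
    n = n, df = df, flag = NA_character_, stringsAsFactors = FALSE
  )
  if (any(fast)) {
    gidx <- match(pairs$gene_id[fast], rownames(expr))
    vidx <- match(pairs$variant_id[fast], rownames(dos))
    eR <- expr - (expr %*% q) %*% t(q)
    dR <- dos - (dos %*% q) %*% t(q)
    syy <- rowSums(eR^2)
    sxx <- rowSums(dR^2)
    sxy <- rowSums(eR[gidx, , drop = FALSE] * dR[vidx, , drop = FALSE])
    degX <- sxx[vidx] <= 1e-12
    degY <- syy[gidx] <= 1e-12
    beta <- ifelse(degX, NA_real_, sxy / sxx[vidx])
    r2 <- ifelse(degX | degY, NA_real_,
      sxy^2 / (sxx[vidx] * syy[gidx])
    )
    r2 <- pmin(r2, 1)
    tval <- sign(beta) * sqrt(df * r2 / pmax(1 - r2, 0))
    se <- sqrt(pmax(syy[gidx] * (1 - r2), 0) / df / sxx[vidx])
    pval <- 2 * stats::pt(-abs(tval), df)
    flag <- rep(NA_character_, sum(fast))
    flag[degX | degY] <- "degenerate"
    perfect <- is.finite(r2) & (1 - r2) <= 1e-12
    flag[perfect] <- "perfect_fit"
    pval[perfect] <- .Machine$double.xmin
    se[perfect] <- 0
    out$beta[fast] <- beta
    out$se[fast] <- se
    out$statistic[fast] <- tval
    out$p[fast] <- pval
    out$flag[fast] <- flag
    out$statistic[fast][degX | degY] <- NA_real_
    out$p[fast][degX | degY] <- NA_real_
  }
  if (any(!fast)) {
    for (i in which(!fast)) {
      g <- pairs$gene_id[i]
      fit <- fitAssociation(
        expr[g, ], dos[pairs$variant_id[i], ],
        cbind(covariates, perGeneCovariates[[g]])
      )
      out[i, c("beta", "se", "statistic", "p", "n", "df", "flag")] <-
        fit[, c("beta", "se", "statistic", "p", "n", "df", "flag")]
    }
  }
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values via [stats::p.adjust()], after validating the
#' input range. The adjustment pool is global: all tested pairs in a run
#' enter one family.
#'
#' @param p numeric vector of p-values in [0, 1] (NA allowed).
#' @return adjusted values, same length.
#' @export
bhAdjust <- function(p) {
  if (!length(p)) {
    return(numeric(0))
  }
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}
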