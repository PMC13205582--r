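# Regulatory enrichment of lead eQTLs against MAF- and TSS-distance-
# matched non-eQTL controls, plus generic gene-set over-representation.

#' Select the lead eQTL per gene
#'
#' Per gene, picks the pair with minimum FDR; ties are broken by minimum
#' raw p, then maximum |beta_meta|, then lexicographically smallest
#' variant id, so the selection is fully deterministic.
#'
#' @param assoc meta-eQTL data.frame with gene_id, variant_id, fdr, p and
#'   beta_meta columns.
#' @return one row per gene (the lead pair), same columns.
#' @export
leadVariants <- function(assoc) {
  stopifnot(all(c("gene_id", "variant_id", "fdr") %in% colnames(assoc)))
  betaCol <- if ("beta_meta" %in% colnames(assoc)) "beta_meta" else "beta"
  ord <- order(
    assoc$gene_id, assoc$fdr, assoc$p, -abs(assoc[[betaCol]]),
    assoc$variant_id
  )
  sorted <- assoc[ord, , drop = FALSE]
  out <- sorted[!duplicated(sorted$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# bin index for values given strictly increasing edges; values at the top
# edge fall in the last bin
binIndex <- function(x, edges) {
  i <- findInterval(x, edges, rightmost.closed = TRUE)
  pmin(pmax(i, 1L), length(edges) - 1L)
}

#' Match specification for the non-eQTL control draw
#'
#' Defaults: MAF bin edges at the deciles of the pooled lead-plus-pool
#' MAF distribution (supplied at draw time when NULL), and |TSS distance|
#' bins at 0, 1 kb, 10 kb, 100 kb and 1 Mb (log-decade edges, extended if
#' the pool exceeds 1 Mb).
#'
#' @param mafBins strictly increasing MAF bin edges, or NULL for pooled
#'   deciles.
#' @param distanceBins strictly increasing |TSS distance| bin edges.
#' @param seed RNG seed for the draw.
#' @return named list understood by [sampleMatchedControls()].
#' @export
matchSpec <- function(mafBins = NULL,
                      distanceBins = c(0, 1e3, 1e4, 1e5, 1e6),
                      seed = 1L) {
  if (!is.null(mafBins)) stopifnot(all(diff(mafBins) > 0))
  stopifnot(all(diff(distanceBins) > 0))
  list(mafBins = mafBins, distanceBins = distanceBins, seed = seed)
}

#' Sample MAF- and distance-matched non-eQTL controls
#'
#' For each lead eQTL, draws one control variant without replacement from
#' the same (MAF bin x |TSS distance| bin) cell of the non-significant
#' pool. When a cell is exhausted, the draw borrows from the nearest cell
#' by Manhattan distance on bin indices (ties resolved toward the lower
#' MAF bin first), and each borrow is logged. The control set always has
#' exactly one entry per lead and is reproducible given the seed.
#'
#' @param leads data.frame with variant_id, maf and tss_distance (or
#'   abs_distance) for the lead set.
#' @param pool data.frame with the same columns for the candidate
#'   controls (callers must restrict it to FDR >= 0.05 rows; if an `fdr`
#'   column is present this is enforced here).
#' @param spec a [matchSpec()] list.
#' @return data.frame of selected controls (rows of `pool`), with the
#'   borrow log attached as attribute `"borrows"`.
#' @export
sampleMatchedControls <- function(leads, pool, spec = matchSpec()) {
  absDist <- function(df) {
    if ("abs_distance" %in% colnames(df)) {
      abs(df$abs_distance)
    } else {
      abs(df$tss_distance)
    }
  }
  if ("fdr" %in% colnames(pool)) {
    pool <- pool[pool$fdr >= 0.05, , drop = FALSE]
  }
  if (nrow(pool) < nrow(leads)) {
    stop("control pool (", nrow(pool), ") smaller than lead set (",
      nrow(leads), ")",
      call. = FALSE
    )
  }
  mafAll <- c(leads$maf, pool$maf)
  mafBins <- spec$mafBins %||% {
    e <- unique(stats::quantile(mafAll, probs = seq(0, 1, 0.1), names = FALSE))
    if (length(e) < 2L) e <- range(mafAll) + c(-1e-9, 1e-9)
    e
  }
  distBins <- spec$distanceBins
  dAll <- c(absDist(leads), absDist(pool))
  if (max(dAll) > max(distBins)) distBins <- c(distBins, max(dAll))
  lm_ <- binIndex(leads$maf, mafBins)
  ld_ <- binIndex(absDist(leads), distBins)
  pm_ <- binIndex(pool$maf, mafBins)
  pd_ <- binIndex(absDist(pool), distBins)
  available <- rep(TRUE, nrow(pool))
  chosen <- integer(nrow(leads))
  borrows <- list()
  withSubstream(spec$seed, "matched-controls", {
    # pre-shuffled per-cell queues make in-cell draws uniform without
    # replacement in O(pool) total; the borrow path is a rare full scan
    cellKey <- paste(pm_, pd_, sep = "_")
    queues <- lapply(split(seq_len(nrow(pool)), cellKey), sample)
    cursor <- stats::setNames(rep(1L, length(queues)), names(queues))
    for (i in seq_len(nrow(leads))) {
      key <- paste(lm_[i], ld_[i], sep = "_")
      pick <- NA_integer_
      qi <- queues[[key]]
      if (!is.null(qi)) {
        while (cursor[[key]] <= length(qi)) {
          cand <- qi[cursor[[key]]]
          cursor[[key]] <- cursor[[key]] + 1L
          if (available[cand]) {
            pick <- cand
            break
          }
        }
      }
      if (is.na(pick)) {
        avail <- which(available)
        dist <- abs(pm_[avail] - lm_[i]) + abs(pd_[avail] - ld_[i])
        best <- min(dist)
        tied <- avail[dist == best]
        # prefer the lower MAF bin among equally distant cells
        tied <- tied[order(pm_[tied], pd_[tied])]
        cand <- tied[pm_[tied] == pm_[tied][1L] & pd_[tied] == pd_[tied][1L]]
        borrows[[length(borrows) + 1L]] <- data.frame(
          lead = leads$variant_id[i],
          from_maf_bin = lm_[i], from_dist_bin = ld_[i],
          to_maf_bin = pm_[cand[1L]], to_dist_bin = pd_[cand[1L]]
        )
        pick <- cand[sample.int(length(cand), 1L)]
      }
      chosen[i] <- pick
      available[pick] <- FALSE
    }
  })
  out <- pool[chosen, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "borrows") <- if (length(borrows)) {
    do.call(rbind, borrows)
  } else {
    NULL
  }
  out
}

#' Overlap variants with an interval track
#'
#' A variant at 1-based position `pos` overlaps a BED interval
#' [start, end) (0-based half-open) when pos - 1 falls inside it; on the
#' 1-based closed coordinates used by GRanges this is an ordinary
#' single-position overlap.
#'
#' @param variants variant DataFrame/data.frame with chrom and pos, or a
#'   [GenotypeData-class].
#' @param track GRanges interval track (e.g. from [readBedTrack()]).
#' @return logical vector, one entry per variant.
#' @export
annotateOverlap <- function(variants, track) {
  if (methods::is(variants, "GenotypeData")) variants <- variantInfo(variants)
  if (!nrow(variants)) {
    return(logical(0))
  }
  if (!length(track)) {
    return(rep(FALSE, nrow(variants)))
  }
  vgr <- GenomicRanges::GRanges(
    seqnames = variants$chrom,
    ranges = IRanges::IRanges(start = variants$pos, width = 1L)
  )
  IRanges::overlapsAny(vgr, track, ignore.strand = TRUE)
}

# OR and Woolf CI from a 2x2, Haldane-Anscombe 0.5 on all cells only when
# any cell is zero; the exact p is never corrected
orWithCI <- function(a, b, c, d, level = 0.95) {
  cc <- if (any(c(a, b, c, d) == 0)) 0.5 else 0
  a2 <- a + cc
  b2 <- b + cc
  c2 <- c + cc
  d2 <- d + cc
  orv <- (a2 * d2) / (b2 * c2)
  z <- stats::qnorm((1 + level) / 2)
  selog <- sqrt(1 / a2 + 1 / b2 + 1 / c2 + 1 / d2)
  c(
    or_value = orv,
    ci_low = exp(log(orv) - z * selog),
    ci_high = exp(log(orv) + z * selog)
  )
}

#' Fisher enrichment of overlap in a query set versus a control set
#'
#' Builds the 2x2 table (query-overlap, query-non-overlap,
#' control-overlap, control-non-overlap), computes the two-sided exact p
#' by the minimum-likelihood rule (sum of hypergeometric probabilities of
#' tables no more likely than the observed one), and the sample odds
#' ratio (a*d)/(b*c) with a Woolf log-scale confidence interval. The
#' Haldane-Anscombe 0.5 correction is applied to all cells -- for the OR
#' and CI only -- when any cell is zero.
#'
#' @param queryOverlap logical vector for the query (lead eQTL) set.
#' @param controlOverlap logical vector for the matched control set.
#' @param category annotation label carried into the record.
#' @return one-row data.frame: category, a, b, c, d, or_value, ci_low,
#'   ci_high, p.
#' @export
fisherEnrichment <- function(queryOverlap, controlOverlap,
                             category = "annotation") {
  stopifnot(length(queryOverlap) > 0L, length(controlOverlap) > 0L)
  a <- sum(queryOverlap)
  b <- sum(!queryOverlap)
  c <- sum(controlOverlap)
  d <- sum(!controlOverlap)
  p <- stats::fisher.test(matrix(c(a, b, c, d), nrow = 2L, byrow = TRUE))$p.value
  orci <- orWithCI(a, b, c, d)
  data.frame(
    category = category, a = a, b = b, c = c, d = d,
    or_value = unname(orci["or_value"]),
    ci_low = unname(orci["ci_low"]),
    ci_high = unname(orci["ci_high"]),
    p = p, stringsAsFactors = FALSE
  )
}

#' Adjust enrichment p-values by annotation family
#'
#' Functional-category and histone-mark families use Benjamini-Hochberg;
#' transcription-factor and RNA-binding-protein families use Bonferroni
#' (min(1, m * p)).
#'
#' @param records data.frame of enrichment records with a `p` column.
#' @param family one of "functional_categories", "histone_marks", "tf",
#'   "rbp".
#' @return the records with p_adj and adjust_method columns added.
#' @export
adjustCategories <- function(records, family) {
  method <- switch(family,
    functional_categories = ,
    histone_marks = "BH",
    tf = ,
    rbp = "bonferroni",
    stop("unknown annotation family: ", family, call. = FALSE)
  )
  records$p_adj <- stats::p.adjust(records$p, method = method)
  records$adjust_method <- if (method == "BH") "BH" else "bonferroni"
  records
}

#' Gene-set over-representation test
#'
#' Upper hypergeometric tail of the query/set overlap given the
#' background: p = P(X >= overlap) with X hypergeometric on
#' (|set in background|, |background \\ set|, |query|). Also reports the
#' sample odds ratio of the induced 2x2 (Haldane-corrected when a cell is
#' zero).
#'
#' @param queryGenes character vector, a subset of `background`.
#' @param geneSet character vector (intersected with the background).
#' @param background character vector of all testable genes.
#' @return one-row data.frame: category, a, b, c, d, or_value, ci_low,
#'   ci_high, p.
#' @examples
#' genesetEnrichment(paste0("g", 1:4), paste0("g", 1:5), paste0("g", 1:10))
#' @export
genesetEnrichment <- function(queryGenes, geneSet, background) {
  queryGenes <- unique(queryGenes)
  background <- unique(background)
  geneSet <- intersect(unique(geneSet), background)
  if (!length(queryGenes)) stop("empty query set", call. = FALSE)
  if (!all(queryGenes %in% background)) {
    stop("query genes must be a subset of the background", call. = FALSE)
  }
  if (!length(geneSet)) {
    stop("gene set does not intersect the background", call. = FALSE)
  }
  N <- length(background)
  m <- length(geneSet)
  k <- length(queryGenes)
  ov <- length(intersect(queryGenes, geneSet))
  p <- stats::phyper(ov - 1L, m, N - m, k, lower.tail = FALSE)
  a <- ov
  b <- k - ov
  c <- m - ov
  d <- N - m - b
  orci <- orWithCI(a, b, c, d)
  data.frame(
    category = "gene_set", a = a, b = b, c = c, d = d,
    or_value = unname(orci["or_value"]),
    ci_low = unname(orci["ci_low"]),
    ci_high = unname(orci["ci_high"]),
    p = p, stringsAsFactors = FALSE
  )
}
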