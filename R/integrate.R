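# GWAS-eQTL intersection, report summaries, and the end-to-end pipeline
# over a simulated (or fixture-backed) study.

#' Intersect GWAS and eQTL evidence into candidate variant-gene pairs
#'
#' Inner-joins the GWAS meta-analysis and the eQTL meta-analysis on the
#' variant id, then keeps pairs with GWAS meta p below `p_meta_max`,
#' nominal association in each cohort (p below `p_cohort_max`), and eQTL
#' FDR below `fdr_max`. The direction note relates the GWAS effect
#' allele to the expression effect: for a protective allele (negative
#' log OR) with a positive expression beta it reads
#' "protective_allele_increases_expression", and so on.
#'
#' @param gwasMeta GWAS meta data.frame (variant_id, beta_meta or beta,
#'   p).
#' @param gwasCohorts named list of per-cohort GWAS tables (variant_id,
#'   beta, p, optionally converged).
#' @param eqtlMeta eQTL meta data.frame (variant_id, gene_id, fdr,
#'   beta_meta, i2, het_flag, p).
#' @param p_meta_max,p_cohort_max,fdr_max thresholds (defaults 1e-5,
#'   0.05, 0.05).
#' @param requireConcordant require a shared GWAS effect sign across
#'   cohorts.
#' @param loci optional locus assignments from [defineLoci()] to carry a
#'   locus_id onto each record.
#' @param reportUnmatched also return GWAS-selected variants absent from
#'   the eQTL table.
#' @return data.frame of candidate records (variant_id, gene_id,
#'   p_meta_gwas, per-cohort p columns, eqtl_fdr, eqtl_beta_meta,
#'   eqtl_i2, het_flag, locus_id, direction_note), with summary counts in
#'   attribute `"counts"` and, if requested, unmatched variants in
#'   attribute `"unmatched"`.
#' @export
integrateEvidence <- function(gwasMeta, gwasCohorts, eqtlMeta,
                              p_meta_max = 1e-5, p_cohort_max = 0.05,
                              fdr_max = 0.05, requireConcordant = TRUE,
                              loci = NULL, reportUnmatched = FALSE) {
  sel <- selectSuggestive(gwasMeta, gwasCohorts,
    p_meta_max = p_meta_max, p_cohort_max = p_cohort_max,
    requireConcordant = requireConcordant
  )
  if (!nrow(sel) || !nrow(eqtlMeta)) {
    if (!length(intersect(sel$variant_id, eqtlMeta$variant_id))) {
      warning("no overlap between GWAS-selected and eQTL variant ids",
        call. = FALSE
      )
    }
  }
  eq <- eqtlMeta[eqtlMeta$fdr < fdr_max, , drop = FALSE]
  i <- match(eq$variant_id, sel$variant_id)
  joined <- eq[!is.na(i), , drop = FALSE]
  si <- i[!is.na(i)]
  gwasBeta <- if ("beta_meta" %in% colnames(sel)) {
    sel$beta_meta[si]
  } else {
    sel$beta[si]
  }
  pCols <- paste0("p_", names(gwasCohorts))
  pCols <- pCols[pCols %in% colnames(sel)]
  out <- data.frame(
    variant_id = joined$variant_id,
    gene_id = joined$gene_id,
    p_meta_gwas = sel$p[si],
    stringsAsFactors = FALSE
  )
  for (pc in pCols) out[[pc]] <- sel[[pc]][si]
  out$gwas_log_or <- gwasBeta
  out$eqtl_fdr <- joined$fdr
  out$eqtl_beta_meta <- joined$beta_meta
  out$eqtl_i2 <- joined$i2
  out$het_flag <- joined$het_flag
  out$locus_id <- rep(NA_character_, nrow(out))
  if (!is.null(loci) && nrow(out)) {
    li <- match(out$variant_id, loci$variant_id)
    out$locus_id <- loci$locus_id[li]
  }
  riskDir <- ifelse(gwasBeta < 0, "protective_allele", "risk_allele")
  exprDir <- ifelse(joined$beta_meta > 0, "increases_expression",
    "decreases_expression"
  )
  out$direction_note <- if (nrow(out)) {
    paste(riskDir, exprDir, sep = "_")
  } else {
    character(0)
  }
  rownames(out) <- NULL
  attr(out, "counts") <- c(
    gwas_selected = nrow(sel),
    candidate_pairs = nrow(out),
    unique_variants = length(unique(out$variant_id)),
    unique_genes = length(unique(out$gene_id)),
    unique_loci = length(unique(stats::na.omit(out$locus_id)))
  )
  if (reportUnmatched) {
    attr(out, "unmatched") <-
      setdiff(sel$variant_id, eqtlMeta$variant_id)
  }
  out
}

#' Emit report tables for a completed run
#'
#' Writes the figure-ready data tables: a Manhattan table (chrom, pos,
#' p), a quantile-quantile table of expected versus observed -log10 p
#' with the genomic inflation factor, a TSS-distance histogram for the
#' lead eQTLs, and a run manifest echoing thresholds, seed and the counts
#' at every filter. Deterministic given its inputs.
#'
#' @param dir output directory.
#' @param gwasMeta GWAS meta table with variant_id, p (positions taken
#'   from `variants`).
#' @param variants variant DataFrame/data.frame (variant_id, chrom, pos).
#' @param leads lead-eQTL table with tss_distance.
#' @param manifest named list of run metadata (thresholds, seed, counts).
#' @param breaks histogram bin edges for |TSS distance| in bp.
#' @return named vector of written paths, invisibly.
#' @export
reportBundle <- function(dir, gwasMeta, variants, leads,
                         manifest = list(),
                         breaks = c(0, 1e3, 1e4, 1e5, 2e5, 5e5, 1e6)) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c()
  vi <- match(gwasMeta$variant_id, variants$variant_id)
  man <- data.frame(
    variant_id = gwasMeta$variant_id,
    chrom = variants$chrom[vi],
    pos = variants$pos[vi],
    p = gwasMeta$p, stringsAsFactors = FALSE
  )
  p <- file.path(dir, "manhattan.tsv")
  writeTsv(man, p)
  paths["manhattan"] <- p
  pv <- sort(gwasMeta$p[!is.na(gwasMeta$p)])
  nqq <- length(pv)
  qq <- data.frame(
    expected = -log10((seq_len(nqq) - 0.5) / nqq),
    observed = -log10(pv)
  )
  lambda <- genomicLambda(pv)
  p <- file.path(dir, "qq.tsv")
  writeTsv(qq, p)
  paths["qq"] <- p
  d <- abs(leads$tss_distance)
  edges <- breaks
  if (length(d) && max(d) > max(edges)) edges <- c(edges, max(d))
  h <- hist(d, breaks = edges, plot = FALSE)
  p <- file.path(dir, "tss_distance_hist.tsv")
  writeTsv(data.frame(
    bin_start = h$breaks[-length(h$breaks)],
    bin_end = h$breaks[-1L],
    count = h$counts
  ), p)
  paths["tss_distance"] <- p
  p <- file.path(dir, "run_manifest.yaml")
  yaml::write_yaml(c(manifest, list(lambda_gwas = lambda)), p)
  paths["manifest"] <- p
  invisible(paths)
}

#' Default pipeline configuration
#'
#' Thresholds carry the standard defaults used throughout the package:
#' QC cut-offs (MAF >= 1%, missingness < 5%, HWE p > 1e-5, quality >=
#' 0.3, FPKM floor 0.1), a +/-1 Mb cis window, 5 ancestry PCs, hidden
#' expression factors (15, capped below the matrix rank), eQTL FDR 0.05,
#' GWAS suggestive threshold 1e-5 with per-cohort 0.05, heterogeneity
#' triage at I2 >= 75% / P_Het < 0.05, and 500 kb locus clumping.
#'
#' @param simulation a [simConfig()] for the synthetic study.
#' @param ... overrides for any threshold element.
#' @return named list.
#' @export
pipelineConfig <- function(simulation = simConfig(), ...) {
  cfg <- list(
    simulation = simulation,
    cis_window = 1e6,
    n_pcs = 5L,
    n_hidden_factors = 15L,
    qc = qcThresholds(),
    eqtl_fdr_max = 0.05,
    gwas_p_meta_max = 1e-5,
    gwas_p_cohort_max = 0.05,
    i2_min = 75,
    p_het_max = 0.05,
    locus_gap = 5e5,
    require_concordant = TRUE
  )
  utils::modifyList(cfg, list(...))
}

#' Run the full integrative pipeline on a synthetic study
#'
#' Executes simulate -> QC -> per-cohort cis-eQTL mapping -> eQTL
#' meta-analysis with BH FDR -> lead-eQTL enrichment against matched
#' controls -> per-cohort GWAS -> GWAS meta-analysis -> intersection ->
#' report bundle, writing each stage's table under `outDir` when given.
#' With `resume = TRUE`, stages whose output file already exists are
#' reloaded instead of recomputed.
#'
#' @param config list from [pipelineConfig()].
#' @param outDir output directory, or NULL to skip writing.
#' @param study optionally a pre-built [SimStudy-class] (skips
#'   simulation).
#' @param resume reuse existing stage outputs in `outDir`.
#' @return list with study, qc, eqtl (per-cohort, meta, leads),
#'   enrichment, gwas (per-cohort, meta, loci), candidates, and paths of
#'   written files.
#' @export
runPipeline <- function(config = pipelineConfig(), outDir = NULL,
                        study = NULL, resume = FALSE) {
  stageFile <- function(name) {
    if (is.null(outDir)) NULL else file.path(outDir, name)
  }
  emit <- function(df, name) {
    f <- stageFile(name)
    if (!is.null(f)) writeTsv(df, f)
    df
  }
  if (!is.null(outDir) && !dir.exists(outDir)) {
    dir.create(outDir, recursive = TRUE)
  }
  simCfg <- config$simulation
  if (is.null(study)) study <- simulateStudy(simCfg, cisWindow = config$cis_window)
  genes <- geneModels(study)

  perCohort <- list()
  gwasTables <- list()
  for (cid in cohortNames(study)) {
    ch <- cohort(study, cid)
    qc <- variantQC(ch$genotypes, config$qc)
    emit(qc$report, sprintf("%s.qc_report.tsv", cid))
    gt <- qc$genotypes
    fpkm <- filterGenesByExpression(ch$fpkm, config$qc$fpkm_mean_min)
    exprInt <- intByGene(fpkm)
    nPcs <- min(config$n_pcs, ncol(dosages(gt)) - 2L, nrow(dosages(gt)) - 1L)
    pcs <- ancestryPCs(gt, k = max(nPcs, 0L))
    known <- cbind(age = ch$phenotype$age, sex = ch$phenotype$sex)
    kFac <- min(config$n_hidden_factors, min(dim(exprInt)) - 1L)
    fac <- hiddenFactors(exprInt, cbind(known, pcs), k = max(kFac, 0L))
    covs <- buildCovariates(known = known, pcs = pcs, factors = fac)
    assocFile <- stageFile(sprintf("%s.eqtl.tsv", cid))
    if (resume && !is.null(assocFile) && file.exists(assocFile)) {
      assoc <- readTsv(assocFile)
    } else {
      pairs <- cisPairs(gt, genes, window = config$cis_window)
      assoc <- mapCohort(exprInt, gt, covs, pairs)
      emit(assoc, sprintf("%s.eqtl.tsv", cid))
    }
    perCohort[[cid]] <- list(
      genotypes = gt, qc = qc$report, covariates = covs,
      assoc = assoc, expr = exprInt
    )
    gwasFile <- stageFile(sprintf("%s.gwas.tsv", cid))
    if (resume && !is.null(gwasFile) && file.exists(gwasFile)) {
      gw <- readTsv(gwasFile)
      gw$converged <- as.logical(gw$converged)
    } else {
      gwasCovs <- buildCovariates(
        known = known,
        pcs = pcs[, seq_len(min(3L, ncol(pcs))), drop = FALSE]
      )
      gw <- gwasScan(gt, ch$phenotype, gwasCovs)
      emit(gw, sprintf("%s.gwas.tsv", cid))
    }
    gwasTables[[cid]] <- gw
  }

  eqtlMeta <- metaAnalyzePairs(
    lapply(perCohort, `[[`, "assoc"),
    by = c("variant_id", "gene_id"),
    i2_min = config$i2_min, p_het_max = config$p_het_max
  )
  eqtlMeta$fdr <- bhAdjust(eqtlMeta$p)
  emit(eqtlMeta, "eqtl_meta.tsv")

  leads <- leadVariants(eqtlMeta[eqtlMeta$fdr < config$eqtl_fdr_max, ,
    drop = FALSE
  ])
  enrichment <- NULL
  vTab <- as.data.frame(variantInfo(cohort(study, cohortNames(study)[1L])$genotypes))
  if (nrow(leads)) {
    mafMap <- stats::setNames(vTab$maf, vTab$variant_id)
    leads$maf <- mafMap[leads$variant_id]
    pool <- eqtlMeta[eqtlMeta$fdr >= 0.05, , drop = FALSE]
    pool$maf <- mafMap[pool$variant_id]
    pool <- pool[!duplicated(pool$variant_id) &
      !pool$variant_id %in% leads$variant_id, , drop = FALSE]
    if (nrow(pool) >= nrow(leads)) {
      controls <- sampleMatchedControls(
        leads, pool,
        matchSpec(seed = simCfg@seed)
      )
      track <- annotationTrack(study)
      qOv <- annotateOverlap(vTab[match(leads$variant_id, vTab$variant_id), ], track)
      cOv <- annotateOverlap(vTab[match(controls$variant_id, vTab$variant_id), ], track)
      enrichment <- fisherEnrichment(qOv, cOv, category = "interval_track")
      enrichment <- adjustCategories(enrichment, "histone_marks")
      emit(enrichment, "enrichment.tsv")
    }
  }

  gwasMeta <- metaAnalyzePairs(gwasTables,
    by = "variant_id",
    i2_min = config$i2_min, p_het_max = config$p_het_max
  )
  emit(gwasMeta, "gwas_meta.tsv")
  sel <- selectSuggestive(gwasMeta, gwasTables,
    p_meta_max = config$gwas_p_meta_max,
    p_cohort_max = config$gwas_p_cohort_max,
    requireConcordant = config$require_concordant
  )
  selPos <- cbind(sel,
    chrom = vTab$chrom[match(sel$variant_id, vTab$variant_id)],
    pos = vTab$pos[match(sel$variant_id, vTab$variant_id)]
  )
  loci <- defineLoci(selPos, gap = config$locus_gap)
  if (nrow(loci$loci)) emit(loci$loci, "loci.tsv")

  candidates <- integrateEvidence(
    gwasMeta, gwasTables, eqtlMeta,
    p_meta_max = config$gwas_p_meta_max,
    p_cohort_max = config$gwas_p_cohort_max,
    fdr_max = config$eqtl_fdr_max,
    requireConcordant = config$require_concordant,
    loci = if (nrow(loci$assignments)) loci$assignments else NULL
  )
  emit(candidates, "candidates.tsv")

  paths <- NULL
  if (!is.null(outDir)) {
    paths <- reportBundle(
      outDir, gwasMeta, vTab, leads,
      manifest = list(
        seed = simCfg@seed,
        thresholds = list(
          eqtl_fdr_max = config$eqtl_fdr_max,
          gwas_p_meta_max = config$gwas_p_meta_max,
          gwas_p_cohort_max = config$gwas_p_cohort_max
        ),
        counts = list(
          variants_post_qc = nrow(perCohort[[1L]]$assoc %||% data.frame()),
          eqtl_pairs_tested = nrow(eqtlMeta),
          egenes = length(unique(leads$gene_id)),
          gwas_selected = nrow(sel),
          candidate_pairs = nrow(candidates)
        )
      )
    )
  }

  list(
    study = study, cohorts = perCohort, eqtl_meta = eqtlMeta,
    leads = leads, enrichment = enrichment, gwas_cohorts = gwasTables,
    gwas_meta = gwasMeta, gwas_selected = sel, loci = loci,
    candidates = candidates, paths = paths
  )
}
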