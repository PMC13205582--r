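# Fixture serialization: dosage VCF, TSV tables, BED tracks, manifest.
# Writers are deterministic (fixed number formatting, no timestamps) so a
# fixed-seed run reproduces byte-identical files.

formatDosage <- function(x) {
  ifelse(is.na(x), ".", sprintf("%.6f", x))
}

#' Write genotype dosages as a VCF 4.2 file with a DS FORMAT field
#'
#' Emits one record per variant with the dosage carried in the `DS`
#' (expected alternative-allele count) genotype field, the target MAF and
#' the imputation-quality analog in INFO. An empty panel yields a valid
#' header-only file.
#'
#' @param genotypes a [GenotypeData-class].
#' @param path output file path.
#' @param chromLength contig length written to the header.
#' @return the path, invisibly.
#' @seealso [readDosageVCF()]
#' @export
writeDosageVCF <- function(genotypes, path, chromLength = NULL) {
  v <- variantInfo(genotypes)
  dos <- dosages(genotypes)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf(
      "##contig=<ID=chr1%s>",
      if (is.null(chromLength)) "" else sprintf(",length=%d", as.integer(chromLength))
    ),
    "##INFO=<ID=MAF,Number=1,Type=Float,Description=\"Target minor allele frequency\">",
    "##INFO=<ID=IQS,Number=1,Type=Float,Description=\"Imputation quality score analog\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Expected alternative allele dosage\">",
    paste(c(
      "#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
      "FORMAT", colnames(dos)
    ), collapse = "\t")
  ), con)
  if (nrow(v)) {
    info <- sprintf("MAF=%.6f;IQS=%.4f", v$maf, v$quality_score)
    body <- vapply(seq_len(nrow(v)), function(i) {
      paste(c(
        v$chrom[i], v$pos[i], v$variant_id[i], v$ref[i], v$alt[i],
        ".", "PASS", info[i], "DS", formatDosage(dos[i, ])
      ), collapse = "\t")
    }, character(1L))
    writeLines(body, con)
  }
  invisible(path)
}

#' Read a dosage VCF back into a GenotypeData object
#'
#' Parses the file with [vcfR::read.vcfR()] and extracts the `DS` genotype
#' field plus the MAF/IQS INFO keys written by [writeDosageVCF()].
#'
#' @param path VCF file path.
#' @param cohortId cohort label for the resulting object.
#' @return A [GenotypeData-class].
#' @export
readDosageVCF <- function(path, cohortId = "cohort") {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  ds <- vcfR::extract.gt(vcf, element = "DS")
  dos <- matrix(suppressWarnings(as.numeric(ds)),
    nrow = nrow(ds),
    dimnames = dimnames(ds)
  )
  getInfo <- function(key) {
    as.numeric(sub(
      sprintf(".*%s=([^;]+).*", key), "\\1",
      fix$INFO
    ))
  }
  variants <- S4Vectors::DataFrame(
    variant_id = fix$ID,
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT,
    maf = getInfo("MAF"),
    quality_score = getInfo("IQS")
  )
  rownames(dos) <- variants$variant_id
  methods::new("GenotypeData",
    dosage = dos, variants = variants,
    cohortId = cohortId
  )
}

#' Read a BED interval track
#'
#' Validates that every interval has start < end (0-based half-open
#' convention) before importing via [rtracklayer::import()]; a malformed
#' line is reported with its line number.
#'
#' @param path BED file path.
#' @return A [GenomicRanges::GRanges] (1-based closed coordinates).
#' @export
readBedTrack <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  dataLines <- which(!grepl("^(track|browser|#)", lines) & nzchar(lines))
  for (i in dataLines) {
    f <- strsplit(lines[i], "\t")[[1L]]
    if (length(f) >= 3L) {
      s <- suppressWarnings(as.numeric(f[2L]))
      e <- suppressWarnings(as.numeric(f[3L]))
      if (!is.na(s) && !is.na(e) && s >= e) {
        stop("malformed BED interval (start >= end) at line ", i,
          call. = FALSE
        )
      }
    }
  }
  rtracklayer::import(path, format = "BED")
}

#' Write a complete fixture set for a simulated study
#'
#' Emits, per cohort, a dosage VCF, expression and phenotype/covariate
#' TSVs; plus shared gene-model, annotation (BED + category TSV) and
#' ground-truth tables, and a manifest echoing the seed and parameters.
#' All files round-trip losslessly (dosages to 6 decimals) through the
#' package readers, and a fixed seed reproduces byte-identical files.
#'
#' @param study a [SimStudy-class].
#' @param dir output directory (created if needed).
#' @return named character vector of written paths, invisibly.
#' @seealso [readFixtureSet()]
#' @export
writeFixtureSet <- function(study, dir) {
  stopifnot(methods::is(study, "SimStudy"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (file.access(dir, 2L) != 0L) {
    stop("directory not writable: ", dir, call. = FALSE)
  }
  cfg <- study@config
  paths <- c()
  for (cid in cohortNames(study)) {
    ch <- cohort(study, cid)
    p <- file.path(dir, sprintf("%s.genotypes.vcf", cid))
    writeDosageVCF(ch$genotypes, p, chromLength = cfg@chromLength)
    paths[sprintf("%s_vcf", cid)] <- p
    p <- file.path(dir, sprintf("%s.expression.tsv", cid))
    expr <- data.frame(
      gene_id = rownames(ch$fpkm),
      signif(ch$fpkm, 7L),
      check.names = FALSE, stringsAsFactors = FALSE
    )
    writeTsv(expr, p)
    paths[sprintf("%s_expression", cid)] <- p
    p <- file.path(dir, sprintf("%s.phenotype.tsv", cid))
    writeTsv(ch$phenotype, p)
    paths[sprintf("%s_phenotype", cid)] <- p
  }
  genes <- study@genes
  p <- file.path(dir, "gene_models.tsv")
  writeTsv(data.frame(
    gene_id = genes$gene_id,
    chrom = as.character(GenomicRanges::seqnames(genes)),
    strand = as.character(GenomicRanges::strand(genes)),
    start = GenomicRanges::start(genes),
    end = GenomicRanges::end(genes),
    tss = genes$tss, stringsAsFactors = FALSE
  ), p)
  paths["gene_models"] <- p
  p <- file.path(dir, "annotations.bed")
  tr <- annotationTrack(study)
  bed <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(tr)),
    start = GenomicRanges::start(tr) - 1L,
    end = GenomicRanges::end(tr)
  )
  utils::write.table(bed, p,
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE
  )
  paths["annotations"] <- p
  p <- file.path(dir, "variant_categories.tsv")
  writeTsv(variantCategories(study), p)
  paths["categories"] <- p
  p <- file.path(dir, "truth_causal_pairs.tsv")
  writeTsv(causalPairs(study), p)
  paths["truth_pairs"] <- p
  p <- file.path(dir, "truth_risk_variants.tsv")
  writeTsv(riskVariants(study), p)
  paths["truth_risk"] <- p
  p <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(list(
    seed = cfg@seed,
    cohorts = as.list(cfg@nSamples),
    n_variants = cfg@nVariants,
    n_genes = cfg@nGenes,
    maf_range = cfg@mafRange,
    ld_block_size = cfg@ldBlockSize,
    ld_rho = cfg@ldRho,
    n_causal_pairs = cfg@nCausalPairs,
    beta_causal = cfg@betaCausal,
    n_hidden_factors = cfg@nHiddenFactors,
    factor_sd = cfg@factorSd,
    noise_sd = cfg@noiseSd,
    n_risk_variants = cfg@nRiskVariants,
    risk_or = cfg@riskOR,
    case_fraction = cfg@caseFraction,
    chrom_length = cfg@chromLength,
    missing_rate = cfg@missingRate
  ), p)
  paths["manifest"] <- p
  invisible(paths)
}

#' Read a fixture set written by [writeFixtureSet()]
#'
#' @param dir directory containing the fixture files.
#' @param cohorts cohort ids to read; default: inferred from the manifest.
#' @return list with `cohorts` (each: genotypes, fpkm, phenotype), `genes`
#'   (GRanges), `annotations` (track + categories), `truth` (data.frames),
#'   `manifest`.
#' @export
readFixtureSet <- function(dir, cohorts = NULL) {
  manifest <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  if (is.null(cohorts)) cohorts <- names(manifest$cohorts)
  gm <- readTsv(file.path(dir, "gene_models.tsv"))
  genes <- GenomicRanges::GRanges(
    seqnames = gm$chrom,
    ranges = IRanges::IRanges(start = gm$start, end = gm$end),
    strand = gm$strand
  )
  genes$gene_id <- gm$gene_id
  genes$tss <- gm$tss
  names(genes) <- gm$gene_id
  readCohort <- function(cid) {
    gt <- readDosageVCF(
      file.path(dir, sprintf("%s.genotypes.vcf", cid)),
      cohortId = cid
    )
    ex <- readTsv(file.path(dir, sprintf("%s.expression.tsv", cid)))
    fpkm <- as.matrix(ex[, -1L, drop = FALSE])
    rownames(fpkm) <- ex$gene_id
    ph <- readTsv(file.path(dir, sprintf("%s.phenotype.tsv", cid)))
    list(genotypes = gt, fpkm = fpkm, phenotype = ph)
  }
  ch <- lapply(cohorts, readCohort)
  names(ch) <- cohorts
  list(
    cohorts = ch,
    genes = genes,
    annotations = list(
      track = readBedTrack(file.path(dir, "annotations.bed")),
      categories = readTsv(file.path(dir, "variant_categories.tsv"))
    ),
    truth = list(
      causal_pairs = readTsv(file.path(dir, "truth_causal_pairs.tsv")),
      risk_variants = readTsv(file.path(dir, "truth_risk_variants.tsv"))
    ),
    manifest = manifest
  )
}
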