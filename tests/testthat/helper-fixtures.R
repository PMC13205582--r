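# shared fixture builders; everything is generated in code at test time

# GenotypeData from a raw dosage matrix (variants x samples)
makeGenotypes <- function(dosage, pos = NULL, maf = NULL, quality = NULL,
                          cohortId = "test") {
  m <- nrow(dosage)
  if (is.null(rownames(dosage))) {
    rownames(dosage) <- sprintf("var%05d", seq_len(m))
  }
  if (is.null(colnames(dosage))) {
    colnames(dosage) <- sprintf("s%04d", seq_len(ncol(dosage)))
  }
  if (is.null(maf)) {
    maf <- apply(dosage, 1L, function(x) {
      f <- mean(x, na.rm = TRUE) / 2
      max(min(f, 1 - f), 0.01)
    })
  }
  methods::new("GenotypeData",
    dosage = dosage,
    variants = S4Vectors::DataFrame(
      variant_id = rownames(dosage),
      chrom = "chr1",
      pos = pos %||% seq(1e5, by = 1e4, length.out = m),
      ref = rep("A", m), alt = rep("G", m),
      maf = maf,
      quality_score = quality %||% rep(0.99, m)
    ),
    cohortId = cohortId
  )
}

# gene GRanges from explicit coordinates
makeGenes <- function(start, end, strand = "+", chrom = "chr1") {
  n <- length(start)
  strand <- rep(strand, length.out = n)
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start, end = end),
    strand = strand
  )
  gr$gene_id <- sprintf("gene%04d", seq_len(n))
  gr$tss <- ifelse(strand == "+", start, end)
  names(gr) <- gr$gene_id
  gr
}

# small two-cohort configuration for fast end-to-end runs
tinyConfig <- function(seed = 5, ...) {
  args <- utils::modifyList(list(
    nSamples = c(a = 80L, b = 100L), nVariants = 120L, nGenes = 15L,
    nCausalPairs = 3L, betaCausal = 0.9, nHiddenFactors = 2L,
    nRiskVariants = 2L, riskOR = 2.5, riskOverlapFraction = 1,
    lowExprFraction = 0, chromLength = 5e6, seed = seed
  ), list(...))
  do.call(simConfig, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
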