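#' @name accessors
#' @title Accessors for synthetic-study containers
#' @description Slot accessors for [GenotypeData-class], [SimTruth-class]
#'   and [SimStudy-class] objects; user code should use these rather than
#'   reaching into slots.
#' @param x the object.
#' @param name for `cohort()`, a cohort id.
#' @return `dosages()` the variants x samples dosage matrix;
#'   `variantInfo()` the variant metadata DataFrame; `cohortId()` the
#'   cohort identifier; `causalPairs()`/`riskVariants()` ground-truth
#'   data.frames; `factorLoadings()` the loading matrix; `geneModels()`
#'   the gene GRanges; `simTruth()` the truth object; `cohortNames()` the
#'   cohort ids; `cohort()` one cohort's list of artifacts.
NULL

#' @rdname accessors
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))
#' @rdname accessors
#' @export
setGeneric("variantInfo", function(x) standardGeneric("variantInfo"))
#' @rdname accessors
#' @export
setGeneric("cohortId", function(x) standardGeneric("cohortId"))
#' @rdname accessors
#' @export
setGeneric("causalPairs", function(x) standardGeneric("causalPairs"))
#' @rdname accessors
#' @export
setGeneric("riskVariants", function(x) standardGeneric("riskVariants"))
#' @rdname accessors
#' @export
setGeneric("factorLoadings", function(x) standardGeneric("factorLoadings"))
#' @rdname accessors
#' @export
setGeneric("geneModels", function(x) standardGeneric("geneModels"))
#' @rdname accessors
#' @export
setGeneric("simTruth", function(x) standardGeneric("simTruth"))
#' @rdname accessors
#' @export
setGeneric("cohortNames", function(x) standardGeneric("cohortNames"))
#' @rdname accessors
#' @export
setGeneric("cohort", function(x, name) standardGeneric("cohort"))

#' @rdname accessors
setMethod("dosages", "GenotypeData", function(x) x@dosage)
#' @rdname accessors
setMethod("variantInfo", "GenotypeData", function(x) x@variants)
#' @rdname accessors
setMethod("cohortId", "GenotypeData", function(x) x@cohortId)
#' @rdname accessors
setMethod("causalPairs", "SimTruth", function(x) x@causalPairs)
#' @rdname accessors
setMethod("riskVariants", "SimTruth", function(x) x@riskVariants)
#' @rdname accessors
setMethod("factorLoadings", "SimTruth", function(x) x@factorLoadings)
#' @rdname accessors
setMethod("geneModels", "SimStudy", function(x) x@genes)
#' @rdname accessors
setMethod("simTruth", "SimStudy", function(x) x@truth)
#' @rdname accessors
setMethod("causalPairs", "SimStudy", function(x) x@truth@causalPairs)
#' @rdname accessors
setMethod("riskVariants", "SimStudy", function(x) x@truth@riskVariants)
#' @rdname accessors
setMethod("cohortNames", "SimStudy", function(x) names(x@cohorts))
#' @rdname accessors
setMethod("cohort", "SimStudy", function(x, name) {
  if (!name %in% names(x@cohorts)) {
    stop("unknown cohort: ", name, call. = FALSE)
  }
  x@cohorts[[name]]
})

#' @rdname accessors
#' @export
setGeneric("annotationTrack", function(x) standardGeneric("annotationTrack"))
#' @rdname accessors
setMethod("annotationTrack", "SimStudy", function(x) x@annotations$track)
#' @rdname accessors
#' @export
setGeneric("variantCategories", function(x) {
  standardGeneric("variantCategories")
})
#' @rdname accessors
setMethod("variantCategories", "SimStudy", function(x) {
  x@annotations$categories
})
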