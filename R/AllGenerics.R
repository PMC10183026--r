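#' Accessors for EamlCohort and PEAExperiment
#'
#' \code{variantRecords} returns the variant table, \code{sampleInfo} the
#' phenotype table, \code{caseLabels} the case/control factor (level order
#' \code{control}, \code{case}), and \code{geneIds} the distinct genes
#' represented in the object.
#'
#' @param x An [EamlCohort-class] or [PEAExperiment-class] object.
#' @return A data.frame, factor or character vector as described.
#' @name cohort-accessors
NULL

#' @rdname cohort-accessors
#' @export
setGeneric("variantRecords", function(x) standardGeneric("variantRecords"))

#' @rdname cohort-accessors
#' @export
setGeneric("sampleInfo", function(x) standardGeneric("sampleInfo"))

#' @rdname cohort-accessors
#' @export
setGeneric("caseLabels", function(x) standardGeneric("caseLabels"))

#' @rdname cohort-accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname cohort-accessors
#' @export
setMethod("variantRecords", "EamlCohort", function(x) x@variants)

#' @rdname cohort-accessors
#' @export
setMethod("sampleInfo", "EamlCohort", function(x) x@samples)

#' @rdname cohort-accessors
#' @export
setMethod("sampleInfo", "PEAExperiment",
          function(x) as.data.frame(colData(x)))

#' @rdname cohort-accessors
#' @export
setMethod("caseLabels", "EamlCohort", function(x) {
  factor(x@samples$phenotype, levels = c("control", "case"))
})

#' @rdname cohort-accessors
#' @export
setMethod("caseLabels", "PEAExperiment", function(x) {
  factor(colData(x)$phenotype, levels = c("control", "case"))
})

#' @rdname cohort-accessors
#' @export
setMethod("geneIds", "EamlCohort", function(x) unique(x@variants$gene))

#' @rdname cohort-accessors
#' @export
setMethod("geneIds", "PEAExperiment", function(x) {
  unique(rowData(x)$gene)
})

#' Cohort metadata
#'
#' @param x An [EamlCohort-class] object.
#' @return The metadata list (for simulated cohorts this includes the truth
#'   record of planted genes).
#' @export
cohortMetadata <- function(x) {
  stopifnot(is(x, "EamlCohort"))
  x@metadata
}

#' Subset a cohort by sample
#'
#' Keeps the given samples (cases and controls) and their variant records.
#'
#' @param x An [EamlCohort-class] object.
#' @param sample_ids character vector of sample identifiers to keep.
#' @return A new [EamlCohort-class].
#' @export
cohortSubset <- function(x, sample_ids) {
  stopifnot(is(x, "EamlCohort"))
  missing <- setdiff(sample_ids, x@samples$sample_id)
  if (length(missing)) {
    stop("unknown sample ids: ", paste(utils::head(missing, 5), collapse = ", "))
  }
  s <- x@samples[match(sample_ids, x@samples$sample_id), , drop = FALSE]
  rownames(s) <- NULL
  v <- x@variants[x@variants$sample_id %in% sample_ids, , drop = FALSE]
  rownames(v) <- NULL
  EamlCohort(v, s, metadata = x@metadata)
}
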