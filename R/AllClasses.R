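#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
NULL

.VARIANT_CLASSES <- c("missense", "synonymous", "stop_or_frameshift",
                      "inframe_indel")
.ZYGOSITIES <- c("het", "hom", "hemi")
.VARIANT_COLS <- c("sample_id", "gene", "variant_class", "ea", "zygosity")
.SAMPLE_COLS <- c("sample_id", "phenotype", "sex", "age", "apoe_genotype")

#' Case-control exome cohort
#'
#' Container pairing a table of per-sample coding-variant observations with
#' the per-sample phenotype table.  Each variant record carries the gene
#' symbol, the variant class, the Evolutionary Action (EA) deleteriousness
#' score in \[0, 100\] (missing for non-missense classes), and the zygosity
#' of the call.  Gene identifiers are opaque strings; no symbol remapping is
#' attempted.
#'
#' @slot variants data.frame with columns \code{sample_id}, \code{gene},
#'   \code{variant_class} (one of \code{missense}, \code{synonymous},
#'   \code{stop_or_frameshift}, \code{inframe_indel}), \code{ea},
#'   \code{zygosity} (\code{het}, \code{hom}, \code{hemi}).
#' @slot samples data.frame with columns \code{sample_id},
#'   \code{phenotype} (\code{case}/\code{control}), \code{sex}
#'   (\code{male}/\code{female}/\code{unknown}), \code{age},
#'   \code{apoe_genotype}.
#' @slot metadata list of run/provenance information (e.g. the truth record
#'   of a simulated cohort).
#'
#' @seealso [EamlCohort()] the constructor, [simulateCohort()],
#'   [buildDesignMatrix()]
#' @exportClass EamlCohort
setClass("EamlCohort",
  representation(variants = "data.frame",
                 samples = "data.frame",
                 metadata = "list"))

setValidity("EamlCohort", function(object) {
  v <- object@variants
  s <- object@samples
  msgs <- character()
  if (!all(.VARIANT_COLS %in% names(v))) {
    msgs <- c(msgs, paste("variants must have columns:",
                          paste(.VARIANT_COLS, collapse = ", ")))
  }
  if (!all(.SAMPLE_COLS %in% names(s))) {
    msgs <- c(msgs, paste("samples must have columns:",
                          paste(.SAMPLE_COLS, collapse = ", ")))
  }
  if (length(msgs)) return(msgs)
  if (anyDuplicated(s$sample_id)) {
    msgs <- c(msgs, "sample_id must be unique in the phenotype table")
  }
  if (anyNA(s$phenotype) || !all(s$phenotype %in% c("case", "control"))) {
    msgs <- c(msgs, "phenotype must be 'case' or 'control' and never missing")
  }
  if (!all(s$sex %in% c("male", "female", "unknown"))) {
    msgs <- c(msgs, "sex must be 'male', 'female' or 'unknown'")
  }
  if (nrow(v)) {
    if (!all(v$variant_class %in% .VARIANT_CLASSES)) {
      msgs <- c(msgs, "unknown variant_class value")
    }
    if (!all(v$zygosity %in% .ZYGOSITIES)) {
      msgs <- c(msgs, "zygosity must be 'het', 'hom' or 'hemi'")
    }
    ea <- v$ea[!is.na(v$ea)]
    if (length(ea) && (min(ea) < 0 || max(ea) > 100)) {
      msgs <- c(msgs, "EA scores must lie in [0, 100]")
    }
    missing_samp <- setdiff(unique(v$sample_id), s$sample_id)
    if (length(missing_samp)) {
      msgs <- c(msgs, paste("variant records refer to unknown samples:",
                            paste(utils::head(missing_samp, 5),
                                  collapse = ", ")))
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct an EamlCohort
#'
#' @param variants data.frame of variant records (see [EamlCohort-class]).
#' @param samples data.frame of per-sample phenotype records.
#' @param metadata optional list of provenance information.
#' @return An [EamlCohort-class] object.
#' @examples
#' v <- data.frame(sample_id = "S1", gene = "G1", variant_class = "missense",
#'                 ea = 50, zygosity = "het")
#' s <- data.frame(sample_id = c("S1", "S2"),
#'                 phenotype = c("case", "control"),
#'                 sex = "unknown", age = NA_real_,
#'                 apoe_genotype = NA_character_)
#' EamlCohort(v, s)
#' @export
EamlCohort <- function(variants, samples, metadata = list()) {
  variants <- as.data.frame(variants)
  samples <- as.data.frame(samples)
  variants$sample_id <- as.character(variants$sample_id)
  variants$gene <- as.character(variants$gene)
  samples$sample_id <- as.character(samples$sample_id)
  samples$phenotype <- as.character(samples$phenotype)
  new("EamlCohort", variants = variants, samples = samples,
      metadata = metadata)
}

#' pEA design matrix
#'
#' A [SummarizedExperiment::SummarizedExperiment] whose single assay
#' \code{"pEA"} holds the gene-level EA-probability features: rows are
#' gene-by-feature combinations (inheritance mode crossed with an EA
#' threshold), columns are samples, and every value lies in \[0, 1\].
#' Row metadata records \code{gene}, \code{mode} (\code{dominant} or
#' \code{recessive}) and \code{threshold}; column metadata carries the
#' phenotype table.
#'
#' @seealso [buildDesignMatrix()], [geneFeatureSlice()]
#' @exportClass PEAExperiment
setClass("PEAExperiment", contains = "SummarizedExperiment")

setValidity("PEAExperiment", function(object) {
  msgs <- character()
  if (!"pEA" %in% SummarizedExperiment::assayNames(object)) {
    return("assay 'pEA' is required")
  }
  rd <- rowData(object)
  if (!all(c("gene", "mode", "threshold") %in% names(rd))) {
    msgs <- c(msgs, "rowData must have columns gene, mode, threshold")
  }
  a <- assay(object, "pEA")
  if (length(a) && (min(a) < 0 || max(a) > 1 + 1e-12)) {
    msgs <- c(msgs, "pEA values must lie in [0, 1]")
  }
  if (!"phenotype" %in% names(colData(object))) {
    msgs <- c(msgs, "colData must carry a phenotype column")
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "EamlCohort", function(object) {
  s <- object@samples
  cat("EamlCohort:", nrow(s), "samples (",
      sum(s$phenotype == "case"), "cases /",
      sum(s$phenotype == "control"), "controls ),",
      nrow(object@variants), "variant records over",
      length(unique(object@variants$gene)), "genes\n")
  if (length(object@metadata)) {
    cat("metadata fields:", paste(names(object@metadata), collapse = ", "),
        "\n")
  }
})
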