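#' @importFrom data.table data.table setkey := .N
NULL

# Effective EA used inside the pEA product: stop/frameshift records (and, by
# default, inframe indels) act as total loss of function and enter as
# EA = 100, which drives the product term to zero and pEA to 1 whenever the
# record qualifies.  Synonymous records never contribute.
.effectiveEA <- function(variant_class, ea, inframeAsLof = TRUE) {
  out <- ea
  out[variant_class == "stop_or_frameshift"] <- 100
  if (inframeAsLof) out[variant_class == "inframe_indel"] <- 100
  out[variant_class == "synonymous"] <- NA_real_
  out
}

.zygoExponent <- function(zygosity, hemizygousExponent = 2) {
  ifelse(zygosity == "het", 1,
         ifelse(zygosity == "hom", 2, hemizygousExponent))
}

#' Canonical pEA feature specifications
#'
#' The default feature set crosses the two inheritance modes with the EA
#' thresholds, giving the canonical six features per gene (dominant and
#' recessive at EA > 1, > 30, > 70).
#'
#' @param thresholds numeric vector of EA thresholds (strict lower bounds).
#' @return data.frame with columns \code{mode} and \code{threshold} in
#'   canonical order (all dominant features first).
#' @export
featureSpecs <- function(thresholds = c(1, 30, 70)) {
  data.frame(mode = rep(c("dominant", "recessive"),
                        each = length(thresholds)),
             threshold = rep(thresholds, 2),
             stringsAsFactors = FALSE)
}

#' Gene-level EA probability (pEA)
#'
#' Aggregates the qualifying variant records of one sample in one gene into
#' the EA probability
#' \deqn{pEA = 1 - \prod_j (1 - EA_j/100)^{zygo_j}}
#' where the exponent is 1 for heterozygous and 2 for homozygous (and, by
#' default, hemizygous) calls.  A record qualifies when it is
#' non-synonymous, its effective EA strictly exceeds the threshold
#' \code{C}, and (for the recessive mode) it is homozygous or hemizygous.
#' Stop/frameshift records carry effective EA 100, so a qualifying one
#' forces pEA = 1; a sample with only synonymous records scores 0.
#'
#' @param records data.frame of variant records for a single sample x gene
#'   (columns \code{variant_class}, \code{ea}, \code{zygosity}).
#' @param mode \code{"dominant"} (all zygosities) or \code{"recessive"}
#'   (homozygous/hemizygous only).
#' @param threshold strict EA lower bound \code{C}; variants with effective
#'   EA exactly equal to \code{C} are excluded.
#' @param hemizygousExponent zygosity exponent for hemizygous calls
#'   (default 2: a hemizygous variant is functionally total, like a
#'   homozygote).
#' @param inframeAsLof treat inframe indels as loss of function (EA 100).
#' @return A single pEA value in \[0, 1\].  Missense records with missing EA
#'   are skipped with a warning rather than imputed.
#' @examples
#' computePEA(data.frame(variant_class = "missense", ea = 50,
#'                       zygosity = "het"), "dominant", 30)  # 0.5
#' @export
computePEA <- function(records, mode = c("dominant", "recessive"),
                       threshold = 1, hemizygousExponent = 2,
                       inframeAsLof = TRUE) {
  mode <- match.arg(mode)
  if (nrow(records) == 0L) return(0)
  ea <- .effectiveEA(records$variant_class, records$ea, inframeAsLof)
  n_missing <- sum(is.na(ea) & records$variant_class != "synonymous")
  if (n_missing > 0L) {
    warning(n_missing, " non-synonymous record(s) with missing EA skipped")
  }
  keep <- !is.na(ea) & ea > threshold
  if (mode == "recessive") keep <- keep & records$zygosity %in% c("hom", "hemi")
  if (!any(keep)) return(0)
  zygo <- .zygoExponent(records$zygosity[keep], hemizygousExponent)
  1 - prod((1 - ea[keep] / 100)^zygo)
}

#' Build the pEA design matrix
#'
#' Computes pEA for every sample x gene x feature cell and assembles the
#' design matrix: one row per gene-by-feature combination, one column per
#' sample, values in \[0, 1\].  With the canonical six features the matrix
#' is the transpose of the n x 6G layout used by the per-gene classifiers.
#' Samples without any variant record get all-zero columns; genes appear
#' only if at least one sample carries a record in them.
#'
#' @param cohort An [EamlCohort-class].
#' @param thresholds EA thresholds (default \code{c(1, 30, 70)}).
#' @param hemizygousExponent,inframeAsLof see [computePEA()].
#' @return A [PEAExperiment-class].  Non-synonymous records with missing EA
#'   are skipped with one warning reporting the count.
#' @export
buildDesignMatrix <- function(cohort, thresholds = c(1, 30, 70),
                              hemizygousExponent = 2, inframeAsLof = TRUE) {
  stopifnot(is(cohort, "EamlCohort"))
  v <- cohort@variants
  samples <- cohort@samples
  specs <- featureSpecs(thresholds)
  genes <- sort(unique(v$gene))
  sample_ids <- samples$sample_id

  unknown <- setdiff(unique(v$sample_id), sample_ids)
  if (length(unknown)) {
    stop("variant records for samples absent from the phenotype table: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }

  ea <- .effectiveEA(v$variant_class, v$ea, inframeAsLof)
  n_missing <- sum(is.na(ea) & v$variant_class != "synonymous")
  if (n_missing > 0L) {
    warning(n_missing, " non-synonymous record(s) with missing EA skipped")
  }

  dt <- data.table(
    gi = match(v$gene, genes),
    si = match(v$sample_id, sample_ids),
    ea = ea,
    hom = v$zygosity %in% c("hom", "hemi"),
    # log of the per-variant survival term (1 - EA/100)^zygo; EA = 100 gives
    # -Inf and hence pEA exactly 1 after exponentiation
    lterm = .zygoExponent(v$zygosity, hemizygousExponent) *
      log(1 - ea / 100)
  )
  dt <- dt[!is.na(ea)]

  mat <- matrix(0, nrow = length(genes) * nrow(specs),
                ncol = length(sample_ids))
  featureRow <- function(gi, k) (gi - 1L) * nrow(specs) + k
  for (k in seq_len(nrow(specs))) {
    sel <- dt$ea > specs$threshold[k]
    if (specs$mode[k] == "recessive") sel <- sel & dt$hom
    if (!any(sel)) next
    agg <- dt[sel, list(lsum = sum(lterm)), by = c("gi", "si")]
    mat[cbind(featureRow(agg$gi, k), agg$si)] <- 1 - exp(agg$lsum)
  }

  rd <- DataFrame(gene = rep(genes, each = nrow(specs)),
                  mode = rep(specs$mode, length(genes)),
                  threshold = rep(specs$threshold, length(genes)))
  rownames(mat) <- paste(rd$gene, rd$mode, rd$threshold, sep = "::")
  colnames(mat) <- sample_ids
  cd <- DataFrame(samples, row.names = sample_ids)
  se <- SummarizedExperiment(assays = list(pEA = mat), rowData = rd,
                             colData = cd)
  new("PEAExperiment", se)
}

#' Per-gene feature slice
#'
#' Extracts one gene's n x 6 feature block (samples in rows, features in
#' canonical order: dominant features at increasing threshold, then
#' recessive).
#'
#' @param x A [PEAExperiment-class].
#' @param gene gene identifier.
#' @return Numeric matrix, samples x features.
#' @export
geneFeatureSlice <- function(x, gene) {
  stopifnot(is(x, "PEAExperiment"))
  idx <- which(rowData(x)$gene == gene)
  if (!length(idx)) stop("gene not present in design matrix: ", gene)
  rd <- rowData(x)[idx, ]
  ord <- order(match(rd$mode, c("dominant", "recessive")), rd$threshold)
  m <- t(assay(x, "pEA")[idx[ord], , drop = FALSE])
  colnames(m) <- paste(substr(rd$mode[ord], 1, 3), rd$threshold[ord],
                       sep = "_")
  m
}
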