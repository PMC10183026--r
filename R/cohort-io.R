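#' @importFrom data.table fread fwrite
#' @importFrom jsonlite write_json read_json
NULL

# Load report: every dropped or flagged row is accounted for, so
# rows in = rows kept + rows dropped.
.loadReport <- function(n_in, n_kept, n_dropped, flags = list()) {
  stopifnot(n_in == n_kept + n_dropped)
  c(list(n_in = n_in, n_kept = n_kept, n_dropped = n_dropped), flags)
}

#' Read a variant table
#'
#' Reads the canonical flat TSV of per-sample variant observations
#' (columns \code{sample_id}, \code{gene}, \code{variant_class},
#' \code{ea}, \code{zygosity}; \code{"."} denotes a missing EA).  Rows
#' whose class is not in \code{filters} (e.g. copy-number calls in an
#' upstream table) are dropped with a warning giving the count.  Missense
#' rows with missing EA are retained but counted in the load report.
#'
#' @param path TSV file.
#' @param filters variant classes to keep (default: all four supported
#'   classes).
#' @return data.frame of variant records with a \code{"load_report"}
#'   attribute (rows in / kept / dropped, flagged missing-EA count).
#' @export
readVariantTable <- function(path, filters = .VARIANT_CLASSES) {
  .assertChoice(filters, .VARIANT_CLASSES, "variant class filter")
  d <- fread(path, sep = "\t", colClasses = list(character = "sample_id"),
             na.strings = ".", data.table = FALSE, showProgress = FALSE)
  need <- setdiff(.VARIANT_COLS, names(d))
  if (length(need)) {
    stop("variant table is missing required column(s): ",
         paste(need, collapse = ", "))
  }
  d <- d[, .VARIANT_COLS]
  d$ea <- as.numeric(d$ea)
  bad_ea <- which(!is.na(d$ea) & (d$ea < 0 | d$ea > 100))
  if (length(bad_ea)) {
    stop("EA outside [0, 100] at row(s): ",
         paste(utils::head(bad_ea, 5), collapse = ", "))
  }
  bad_zy <- which(!d$zygosity %in% .ZYGOSITIES)
  if (length(bad_zy)) {
    stop("invalid zygosity at row(s): ",
         paste(utils::head(bad_zy, 5), collapse = ", "))
  }
  keep <- d$variant_class %in% filters
  n_drop <- sum(!keep)
  if (n_drop > 0L) {
    warning(n_drop, " row(s) with variant class outside the filter dropped")
  }
  d <- d[keep, , drop = FALSE]
  rownames(d) <- NULL
  flagged <- sum(d$variant_class == "missense" & is.na(d$ea))
  if (flagged > 0L) {
    warning(flagged, " missense row(s) with missing EA retained but flagged")
  }
  attr(d, "load_report") <- .loadReport(length(keep), nrow(d), n_drop,
                                        list(missense_missing_ea = flagged))
  d
}

#' @rdname readVariantTable
#' @param variants data.frame of variant records.
#' @export
writeVariantTable <- function(variants, path) {
  fwrite(variants[, .VARIANT_COLS], path, sep = "\t", na = ".",
         quote = FALSE)
  invisible(path)
}

#' Read / write a phenotype table
#'
#' TSV with columns \code{sample_id}, \code{phenotype} (1 = case,
#' 0 = control), \code{sex} (M/F/U), \code{age}, \code{apoe}
#' (\code{"."} = missing).
#'
#' @param path TSV file.
#' @return data.frame in the internal representation (phenotype
#'   \code{case}/\code{control}, sex \code{male}/\code{female}/
#'   \code{unknown}).
#' @export
readPhenotypeTable <- function(path) {
  d <- fread(path, sep = "\t", na.strings = ".", data.table = FALSE,
             colClasses = list(character = "sample_id"),
             showProgress = FALSE)
  need <- setdiff(c("sample_id", "phenotype", "sex", "age", "apoe"),
                  names(d))
  if (length(need)) {
    stop("phenotype table is missing required column(s): ",
         paste(need, collapse = ", "))
  }
  if (anyNA(d$phenotype) || !all(d$phenotype %in% c(0L, 1L))) {
    stop("phenotype must be 0 (control) or 1 (case), never missing")
  }
  if (anyDuplicated(d$sample_id)) stop("duplicate sample_id")
  data.frame(sample_id = d$sample_id,
             phenotype = ifelse(d$phenotype == 1L, "case", "control"),
             sex = c(M = "male", F = "female", U = "unknown")[
               ifelse(is.na(d$sex), "U", d$sex)],
             age = as.numeric(d$age),
             apoe_genotype = as.character(d$apoe),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' @rdname readPhenotypeTable
#' @param samples data.frame of sample records.
#' @export
writePhenotypeTable <- function(samples, path) {
  out <- data.frame(sample_id = samples$sample_id,
                    phenotype = as.integer(samples$phenotype == "case"),
                    sex = c(male = "M", female = "F", unknown = "U")[
                      samples$sex],
                    age = samples$age,
                    apoe = samples$apoe_genotype)
  fwrite(out, path, sep = "\t", na = ".", quote = FALSE)
  invisible(path)
}

#' Read a cohort (variant + phenotype tables)
#'
#' @param variant_path,phenotype_path file paths.
#' @param filters variant-class filter, see [readVariantTable()].
#' @return An [EamlCohort-class].
#' @export
readCohort <- function(variant_path, phenotype_path,
                       filters = .VARIANT_CLASSES) {
  v <- readVariantTable(variant_path, filters)
  s <- readPhenotypeTable(phenotype_path)
  EamlCohort(v, s, metadata = list(load_report = attr(v, "load_report")))
}

#' Read a weighted edge list
#'
#' Whitespace- or tab-separated three-column edge list (node, node,
#' positive weight; e.g. a combined interaction-confidence score).
#' Self-loops are dropped with a warning and duplicate edges collapsed to
#' their maximum weight; the result is an undirected weighted graph.
#'
#' @param path edge-list file.
#' @return An \code{igraph} with edge attribute \code{weight} and a
#'   \code{"load_report"} attribute.
#' @export
readNetwork <- function(path) {
  d <- fread(path, header = FALSE, data.table = FALSE, showProgress = FALSE)
  if (ncol(d) < 3L) stop("edge list must have 3 columns: node, node, weight")
  d <- d[, 1:3]
  names(d) <- c("a", "b", "w")
  d$w <- suppressWarnings(as.numeric(d$w))
  if (anyNA(d$w)) stop("non-numeric edge weight")
  if (any(d$w <= 0)) stop("edge weights must be positive")
  n_in <- nrow(d)
  loops <- d$a == d$b
  if (any(loops)) {
    warning(sum(loops), " self-loop(s) dropped")
    d <- d[!loops, , drop = FALSE]
  }
  # undirected: canonical node order, duplicates collapsed to max weight
  key <- paste(pmin(d$a, d$b), pmax(d$a, d$b), sep = "\r")
  agg <- tapply(d$w, key, max)
  parts <- strsplit(names(agg), "\r", fixed = TRUE)
  edges <- data.frame(a = vapply(parts, `[`, "", 1),
                      b = vapply(parts, `[`, "", 2),
                      weight = as.numeric(agg))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  attr(g, "load_report") <- .loadReport(
    n_in, nrow(edges), n_in - nrow(edges),
    list(self_loops = sum(loops),
         duplicates_collapsed = n_in - sum(loops) - nrow(edges)))
  message("network: ", igraph::vcount(g), " nodes, ",
          igraph::ecount(g), " edges")
  g
}

#' Write a weighted graph as an edge list
#'
#' @param graph an \code{igraph} with a \code{weight} edge attribute.
#' @param path output TSV.
#' @export
writeNetwork <- function(graph, path) {
  el <- igraph::as_edgelist(graph)
  fwrite(data.frame(a = el[, 1], b = el[, 2],
                    w = igraph::E(graph)$weight),
         path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a gene list (one symbol per line)
#'
#' @param path text file.
#' @return character vector.
#' @export
readGeneList <- function(path) {
  x <- readLines(path)
  x <- trimws(x)
  x[nzchar(x)]
}

#' Write / read ranked gene results
#'
#' The results TSV holds one row per gene (per-classifier MCCs, mean MCC,
#' p, q, rank); a JSON sidecar (\code{<path>.json}) records the run
#' configuration, seeds and package version so a ranking is reproducible
#' from its output.
#'
#' @param results ranked data.frame from [rankGenes()].
#' @param path output TSV; the sidecar is written next to it.
#' @param run_config optional list stored in the sidecar.
#' @return \code{path}, invisibly.
#' @export
writeGeneResults <- function(results, path, run_config = list()) {
  fwrite(results, path, sep = "\t", quote = FALSE)
  sidecar <- list(
    package = "eamlr",
    version = as.character(utils::packageVersion("eamlr")),
    n_genes = nrow(results),
    classifiers = attr(results, "classifiers"),
    fdr = attr(results, "fdr"),
    config = run_config)
  write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
             digits = NA, null = "null")
  invisible(path)
}

#' @rdname writeGeneResults
#' @export
readGeneResults <- function(path) {
  d <- fread(path, sep = "\t", data.table = FALSE, showProgress = FALSE)
  sidecar_path <- paste0(path, ".json")
  if (file.exists(sidecar_path)) {
    sc <- read_json(sidecar_path)
    attr(d, "classifiers") <- unlist(sc$classifiers)
    attr(d, "fdr") <- sc$fdr
    attr(d, "sidecar") <- sc
  }
  d
}

#' Read EA-annotated variants from a VCF
#'
#' Convenience reader for VCF 4.x with per-ALT annotations: one record is
#' emitted per sample x alt allele with a non-reference genotype
#' (multi-allelic sites decomposed per alt; \code{0/1} maps to \code{het},
#' \code{1/1} to \code{hom}, haploid calls such as male non-PAR X to
#' \code{hemi}; missing genotypes emit nothing).  EA, gene and variant
#' class are taken from INFO fields.  Requires the VariantAnnotation
#' package.
#'
#' @param path VCF file.
#' @param ea_field INFO field holding the per-ALT EA score.
#' @param gene_field,class_field INFO fields holding gene symbol and
#'   variant class (values as in [EamlCohort-class]; unknown values are
#'   mapped: \code{"stop"}/\code{"frameshift"} to
#'   \code{stop_or_frameshift}).
#' @return data.frame of variant records.
#' @export
readVcfWithEA <- function(path, ea_field = "EA", gene_field = "GENE",
                          class_field = "CLASS") {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE)) {
    stop("readVcfWithEA requires the VariantAnnotation package")
  }
  vcf <- VariantAnnotation::readVcf(path)
  info_names <- names(VariantAnnotation::info(vcf))
  for (fld in c(ea_field, gene_field, class_field)) {
    if (!fld %in% info_names) {
      stop("INFO field '", fld, "' not found; available: ",
           paste(info_names, collapse = ", "))
    }
  }
  vcf <- VariantAnnotation::expand(vcf)  # one row per alt allele
  info <- VariantAnnotation::info(vcf)
  gt <- VariantAnnotation::geno(vcf)$GT
  classmap <- c(stop = "stop_or_frameshift",
                frameshift = "stop_or_frameshift",
                stop_or_frameshift = "stop_or_frameshift",
                missense = "missense", synonymous = "synonymous",
                inframe_indel = "inframe_indel")

  recs <- list()
  samples <- colnames(gt)
  for (j in seq_along(samples)) {
    g <- gt[, j]
    alt_count <- vapply(strsplit(g, "[/|]"), function(a) {
      if (any(a == ".")) return(NA_integer_)
      sum(a == "1")
    }, integer(1))
    ploidy <- lengths(strsplit(g, "[/|]"))
    sel <- which(!is.na(alt_count) & alt_count > 0L)
    if (!length(sel)) next
    zyg <- ifelse(ploidy[sel] == 1L, "hemi",
                  ifelse(alt_count[sel] == 2L, "hom", "het"))
    ea <- suppressWarnings(as.numeric(unlist(info[[ea_field]])[sel]))
    recs[[j]] <- data.frame(
      sample_id = samples[j],
      gene = as.character(unlist(info[[gene_field]])[sel]),
      variant_class = unname(classmap[
        as.character(unlist(info[[class_field]])[sel])]),
      ea = ea,
      zygosity = zyg, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, recs)
  if (is.null(out)) {
    out <- data.frame(sample_id = character(), gene = character(),
                      variant_class = character(), ea = numeric(),
                      zygosity = character())
  }
  rownames(out) <- NULL
  out
}
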