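#' @importFrom stats p.adjust pnorm mad median
NULL

#' Matthews correlation coefficient
#'
#' \deqn{MCC = (TP \cdot TN - FP \cdot FN) /
#'   \sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}
#' Returns 0 by convention whenever any factor of the denominator is zero
#' (e.g. a degenerate classifier that predicts a single class).  MCC is
#' preferred over accuracy because it remains informative under imbalanced
#' class sizes.
#'
#' @param tp,tn,fp,fn non-negative confusion counts.
#' @return Value in \[-1, 1\].
#' @examples
#' mccScore(5, 5, 0, 0)   # 1
#' mccScore(3, 4, 1, 2)   # 10 / sqrt(600)
#' @export
mccScore <- function(tp, tn, fp, fn) {
  if (any(c(tp, tn, fp, fn) < 0)) stop("confusion counts must be >= 0")
  # work in double: the products overflow 32-bit integers at modest n
  tp <- as.numeric(tp)
  tn <- as.numeric(tn)
  fp <- as.numeric(fp)
  fn <- as.numeric(fn)
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (denom == 0) return(0)
  (tp * tn - fp * fn) / sqrt(denom)
}

#' Cross-validation configuration
#'
#' @param k number of folds (default 10; the cohort is split into k equal
#'   stratified parts, each used once as the held-out test set).
#' @param seed integer seed controlling the fold assignment.
#' @return list with class \code{"eamlCV"}.
#' @export
cvConfig <- function(k = 10L, seed = 1L) {
  if (k < 2L) stop("k must be at least 2")
  structure(list(k = as.integer(k), seed = as.integer(seed)),
            class = "eamlCV")
}

#' Score one gene with the classifier ensemble
#'
#' Runs stratified k-fold cross-validation of every roster classifier on the
#' gene's feature block, pools each classifier's confusion counts over the
#' held-out folds into a single MCC, and averages the per-classifier MCCs
#' into the gene's score.  All-constant feature blocks are not fit: every
#' MCC is 0 and the result is flagged.
#'
#' @param features samples x features numeric matrix
#'   (see [geneFeatureSlice()]).
#' @param labels case/control factor (positive class = \code{"case"}).
#' @param roster classifier list from [classifierRoster()].
#' @param folds integer fold assignment per sample; supply the same vector
#'   for every gene so results are comparable.  Defaults to a stratified
#'   split from \code{cv}.
#' @param cv a [cvConfig()].
#' @return list with \code{mcc_by_classifier} (named numeric),
#'   \code{mean_mcc}, \code{n_carriers} (samples with any non-zero
#'   feature), and \code{constant} flag.
#' @export
evaluateGene <- function(features, labels, roster = classifierRoster(),
                         folds = NULL, cv = cvConfig()) {
  labels <- factor(as.character(labels), levels = c("control", "case"))
  if (nlevels(droplevels(labels)) < 2L) {
    stop("both classes must be present")
  }
  if (is.null(folds)) folds <- .stratifiedFolds(labels, cv$k, cv$seed)
  stopifnot(length(folds) == nrow(features))

  n_carriers <- sum(rowSums(features != 0) > 0)
  if (all(features == features[1])) {
    mcc <- stats::setNames(rep(0, length(roster)), names(roster))
    return(list(mcc_by_classifier = mcc, mean_mcc = 0,
                n_carriers = n_carriers, constant = TRUE))
  }

  k <- max(folds)
  conf <- matrix(0, nrow = length(roster), ncol = 4,
                 dimnames = list(names(roster), c("tp", "tn", "fp", "fn")))

  # Samples sharing a feature profile are interchangeable for every
  # learner, so map each sample to a dense integer profile id once and
  # collapse folds with integer arithmetic (see classifierRoster()).
  prof <- rep(1L, nrow(features))
  for (j in seq_len(ncol(features))) {
    u <- unique(features[, j])
    prof <- prof * length(u) + match(features[, j], u) - 1L
    prof <- match(prof, unique(prof))
  }
  uniq <- which(!duplicated(prof))
  profiles <- features[uniq[order(prof[uniq])], , drop = FALSE]
  n_prof <- nrow(profiles)
  is_case_lab <- labels == "case"

  for (f in seq_len(k)) {
    te <- folds == f
    tr_prof <- prof[!te]
    tr_case <- is_case_lab[!te]

    # training fold: unique (profile, label) pairs with frequency weights
    w_ctrl <- tabulate(tr_prof[!tr_case], n_prof)
    w_case <- tabulate(tr_prof[tr_case], n_prof)
    pres <- c(which(w_ctrl > 0), which(w_case > 0))
    wtr <- c(w_ctrl[w_ctrl > 0], w_case[w_case > 0])
    xtr_u <- profiles[pres, , drop = FALSE]
    ytr_u <- factor(rep(c("control", "case"),
                        c(sum(w_ctrl > 0), sum(w_case > 0))),
                    levels = c("control", "case"))

    # test fold: unique profiles with per-class counts
    te_prof <- prof[te]
    te_case <- is_case_lab[te]
    n_ctrl <- tabulate(te_prof[!te_case], n_prof)
    n_case <- tabulate(te_prof[te_case], n_prof)
    epres <- which(n_ctrl + n_case > 0)
    xte_u <- profiles[epres, , drop = FALSE]
    n_ctrl <- n_ctrl[epres]
    n_case <- n_case[epres]

    # shared per-fold data.frames for the formula-interface learners
    attr(xtr_u, "df") <- structure(
      lapply(seq_len(ncol(xtr_u)), function(j) xtr_u[, j]),
      names = colnames(xtr_u), class = "data.frame",
      row.names = .set_row_names(nrow(xtr_u)))
    attr(xte_u, "df") <- structure(
      lapply(seq_len(ncol(xte_u)), function(j) xte_u[, j]),
      names = colnames(xte_u), class = "data.frame",
      row.names = .set_row_names(nrow(xte_u)))

    xtr <- ytr <- NULL  # expanded rows, built lazily for unweighted learners

    for (ci in seq_along(roster)) {
      fn <- roster[[ci]]
      seed_ci <- .childSeed(cv$seed, f * 131L + ci)
      if (isTRUE(attr(fn, "weighted"))) {
        pred <- fn(xtr_u, ytr_u, wtr, xte_u, seed_ci)
      } else {
        if (is.null(xtr)) {
          xtr <- features[!te, , drop = FALSE]
          ytr <- labels[!te]
          attr(xtr, "df") <- structure(
            lapply(seq_len(ncol(xtr)), function(j) xtr[, j]),
            names = colnames(xtr), class = "data.frame",
            row.names = .set_row_names(nrow(xtr)))
        }
        pred <- fn(xtr, ytr, rep(1, length(ytr)), xte_u, seed_ci)
      }
      is_case <- !is.na(pred) & pred == "case"
      conf[ci, ] <- conf[ci, ] + c(sum(n_case[is_case]),
                                   sum(n_ctrl[!is_case]),
                                   sum(n_ctrl[is_case]),
                                   sum(n_case[!is_case]))
    }
  }
  mcc <- apply(conf, 1, function(r) mccScore(r[1], r[2], r[3], r[4]))
  list(mcc_by_classifier = mcc, mean_mcc = mean(mcc),
       n_carriers = n_carriers, constant = FALSE)
}

#' Score every gene of a design matrix
#'
#' Applies [evaluateGene()] to each gene's feature block using one shared
#' fold assignment.  Genes without any qualifying carrier are excluded from
#' evaluation (and later from FDR multiplicity) and reported in the
#' \code{"excluded"} attribute.
#'
#' @param pea A [PEAExperiment-class].
#' @param roster classifier roster.
#' @param cv a [cvConfig()].
#' @param labels optional label override (defaults to the design-matrix
#'   phenotype column); used internally for permutation nulls.
#' @param genes optional subset of genes to score.
#' @return data.frame with one row per evaluated gene: per-classifier MCCs,
#'   \code{mean_mcc}, \code{n_carriers}, \code{constant}.
#' @export
evaluateAllGenes <- function(pea, roster = classifierRoster(),
                             cv = cvConfig(), labels = NULL, genes = NULL) {
  stopifnot(is(pea, "PEAExperiment"))
  if (is.null(labels)) labels <- caseLabels(pea)
  labels <- factor(as.character(labels), levels = c("control", "case"))
  folds <- .stratifiedFolds(labels, cv$k, cv$seed)
  all_genes <- geneIds(pea)
  if (is.null(genes)) genes <- all_genes
  .assertChoice(genes, all_genes, "gene")

  res <- vector("list", length(genes))
  for (i in seq_along(genes)) {
    feat <- geneFeatureSlice(pea, genes[i])
    if (!any(feat != 0)) next  # no qualifying carrier: res[[i]] stays NULL
    res[[i]] <- evaluateGene(feat, labels, roster, folds = folds, cv = cv)
  }
  evaluated <- !vapply(res, is.null, logical(1))
  excluded <- genes[!evaluated]
  genes <- genes[evaluated]
  res <- res[evaluated]

  mccs <- do.call(rbind, lapply(res, function(r) r$mcc_by_classifier))
  out <- data.frame(gene = genes, mccs,
                    mean_mcc = vapply(res, `[[`, numeric(1), "mean_mcc"),
                    n_carriers = vapply(res, `[[`, numeric(1), "n_carriers"),
                    constant = vapply(res, `[[`, logical(1), "constant"),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "excluded") <- excluded
  attr(out, "classifiers") <- names(roster)
  out
}

#' Pooled permutation null for mean MCC
#'
#' Repeats the full per-gene evaluation under \code{B} random permutations
#' of the case/control labels and pools the resulting mean-MCC values into
#' an empirical null distribution.  To keep large designs tractable a
#' random subset of genes (\code{genesFraction}) can be scored per
#' permutation; the pooled null remains exchangeable across genes because
#' labels carry no gene-specific structure under the null.
#'
#' @param pea A [PEAExperiment-class].
#' @param roster classifier roster.
#' @param cv a [cvConfig()] (fold seed is re-derived per permutation).
#' @param B number of label permutations (>= 1).
#' @param genesFraction fraction of genes scored per permutation
#'   (default 1 = all).
#' @param seed master seed for permutations and gene subsampling.
#' @return numeric vector of pooled null mean-MCC values.
#' @export
permuteNull <- function(pea, roster = classifierRoster(), cv = cvConfig(),
                        B = 50L, genesFraction = 1, seed = 1L) {
  if (B < 1L) stop("B must be >= 1")
  labels <- caseLabels(pea)
  genes <- geneIds(pea)
  n_pick <- max(1L, ceiling(genesFraction * length(genes)))
  out <- vector("list", B)
  for (b in seq_len(B)) {
    sb <- .childSeed(seed, b)
    perm <- withr::with_seed(sb, sample(labels))
    sub <- withr::with_seed(sb + 1L,
                            sample(genes, n_pick))
    r <- evaluateAllGenes(pea, roster,
                          cv = cvConfig(cv$k, .childSeed(sb, 2L)),
                          labels = perm, genes = sub)
    out[[b]] <- r$mean_mcc
  }
  unlist(out)
}

#' Attach p-values, FDR and ranks to gene results
#'
#' Two p-value modes are available, both mapping the mean-MCC distribution
#' to significance.  \code{"permutation"} computes the empirical
#' upper-tail p against a pooled label-permutation null,
#' \eqn{p = (1 + \#\{null \ge mcc\}) / (1 + \#null)}.
#' \code{"parametric"} computes a robust z-score of each gene's mean MCC
#' against the genome-wide distribution (median/MAD) and converts it to a
#' one-sided normal p.  Benjamini-Hochberg adjustment over all evaluated
#' genes yields q; genes are ranked by mean MCC (ties broken by the best
#' single-classifier MCC, then gene name).
#'
#' @param results data.frame from [evaluateAllGenes()].
#' @param null_mccs numeric null values from [permuteNull()] (permutation
#'   mode only).
#' @param method \code{"permutation"} or \code{"parametric"}.
#' @param fdr significance threshold recorded in the
#'   \code{"significant"} attribute (default 0.01).
#' @return The results data.frame sorted by rank with added columns
#'   \code{p}, \code{q}, \code{rank}.
#' @export
rankGenes <- function(results, null_mccs = NULL,
                      method = c("permutation", "parametric"), fdr = 0.01) {
  method <- match.arg(method)
  if (!nrow(results)) stop("no gene results to rank")
  if (method == "permutation") {
    if (is.null(null_mccs) || !length(null_mccs)) {
      stop("permutation mode needs a non-empty null distribution")
    }
    nn <- length(null_mccs)
    results$p <- vapply(results$mean_mcc, function(m) {
      (1 + sum(null_mccs >= m)) / (1 + nn)
    }, numeric(1))
  } else {
    s <- mad(results$mean_mcc)
    if (s == 0) s <- max(sd(results$mean_mcc), .Machine$double.eps)
    z <- (results$mean_mcc - median(results$mean_mcc)) / s
    results$p <- pnorm(z, lower.tail = FALSE)
  }
  results$q <- p.adjust(results$p, method = "BH")

  cls <- attr(results, "classifiers")
  best <- apply(results[, cls, drop = FALSE], 1, max)
  ord <- order(-results$mean_mcc, -best, results$gene)
  results <- results[ord, , drop = FALSE]
  results$rank <- seq_len(nrow(results))
  rownames(results) <- NULL
  attr(results, "classifiers") <- cls
  attr(results, "significant") <- results$gene[results$q < fdr]
  attr(results, "fdr") <- fdr
  results
}

#' Full gene-ranking pipeline on a cohort
#'
#' Convenience wrapper: build the design matrix, score every gene, build
#' the null (permutation mode), and rank.
#'
#' @param cohort An [EamlCohort-class].
#' @param thresholds EA thresholds for the feature set.
#' @param roster classifier roster.
#' @param cv a [cvConfig()].
#' @param method p-value mode, see [rankGenes()].
#' @param B,genesFraction permutation-null settings, see [permuteNull()].
#' @param fdr FDR threshold.
#' @return Ranked results data.frame (see [rankGenes()]).
#' @export
eamlRank <- function(cohort, thresholds = c(1, 30, 70),
                     roster = classifierRoster(), cv = cvConfig(),
                     method = c("parametric", "permutation"),
                     B = 50L, genesFraction = 1, fdr = 0.01) {
  method <- match.arg(method)
  pea <- buildDesignMatrix(cohort, thresholds)
  res <- evaluateAllGenes(pea, roster, cv)
  null_mccs <- NULL
  if (method == "permutation") {
    null_mccs <- permuteNull(pea, roster, cv, B = B,
                             genesFraction = genesFraction, seed = cv$seed)
  }
  rankGenes(res, null_mccs, method = method, fdr = fdr)
}

#' Sex-stratified gene ranking
#'
#' Runs the full ranking independently on the combined cohort and on the
#' male and female strata, then summarises the pairwise and triple overlaps
#' of the significant gene sets.  A stratum with fewer than \code{2 * k}
#' samples of either class is skipped with a warning.
#'
#' @param cohort An [EamlCohort-class] with recorded sex.
#' @param ... arguments passed to [eamlRank()].
#' @param cv a [cvConfig()].
#' @return list with elements \code{combined}, \code{male}, \code{female}
#'   (ranked results or NULL for skipped strata) and \code{overlap}, the
#'   intersection counts of the significant sets.
#' @export
runSexStratified <- function(cohort, cv = cvConfig(), ...) {
  s <- sampleInfo(cohort)
  runs <- list(combined = cohort)
  for (sx in c("male", "female")) {
    ids <- s$sample_id[s$sex == sx]
    sub <- cohortSubset(cohort, ids)
    tab <- table(sampleInfo(sub)$phenotype)
    if (length(tab) < 2L || min(tab) < 2L * cv$k) {
      warning("stratum '", sx, "' has too few samples per class; skipped")
      runs[sx] <- list(NULL)
    } else {
      runs[[sx]] <- sub
    }
  }
  out <- lapply(runs, function(co) {
    if (is.null(co)) NULL else eamlRank(co, cv = cv, ...)
  })
  sig <- lapply(out, function(r) if (is.null(r)) character() else
    attr(r, "significant"))
  ov <- list(
    combined_male = length(intersect(sig$combined, sig$male)),
    combined_female = length(intersect(sig$combined, sig$female)),
    male_female = length(intersect(sig$male, sig$female)),
    all = length(Reduce(intersect, sig)))
  c(out, list(overlap = ov, significant = sig))
}
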