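#' @importFrom stats t.test glm binomial
NULL

#' Per-gene pEA feature matrix for risk prediction
#'
#' Represents every sample as a vector of h pEA values, one per selected
#' gene, taken from the dominant-mode feature at the lowest threshold
#' (all non-synonymous variants) unless another feature is requested.
#'
#' @param selected_genes genes to use as features (e.g. the FDR-significant
#'   set of a ranking run); order defines the column order.
#' @param pea A [PEAExperiment-class].
#' @param mode,threshold which pEA feature to extract (default dominant,
#'   threshold 1).
#' @return Samples x genes numeric matrix.
#' @export
buildGeneFeatures <- function(selected_genes, pea, mode = "dominant",
                              threshold = 1) {
  stopifnot(is(pea, "PEAExperiment"))
  rd <- rowData(pea)
  idx <- vapply(selected_genes, function(g) {
    i <- which(rd$gene == g & rd$mode == mode & rd$threshold == threshold)
    if (!length(i)) stop("gene not present in design matrix: ", g)
    i[1]
  }, integer(1))
  m <- t(assay(pea, "pEA")[idx, , drop = FALSE])
  colnames(m) <- selected_genes
  m
}

#' APOE + age baseline feature matrix
#'
#' Two columns per sample: the pEA of the sample's APOE variants
#' (dominant mode, threshold 1: a benign-genotype carrier scores 0) and the
#' age, z-scored over the whole cohort (sample standard deviation).  The
#' cohort-wide normalization follows the published protocol; it leaks
#' test-fold means into training folds, so a fold-wise alternative is
#' available.
#'
#' @param samples phenotype data.frame (see [EamlCohort-class]); ages must
#'   be present.
#' @param apoe_variants variant records of the APOE gene for these samples.
#' @param normalizeAge \code{"cohort"} (default, matches the published
#'   protocol) or \code{"none"} (leave raw, e.g. for fold-wise scaling by
#'   the caller).
#' @return Samples x 2 matrix with columns \code{apoe_pea}, \code{age}.
#' @export
buildBaselineFeatures <- function(samples, apoe_variants,
                                  normalizeAge = c("cohort", "none")) {
  normalizeAge <- match.arg(normalizeAge)
  if (anyNA(samples$age)) {
    stop("age missing for samples: ",
         paste(utils::head(samples$sample_id[is.na(samples$age)], 5),
               collapse = ", "))
  }
  apoe_pea <- vapply(samples$sample_id, function(sid) {
    rec <- apoe_variants[apoe_variants$sample_id == sid, , drop = FALSE]
    computePEA(rec, "dominant", threshold = 1)
  }, numeric(1))
  age <- samples$age
  if (normalizeAge == "cohort") {
    s <- sd(age)
    if (s == 0) stop("zero age variance; cannot z-score")
    age <- (age - mean(age)) / s
  }
  m <- cbind(apoe_pea = unname(apoe_pea), age = age)
  rownames(m) <- samples$sample_id
  m
}

# --- base learners of the stacked risk classifier -------------------------
# Each returns a case-probability-like score on new data.

.riskBaseLearners <- function(rfTrees = 100L, adaboostIterations = 25L,
                              ridgeLambda = 1e-3) {
  list(
    random_forest = function(xtr, ytr, seed) {
      fit <- withr::with_seed(seed,
        randomForest(xtr, ytr, ntree = rfTrees))
      function(x) predict(fit, x, type = "prob")[, "case"]
    },
    logistic = function(xtr, ytr, seed) {
      if (ncol(xtr) < 2L) xtr <- cbind(xtr, 0)
      fit <- glmnet(xtr, ytr, family = "binomial", alpha = 0,
                    lambda = ridgeLambda)
      function(x) {
        if (ncol(x) < 2L) x <- cbind(x, 0)
        drop(predict(fit, x, type = "response"))
      }
    },
    adaboost = function(xtr, ytr, seed) {
      model <- .adaboostTrain(xtr, as.integer(ytr == "case"),
                              adaboostIterations)
      function(x) plogis(2 * .adaboostScore(model, x))
    }
  )
}

# Meta decision tree over base-learner scores: split threshold and minimum
# information-gain weight fraction follow the stated stacking settings.
.fitMetaTree <- function(meta_x, y, minFraction = 0.01) {
  d <- as.data.frame(meta_x)
  d$.y <- y
  rpart(.y ~ ., data = d, method = "class",
        control = rpart.control(
          cp = 1e-6,
          minbucket = max(2L, floor(minFraction * nrow(d))),
          xval = 0L))
}

#' Stacked risk classifier under cross-validation
#'
#' Trains the three-learner stacked ensemble (random forest, ridge
#' logistic regression, AdaBoost on stumps, combined by a decision-tree
#' meta learner) under stratified k-fold cross-validation.  Within each
#' training fold, inner out-of-fold predictions of the base learners form
#' the meta-training matrix; the base learners are then refit on the whole
#' training fold and the held-out fold is scored by the meta tree.  One
#' ROC AUC is reported per held-out fold.
#'
#' @param features samples x h numeric matrix (see
#'   [buildGeneFeatures()] / [buildBaselineFeatures()]).
#' @param labels case/control factor or character vector.
#' @param k outer folds (default 10).
#' @param seed seed for fold assignment and stochastic learners.
#' @param innerK inner folds generating the meta-training predictions.
#' @param rfTrees,adaboostIterations,ridgeLambda base-learner settings.
#' @return list with class \code{"riskRun"}: \code{per_fold_auc},
#'   \code{mean_auc}, \code{k}.
#' @export
trainStacked <- function(features, labels, k = 10L, seed = 1L, innerK = 5L,
                         rfTrees = 100L, adaboostIterations = 25L,
                         ridgeLambda = 1e-3) {
  if (is.null(dim(features)) || ncol(features) < 1L) {
    stop("at least one feature column is required")
  }
  labels <- factor(as.character(labels), levels = c("control", "case"))
  base <- .riskBaseLearners(rfTrees, adaboostIterations, ridgeLambda)
  folds <- .stratifiedFolds(labels, k, seed)
  aucs <- numeric(k)
  for (f in seq_len(k)) {
    te <- folds == f
    xtr <- features[!te, , drop = FALSE]
    ytr <- labels[!te]
    xte <- features[te, , drop = FALSE]
    yte <- labels[te]

    inner <- .stratifiedFolds(ytr, innerK, .childSeed(seed, f))
    meta_tr <- matrix(NA_real_, nrow(xtr), length(base),
                      dimnames = list(NULL, names(base)))
    for (g in seq_len(innerK)) {
      ite <- inner == g
      for (b in seq_along(base)) {
        pred <- base[[b]](xtr[!ite, , drop = FALSE], ytr[!ite],
                          .childSeed(seed, f * 100L + g * 10L + b))
        meta_tr[ite, b] <- pred(xtr[ite, , drop = FALSE])
      }
    }
    meta_fit <- .fitMetaTree(meta_tr, ytr)

    meta_te <- matrix(NA_real_, nrow(xte), length(base),
                      dimnames = list(NULL, names(base)))
    for (b in seq_along(base)) {
      pred <- base[[b]](xtr, ytr, .childSeed(seed, f * 100L + b))
      meta_te[, b] <- pred(xte)
    }
    score <- predict(meta_fit, as.data.frame(meta_te))[, "case"]
    aucs[f] <- .aucRank(score, yte == "case")
  }
  structure(list(per_fold_auc = aucs, mean_auc = mean(aucs), k = k),
            class = "riskRun")
}

#' @export
print.riskRun <- function(x, ...) {
  cat("Stacked risk run:", x$k, "folds, mean AUC",
      sprintf("%.3f", x$mean_auc), "\n")
  invisible(x)
}

#' Compare two cross-validated risk runs
#'
#' Two-sided t-test between the per-fold AUC distributions of two runs
#' (unpaired by default; set \code{paired = TRUE} when both runs used the
#' identical fold split).  Degenerate zero-variance comparisons are
#' reported with \code{p} below machine epsilon and flagged.
#'
#' @param a,b \code{"riskRun"} objects with equal fold counts.
#' @param paired use a paired test.
#' @return list with \code{t}, \code{p}, \code{mean_diff},
#'   \code{degenerate}.
#' @export
compareRuns <- function(a, b, paired = FALSE) {
  if (a$k != b$k) stop("runs must have the same number of folds")
  if (a$k < 2L) stop("need at least 2 folds to compare")
  mean_diff <- a$mean_auc - b$mean_auc
  if (sd(a$per_fold_auc) == 0 && sd(b$per_fold_auc) == 0) {
    if (mean_diff == 0) {
      return(list(t = 0, p = 1, mean_diff = 0, degenerate = TRUE))
    }
    return(list(t = sign(mean_diff) * Inf, p = .Machine$double.xmin,
                mean_diff = mean_diff, degenerate = TRUE))
  }
  tt <- t.test(a$per_fold_auc, b$per_fold_auc, paired = paired)
  list(t = unname(tt$statistic), p = tt$p.value, mean_diff = mean_diff,
       degenerate = FALSE)
}
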