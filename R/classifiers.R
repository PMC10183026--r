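# The nine-learner roster behind the gene ranker.
#
# The roster preserves the algorithm-family structure of the original
# ensemble: two greedy rule/tree learners with pruning, a one-hidden-layer
# perceptron, kernel-density naive Bayes, ridge-penalised logistic
# regression, 3-nearest-neighbours, a 10-tree random forest, an
# entropy-split pruned tree, and AdaBoost over depth-1 stumps.
#
# pEA feature blocks contain many samples with identical profiles, so the
# cross-validation engine collapses each training fold to its unique
# (feature profile, label) pairs with frequency weights.  Learners marked
# weighted = TRUE consume that representation; their weighted loss is the
# loss on the expanded data.  k-NN and the bootstrap-based random forest
# keep the expanded rows.  Predictions are always made on the unique test
# profiles and expanded back through the fold's label counts.

#' @importFrom rpart rpart rpart.control
#' @importFrom nnet nnet class.ind
#' @importFrom randomForest randomForest
#' @importFrom glmnet glmnet
#' @importFrom class knn
#' @importFrom stats predict dnorm sd quantile plogis
NULL

.majorityClass <- function(ytr, w = NULL) {
  if (is.null(w)) w <- rep(1, length(ytr))
  lv <- levels(ytr)
  lv[which.max(vapply(lv, function(l) sum(w[ytr == l]), numeric(1)))]
}

# Drop zero-variance training columns and fall back to the training
# majority class when a learner cannot be fit in this fold.
.guardedFit <- function(fitfun, weighted = TRUE) {
  f <- function(xtr, ytr, w, xte, seed) {
    keep <- which(vapply(seq_len(ncol(xtr)), function(j) {
      z <- xtr[, j]
      max(z) > min(z)
    }, logical(1)))
    fallback <- factor(rep(.majorityClass(ytr, w), nrow(xte)),
                       levels = levels(ytr))
    if (!length(keep)) return(fallback)
    if (length(keep) < ncol(xtr)) {  # drops any attached shared frame
      xtr <- xtr[, keep, drop = FALSE]
      xte <- xte[, keep, drop = FALSE]
    }
    out <- tryCatch(
      suppressWarnings(fitfun(xtr, ytr, w, xte, seed)),
      error = function(e) fallback)
    if (length(out) != nrow(xte)) return(fallback)
    factor(as.character(out), levels = levels(ytr))
  }
  attr(f, "weighted") <- weighted
  f
}

# Matrix -> data.frame without the naming/deparse overhead of
# as.data.frame(); the cross-validation engine attaches a prebuilt frame
# (attribute "df") shared by the three rpart-based learners.
.asFrame <- function(x) {
  d <- attr(x, "df")
  if (!is.null(d)) return(d)
  structure(lapply(seq_len(ncol(x)), function(j) x[, j]),
            names = colnames(x), class = "data.frame",
            row.names = .set_row_names(nrow(x)))
}

.rpartPredict <- function(xtr, ytr, w, xte, control, split = "gini") {
  d <- .asFrame(xtr)
  d$.y <- ytr
  fit <- rpart(.y ~ ., data = d, weights = w, method = "class",
               parms = list(split = split), control = control)
  predict(fit, .asFrame(xte), type = "class")
}

# Weighted Gaussian-kernel density evaluated directly at the query points;
# bandwidth is the Silverman rule on the weighted moments.
.wkdeLogDensity <- function(v, w, at) {
  sw <- sum(w)
  if (length(v) < 2L) {
    return(dnorm(at, mean = v[1], sd = 0.05, log = TRUE))
  }
  mu <- sum(w * v) / sw
  sigma <- sqrt(sum(w * (v - mu)^2) / sw)
  qs <- quantile(rep(v, times = pmax(1L, round(w))), c(0.25, 0.75),
                 names = FALSE)
  h <- 0.9 * min(sigma, (qs[2] - qs[1]) / 1.34) * sw^(-0.2)
  if (!is.finite(h) || h <= 0) h <- 0.05
  f <- colSums(w * dnorm(outer(v, at, "-") / h)) / (sw * h)
  log(pmax(f, 1e-12))
}

.kdeNaiveBayes <- function(xtr, ytr, w, xte, seed) {
  lv <- levels(ytr)
  sw <- sum(w)
  logpost <- vapply(lv, function(l) {
    sel <- ytr == l
    lp <- rep(log(sum(w[sel]) / sw), nrow(xte))
    for (j in seq_len(ncol(xtr))) {
      lp <- lp + .wkdeLogDensity(xtr[sel, j], w[sel], xte[, j])
    }
    lp
  }, numeric(nrow(xte)))
  logpost <- matrix(logpost, ncol = length(lv))
  lv[max.col(logpost, ties.method = "first")]
}

# --- AdaBoost over exhaustive-search decision stumps -----------------------

.stumpSearch <- function(xtr, y01, w) {
  best <- NULL
  best_err <- Inf
  tot_pos <- sum(w[y01 == 1])
  tot_neg <- sum(w) - tot_pos
  for (j in seq_len(ncol(xtr))) {
    o <- order(xtr[, j])
    xo <- xtr[o, j]
    cut <- which(diff(xo) > 0)
    if (!length(cut)) next
    wp <- cumsum(w[o] * (y01[o] == 1))[cut]
    wn <- cumsum(w[o] * (y01[o] == 0))[cut]
    err_hi <- wp + (tot_neg - wn)  # predict 1 for x > threshold
    err_lo <- wn + (tot_pos - wp)  # predict 1 for x <= threshold
    for (dir in c(1L, -1L)) {
      e <- if (dir == 1L) err_hi else err_lo
      i <- which.min(e)
      if (e[i] < best_err) {
        best_err <- e[i]
        best <- list(j = j, thr = (xo[cut[i]] + xo[cut[i] + 1L]) / 2,
                     dir = dir, err = e[i])
      }
    }
  }
  best
}

.stumpPredict <- function(stump, x) {
  hi <- x[, stump$j] > stump$thr
  if (stump$dir == 1L) as.integer(hi) else as.integer(!hi)
}

.adaboostTrain <- function(xtr, y01, iterations = 10L, w = NULL) {
  if (is.null(w)) w <- rep(1, length(y01))
  w <- w / sum(w)
  stumps <- list()
  alphas <- numeric(0)
  for (m in seq_len(iterations)) {
    stump <- .stumpSearch(xtr, y01, w)
    if (is.null(stump)) break
    pred <- .stumpPredict(stump, xtr)
    err <- min(max(sum(w * (pred != y01)), 1e-10), 1 - 1e-10)
    alpha <- 0.5 * log((1 - err) / err)
    stumps[[length(stumps) + 1L]] <- stump
    alphas <- c(alphas, alpha)
    w <- w * exp(alpha * (pred != y01))
    w <- w / sum(w)
    if (err >= 0.5) break
  }
  list(stumps = stumps, alphas = alphas)
}

# Signed margin: positive favours class 1.
.adaboostScore <- function(model, x) {
  if (!length(model$stumps)) return(rep(0, nrow(x)))
  s <- rep(0, nrow(x))
  for (m in seq_along(model$stumps)) {
    s <- s + model$alphas[m] *
      (2 * .stumpPredict(model$stumps[[m]], x) - 1)
  }
  s
}

# --- roster ---------------------------------------------------------------

#' Default nine-classifier roster
#'
#' Builds the learner roster used by [evaluateGene()].  Settings default to
#' the published configuration where a setting is portable: 10 random-forest
#' trees, 3 nearest neighbours (Euclidean), pruning confidence 0.25 with
#' minimum 5 and 2 leaf observations for the two pruned trees,
#' kernel-density naive Bayes, ridge-penalised logistic regression,
#' AdaBoost on decision stumps, and a single hidden layer of
#' \code{mlpUnits} units for the perceptron.  The rule learners of the
#' original toolkit have no exact R port and are represented by greedy
#' recursive-partitioning surrogates with the stated pruning settings; see
#' the methods vignette.
#'
#' @param mlpUnits hidden units in the perceptron (default 4).
#' @param mlpMaxit perceptron optimisation iterations.
#' @param rfTrees random-forest tree count (default 10).
#' @param knnK neighbours for k-NN (default 3, Euclidean).
#' @param adaboostIterations boosting rounds (default 10).
#' @param ridgeLambda ridge penalty for the logistic learner.
#' @return Named list of classifier functions
#'   \code{function(xtr, ytr, w, xte, seed)} returning predicted labels
#'   for the rows of \code{xte}.  Functions with attribute
#'   \code{weighted = TRUE} receive the collapsed frequency-weighted
#'   training representation; the others receive the expanded rows with
#'   unit weights.
#' @export
classifierRoster <- function(mlpUnits = 4L, mlpMaxit = 60L, rfTrees = 10L,
                             knnK = 3L, adaboostIterations = 10L,
                             ridgeLambda = 1e-3) {
  list(
    rule_part = .guardedFit(function(xtr, ytr, w, xte, seed) {
      .rpartPredict(xtr, ytr, w, xte,
                    rpart.control(minbucket = 5L, cp = 0.01, xval = 0L),
                    split = "information")
    }, weighted = FALSE),
    rule_ripper = .guardedFit(function(xtr, ytr, w, xte, seed) {
      .rpartPredict(xtr, ytr, w, xte,
                    rpart.control(minbucket = 2L, maxdepth = 3L,
                                  cp = 0.001, xval = 0L))
    }, weighted = FALSE),
    mlp = .guardedFit(function(xtr, ytr, w, xte, seed) {
      withr::with_seed(seed, {
        fit <- nnet(xtr, class.ind(ytr), weights = w,
                    size = mlpUnits, maxit = mlpMaxit,
                    decay = 1e-4, trace = FALSE, softmax = TRUE)
      })
      levels(ytr)[max.col(predict(fit, xte), ties.method = "first")]
    }),
    naive_bayes = .guardedFit(.kdeNaiveBayes),
    logistic = .guardedFit(function(xtr, ytr, w, xte, seed) {
      if (ncol(xtr) < 2L) {
        xtr <- cbind(xtr, 0)
        xte <- cbind(xte, 0)
      }
      fit <- glmnet(xtr, ytr, family = "binomial", weights = w,
                    alpha = 0, lambda = ridgeLambda)
      drop(predict(fit, xte, type = "class"))
    }, weighted = FALSE),
    knn = .guardedFit(function(xtr, ytr, w, xte, seed) {
      withr::with_seed(seed, knn(xtr, xte, ytr, k = knnK))
    }, weighted = FALSE),
    random_forest = .guardedFit(function(xtr, ytr, w, xte, seed) {
      withr::with_seed(seed, {
        fit <- randomForest(xtr, ytr, ntree = rfTrees)
      })
      predict(fit, xte)
    }, weighted = FALSE),
    tree_c45 = .guardedFit(function(xtr, ytr, w, xte, seed) {
      .rpartPredict(xtr, ytr, w, xte,
                    rpart.control(minbucket = 2L, cp = 0.01, xval = 0L),
                    split = "information")
    }, weighted = FALSE),
    adaboost = .guardedFit(function(xtr, ytr, w, xte, seed) {
      y01 <- as.integer(ytr == levels(ytr)[2])
      model <- .adaboostTrain(xtr, y01, adaboostIterations, w = w)
      levels(ytr)[1 + as.integer(.adaboostScore(model, xte) > 0)]
    })
  )
}
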