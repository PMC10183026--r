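test_that("gene feature vectors take the dominant low-threshold pEA", {
  co <- tinyCohort()
  pea <- buildDesignMatrix(co)
  m <- buildGeneFeatures(c("GA", "GB"), pea)
  expect_equal(colnames(m), c("GA", "GB"))
  # S1: het missense EA=80 in GA -> 0.8; synonymous in GB -> 0
  expect_equal(unname(m["S1", ]), c(0.8, 0))
  # S4: het EA=20 qualifies at C = 1 -> 0.2
  expect_equal(unname(m["S4", "GB"]), 0.2)
  expect_error(buildGeneFeatures("NOPE", pea), "not present")
})

test_that("baseline features follow the APOE-pEA + z-scored age contract", {
  s <- data.frame(sample_id = c("S1", "S2"),
                  phenotype = c("case", "control"), sex = "unknown",
                  age = c(60, 70), apoe_genotype = NA_character_)
  apoe <- data.frame(sample_id = "S1", gene = "APOE",
                     variant_class = "missense", ea = 50, zygosity = "het")
  m <- buildBaselineFeatures(s, apoe)
  expect_equal(unname(m[, "apoe_pea"]), c(0.5, 0))
  # sample-sd z-score of (60, 70)
  expect_equal(unname(m[, "age"]), c(-5, 5) / sd(c(60, 70)))
  raw <- buildBaselineFeatures(s, apoe, normalizeAge = "none")
  expect_equal(unname(raw[, "age"]), c(60, 70))

  s$age[2] <- NA
  expect_error(buildBaselineFeatures(s, apoe), "S2")
  s$age <- 64
  expect_error(buildBaselineFeatures(s, apoe), "zero age variance")
})

test_that("rank AUC agrees with pROC and is monotone-invariant", {
  skip_if_not_installed("pROC")
  withr::local_seed(23)
  for (i in 1:20) {
    y <- sample(c(TRUE, FALSE), 50, replace = TRUE)
    if (length(unique(y)) < 2) next
    sc <- round(rnorm(50), 1)  # ties included
    ref <- as.numeric(suppressMessages(
      pROC::auc(pROC::roc(y, sc, direction = "<", quiet = TRUE))))
    expect_equal(eamlr:::.aucRank(sc, y), ref, tolerance = 1e-12)
    expect_equal(eamlr:::.aucRank(exp(sc), y), eamlr:::.aucRank(sc, y))
  }
})

test_that("a perfectly separating feature gives AUC 1 in every fold", {
  labels <- factor(rep(c("case", "control"), each = 30),
                   levels = c("control", "case"))
  feat <- cbind(score = as.numeric(labels == "case"))
  run <- trainStacked(feat, labels, k = 5, seed = 2)
  expect_equal(run$per_fold_auc, rep(1, 5))
  expect_equal(run$mean_auc, 1)
})

test_that("stacked training is reproducible and rejects empty features", {
  co <- cached("simPlantedSmall", simulateCohort(
    simConfig(n_genes = 20, n_cases = 80, n_controls = 80,
              planted = plantedGenes(2, beta = log(4))), seed = 19))
  pea <- buildDesignMatrix(co)
  feats <- buildGeneFeatures(c("APOE", "RISK01", "RISK02"), pea)
  lab <- caseLabels(pea)
  r1 <- trainStacked(feats, lab, k = 5, seed = 3, rfTrees = 30)
  r2 <- trainStacked(feats, lab, k = 5, seed = 3, rfTrees = 30)
  expect_identical(r1$per_fold_auc, r2$per_fold_auc)
  expect_equal(r1$mean_auc, mean(r1$per_fold_auc))
  expect_error(trainStacked(feats[, 0, drop = FALSE], lab), "at least one")
})

test_that("stacking does not fall far below its best base learner", {
  co <- cached("simPlantedSmall", simulateCohort(
    simConfig(n_genes = 20, n_cases = 80, n_controls = 80,
              planted = plantedGenes(2, beta = log(4))), seed = 19))
  pea <- buildDesignMatrix(co)
  feats <- buildGeneFeatures(c("APOE", "RISK01", "RISK02"), pea)
  lab <- caseLabels(pea)
  stacked <- trainStacked(feats, lab, k = 5, seed = 3, rfTrees = 30)

  # single-learner reference: ridge logistic scores under the same folds
  folds <- eamlr:::.stratifiedFolds(lab, 5, 3)
  base_auc <- vapply(1:5, function(f) {
    te <- folds == f
    fit <- glmnet::glmnet(feats[!te, , drop = FALSE], lab[!te],
                          family = "binomial", alpha = 0, lambda = 1e-3)
    sc <- drop(predict(fit, feats[te, , drop = FALSE]))
    eamlr:::.aucRank(sc, lab[te] == "case")
  }, numeric(1))
  expect_gte(stacked$mean_auc, mean(base_auc) - 0.05)
})

test_that("gene-feature discrimination is bounded by the liability ceiling", {
  # Bayes-optimal AUC of the gene-feature representation under the
  # reference planted-cohort conditions (10 dominant genes, carrier
  # frequency 0.1, odds ratio 2.5, APOE-like and age covariates at their
  # generator defaults), computed from the liability model itself: no
  # classifier trained on the gene features can beat the AUC of the true
  # gene-plus-APOE linear predictor.
  withr::local_seed(3)
  n <- 4e5
  carriers <- matrix(rbinom(n * 10, 1, 0.1), n, 10)
  g1 <- rbinom(n, 2, 0.15)
  g2 <- rbinom(n, 2, 0.10)
  apoe_pea <- 1 - (1 - 0.85)^g1 * (1 - 0.40)^g2
  age <- pmin(pmax(rnorm(n, 74, 6), 55), 95)
  eta_gene <- rowSums(carriers) * log(2.5) + 1.2 * apoe_pea
  eta <- eta_gene + 0.04 * (age - mean(age))
  b0 <- uniroot(function(b) mean(plogis(b + eta)) - 0.5, c(-10, 10))$root
  y <- rbinom(n, 1, plogis(b0 + eta))
  ceiling_auc <- eamlr:::.aucRank(eta_gene, y == 1)
  expect_lt(ceiling_auc, 0.75)  # documented in the methods vignette
  expect_gt(ceiling_auc, 0.70)
})

test_that("run comparison handles identity, separation and symmetry", {
  a <- structure(list(per_fold_auc = c(0.8, 0.85, 0.9), mean_auc = 0.85,
                      k = 3L), class = "riskRun")
  expect_equal(compareRuns(a, a)$p, 1)
  expect_equal(compareRuns(a, a)$t, 0)

  b <- structure(list(per_fold_auc = c(0.5, 0.55, 0.6), mean_auc = 0.55,
                      k = 3L), class = "riskRun")
  cab <- compareRuns(a, b)
  cba <- compareRuns(b, a)
  expect_equal(cab$t, -cba$t)
  expect_equal(cab$p, cba$p)

  # degenerate zero-variance comparison is flagged, p below epsilon
  c1 <- structure(list(per_fold_auc = rep(0.9, 3), mean_auc = 0.9, k = 3L),
                  class = "riskRun")
  c2 <- structure(list(per_fold_auc = rep(0.5, 3), mean_auc = 0.5, k = 3L),
                  class = "riskRun")
  cmp <- compareRuns(c1, c2)
  expect_true(cmp$degenerate)
  expect_lt(cmp$p, .Machine$double.eps)
  expect_error(compareRuns(a, structure(list(per_fold_auc = 0.5,
                                             mean_auc = 0.5, k = 1L),
                                        class = "riskRun")),
               "same number of folds")
})
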