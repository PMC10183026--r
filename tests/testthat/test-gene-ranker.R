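test_that("MCC matches hand-computed values and conventions", {
  expect_equal(mccScore(5, 5, 0, 0), 1)
  expect_equal(mccScore(25, 25, 25, 25), 0)
  expect_equal(mccScore(3, 4, 1, 2), 10 / sqrt(600))
  expect_equal(mccScore(0, 5, 0, 5), 0)  # zero-denominator convention
  expect_error(mccScore(-1, 2, 3, 4), ">= 0")
})

test_that("MCC is symmetric under class swap and antisymmetric under flip", {
  withr::local_seed(1)
  ok <- vapply(1:1000, function(i) {
    cm <- sample(0:30, 4, replace = TRUE)
    m <- mccScore(cm[1], cm[2], cm[3], cm[4])
    mccScore(cm[2], cm[1], cm[4], cm[3]) == m &&
      mccScore(cm[4], cm[3], cm[2], cm[1]) == -m &&
      m >= -1 && m <= 1
  }, logical(1))
  expect_true(all(ok))
})

test_that("a perfectly separating gene scores MCC 1 for every classifier", {
  co <- separableCohort(30)
  pea <- buildDesignMatrix(co)
  ev <- evaluateGene(geneFeatureSlice(pea, "GSEP"), caseLabels(pea),
                     cv = cvConfig(k = 10, seed = 2))
  expect_equal(unname(ev$mcc_by_classifier),
               rep(1, 9), tolerance = 1e-12)
  expect_equal(ev$mean_mcc, 1)
  # direct threshold rule agrees: carriers are exactly the cases
  block <- geneFeatureSlice(pea, "GSEP")
  expect_equal(unname(block[, 1] == 1),
               unname(caseLabels(pea) == "case"))
})

test_that("all-constant features are flagged and scored 0 without fitting", {
  labels <- factor(rep(c("control", "case"), each = 20),
                   levels = c("control", "case"))
  feat <- matrix(0, 40, 6)
  ev <- evaluateGene(feat, labels, cv = cvConfig(seed = 1))
  expect_true(ev$constant)
  expect_equal(ev$mean_mcc, 0)
  expect_error(evaluateGene(feat, factor(rep("case", 40),
                                         levels = c("control", "case"))),
               "both classes")
})

test_that("fold assignment partitions samples with stratification", {
  labels <- factor(rep(c("control", "case"), c(55, 45)),
                   levels = c("control", "case"))
  folds <- eamlr:::.stratifiedFolds(labels, 10, seed = 4)
  expect_equal(sort(unique(folds)), 1:10)
  expect_equal(length(folds), 100L)
  per_fold_cases <- tapply(labels == "case", folds, sum)
  expect_true(max(per_fold_cases) - min(per_fold_cases) <= 1)
  expect_identical(folds, eamlr:::.stratifiedFolds(labels, 10, seed = 4))
})

test_that("empirical p, BH adjustment and ranking behave as defined", {
  res <- data.frame(gene = c("G1", "G2", "G3"),
                    c1 = c(0.5, 0.2, 0.01), c2 = c(0.5, 0.2, 0.01),
                    mean_mcc = c(0.5, 0.2, 0.01),
                    n_carriers = 5, constant = FALSE)
  attr(res, "classifiers") <- c("c1", "c2")
  null99 <- seq(0.011, 0.199, length.out = 99)
  rk <- rankGenes(res, null_mccs = null99)
  # mean MCC above all 99 null values -> p = 1/100
  expect_equal(rk$p[rk$gene == "G1"], 0.01)
  expect_equal(rk$rank, 1:3)
  expect_true(all(rk$q >= rk$p))
  expect_error(rankGenes(res, null_mccs = numeric(0)), "non-empty")

  # hand BH: (0.001, 0.02, 0.9) -> (0.003, 0.03, 0.9)
  expect_equal(p.adjust(c(0.001, 0.02, 0.9), "BH"), c(0.003, 0.03, 0.9))
  expect_equal(p.adjust(rep(0.2, 4), "BH"), rep(0.2, 4))
})

test_that("rank ties break by best single-classifier MCC then gene name", {
  res <- data.frame(gene = c("GB", "GA", "GC"),
                    c1 = c(0.3, 0.4, 0.4), c2 = c(0.3, 0.2, 0.2),
                    mean_mcc = c(0.3, 0.3, 0.3),
                    n_carriers = 5, constant = FALSE)
  attr(res, "classifiers") <- c("c1", "c2")
  rk <- rankGenes(res, method = "parametric")
  expect_equal(rk$gene, c("GA", "GC", "GB"))
})

test_that("evaluateAllGenes excludes carrier-free genes and is seeded", {
  co <- cached("simSmall", simulateCohort(
    simConfig(n_genes = 15, n_cases = 40, n_controls = 40), seed = 3))
  pea <- buildDesignMatrix(co)
  r1 <- evaluateAllGenes(pea, cv = cvConfig(seed = 5))
  r2 <- evaluateAllGenes(pea, cv = cvConfig(seed = 5))
  expect_identical(r1, r2)
  expect_setequal(c(r1$gene, attr(r1, "excluded")), geneIds(pea))
})

test_that("permutation null is seeded and stable under doubling B", {
  co <- cached("simSmall", simulateCohort(
    simConfig(n_genes = 15, n_cases = 40, n_controls = 40), seed = 3))
  pea <- buildDesignMatrix(co)
  n1 <- permuteNull(pea, cv = cvConfig(seed = 5), B = 3,
                    genesFraction = 0.2, seed = 9)
  n2 <- permuteNull(pea, cv = cvConfig(seed = 5), B = 3,
                    genesFraction = 0.2, seed = 9)
  expect_identical(n1, n2)
  expect_error(permuteNull(pea, B = 0), "B must be")

  # doubling the null can move an empirical p by at most 2/(B+1)
  res <- evaluateAllGenes(pea, cv = cvConfig(seed = 5))
  n4 <- permuteNull(pea, cv = cvConfig(seed = 5), B = 6,
                    genesFraction = 0.2, seed = 9)
  p1 <- rankGenes(res, n1)$p
  p2 <- rankGenes(res, n4)$p
  expect_true(all(abs(p1 - p2) <= 2 / (length(n1) + 1) + 1e-12))
})

test_that("sex-stratified runs partition the cohort and skip thin strata", {
  co <- cached("simSexed", simulateCohort(
    simConfig(n_genes = 10, n_cases = 60, n_controls = 60), seed = 13))
  s <- sampleInfo(co)
  expect_equal(sum(s$sex == "male") + sum(s$sex == "female"), nrow(s))
  out <- runSexStratified(co, cv = cvConfig(k = 2, seed = 3),
                          method = "parametric")
  expect_named(out, c("combined", "male", "female", "overlap",
                      "significant"))
  expect_equal(nrow(out$combined),
               length(geneIds(buildDesignMatrix(co))))
  # a stratum below 2k per class is skipped with a warning
  tiny <- cohortSubset(co, s$sample_id[c(which(s$sex == "male")[1:3],
                                         which(s$sex == "female"))])
  expect_warning(out2 <- runSexStratified(
    tiny, cv = cvConfig(k = 2, seed = 3), method = "parametric"),
    "skipped")
  expect_null(out2$male)
})
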