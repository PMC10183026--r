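test_that("pEA reproduces the defining cases", {
  syn <- data.frame(variant_class = "synonymous", ea = NA_real_,
                    zygosity = "het")
  expect_equal(computePEA(syn, "dominant", 1), 0)

  stopv <- data.frame(variant_class = "stop_or_frameshift", ea = NA_real_,
                      zygosity = "het")
  for (C in c(1, 30, 70)) expect_equal(computePEA(stopv, "dominant", C), 1)
  # a het stop contributes nothing to recessive features
  expect_equal(computePEA(stopv, "recessive", 1), 0)

  mis <- data.frame(variant_class = "missense", ea = 50, zygosity = "het")
  expect_equal(computePEA(mis, "dominant", 30), 0.5)
  hom <- data.frame(variant_class = "missense", ea = 50, zygosity = "hom")
  expect_equal(computePEA(hom, "recessive", 1), 0.75)
  low <- data.frame(variant_class = "missense", ea = 20, zygosity = "het")
  expect_equal(computePEA(low, "dominant", 30), 0)
  # threshold is a strict inequality
  eq <- data.frame(variant_class = "missense", ea = 30, zygosity = "het")
  expect_equal(computePEA(eq, "dominant", 30), 0)

  two <- data.frame(variant_class = c("missense", "missense"),
                    ea = c(50, 40), zygosity = c("het", "hom"))
  expect_equal(computePEA(two, "dominant", 1), 0.82)

  hemi <- data.frame(variant_class = "missense", ea = 50, zygosity = "hemi")
  expect_equal(computePEA(hemi, "recessive", 1), 0.75)

  miss_ea <- data.frame(variant_class = "missense", ea = NA_real_,
                        zygosity = "het")
  expect_warning(p <- computePEA(miss_ea, "dominant", 1), "missing EA")
  expect_equal(p, 0)
})

test_that("pEA agrees with the brute-force product oracle on random cells", {
  withr::local_seed(42)
  n_cells <- 2000
  specs <- featureSpecs()
  err <- vapply(seq_len(n_cells), function(i) {
    rec <- randomCell(sample(1:6, 1))
    k <- sample(nrow(specs), 1)
    abs(suppressWarnings(
      computePEA(rec, specs$mode[k], specs$threshold[k])) -
      bruteForcePEA(rec, specs$mode[k], specs$threshold[k]))
  }, numeric(1))
  expect_lt(max(err), 1e-12)
})

test_that("pEA is monotone in added variants, mode and threshold", {
  withr::local_seed(7)
  ok <- vapply(1:300, function(i) {
    rec <- randomCell(sample(2:6, 1))
    extra <- randomCell(1)
    good <- TRUE
    for (mode in c("dominant", "recessive")) {
      vals <- vapply(c(1, 30, 70), function(C) {
        suppressWarnings(computePEA(rec, mode, C))
      }, numeric(1))
      good <- good && all(diff(vals) <= 1e-12) &&          # C-monotone
        suppressWarnings(computePEA(rbind(rec, extra), mode, 1)) >=
          vals[1] - 1e-12                                  # add-monotone
    }
    for (C in c(1, 30, 70)) {                              # dom >= rec
      good <- good &&
        suppressWarnings(computePEA(rec, "dominant", C)) >=
          suppressWarnings(computePEA(rec, "recessive", C)) - 1e-12
    }
    perm <- rec[sample(nrow(rec)), , drop = FALSE]         # order-free
    good && suppressWarnings(computePEA(perm, "dominant", 30)) ==
      suppressWarnings(computePEA(rec, "dominant", 30))
  }, logical(1))
  expect_true(all(ok))
})

test_that("design matrix cells equal computePEA and respect invariants", {
  co <- cached("simSmall", simulateCohort(
    simConfig(n_genes = 15, n_cases = 40, n_controls = 40), seed = 3))
  pea <- buildDesignMatrix(co)
  a <- SummarizedExperiment::assay(pea, "pEA")
  expect_true(all(a >= 0 & a <= 1))
  expect_equal(ncol(a), 80L)

  v <- variantRecords(co)
  specs <- featureSpecs()
  withr::local_seed(11)
  for (i in 1:50) {
    g <- sample(geneIds(pea), 1)
    sid <- sample(sampleInfo(co)$sample_id, 1)
    k <- sample(6, 1)
    rec <- v[v$gene == g & v$sample_id == sid, , drop = FALSE]
    cell <- a[paste(g, specs$mode[k], specs$threshold[k], sep = "::"), sid]
    expect_equal(cell, computePEA(rec, specs$mode[k], specs$threshold[k]),
                 tolerance = 1e-12)
  }

  # dominant >= recessive; non-increasing in threshold, for every cell
  rd <- SummarizedExperiment::rowData(pea)
  for (g in geneIds(pea)) {
    block <- geneFeatureSlice(pea, g)
    expect_true(all(block[, 1:3] - block[, 4:6] >= -1e-12))
    expect_true(all(block[, 1] - block[, 2] >= -1e-12))
    expect_true(all(block[, 2] - block[, 3] >= -1e-12))
  }
})

test_that("single-variant design examples give the stated feature rows", {
  v <- data.frame(sample_id = c("A", "B"), gene = "G1",
                  variant_class = "missense",
                  ea = c(80, 40), zygosity = c("het", "hom"))
  s <- data.frame(sample_id = c("A", "B", "C"),
                  phenotype = c("case", "control", "control"),
                  sex = "unknown", age = NA_real_,
                  apoe_genotype = NA_character_)
  pea <- buildDesignMatrix(EamlCohort(v, s))
  block <- geneFeatureSlice(pea, "G1")
  # het EA=80: dominant 0.8 at all C (80 > 70), recessive all 0
  expect_equal(unname(block["A", ]), c(0.8, 0.8, 0.8, 0, 0, 0))
  # hom EA=40: 1 - 0.6^2 = 0.64 at C in {1,30}, 0 at C=70, both modes
  expect_equal(unname(block["B", ]), c(0.64, 0.64, 0, 0.64, 0.64, 0))
  # sample with no variants: all-zero row
  expect_equal(unname(block["C", ]), rep(0, 6))
})

test_that("gene slices partition the design matrix and are stable", {
  co <- cached("simSmall", simulateCohort(
    simConfig(n_genes = 15, n_cases = 40, n_controls = 40), seed = 3))
  pea <- buildDesignMatrix(co)
  a <- SummarizedExperiment::assay(pea, "pEA")
  reassembled <- do.call(cbind, lapply(geneIds(pea), function(g) {
    geneFeatureSlice(pea, g)
  }))
  expect_equal(dim(reassembled), rev(dim(a)))
  expect_equal(sort(unname(colSums(reassembled))),
               sort(unname(rowSums(a))))
  expect_identical(geneFeatureSlice(pea, geneIds(pea)[2]),
                   geneFeatureSlice(pea, geneIds(pea)[2]))
  expect_error(geneFeatureSlice(pea, "NOT_A_GENE"), "not present")
})

test_that("variants for unknown samples are rejected with offenders named", {
  v <- data.frame(sample_id = "GHOST", gene = "G1",
                  variant_class = "missense", ea = 50, zygosity = "het")
  s <- data.frame(sample_id = "S1", phenotype = "case", sex = "unknown",
                  age = NA_real_, apoe_genotype = NA_character_)
  expect_error(EamlCohort(v, s), "GHOST")
})
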