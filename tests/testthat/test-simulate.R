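test_that("simulation is byte-identical under one seed", {
  cfg <- simConfig(n_genes = 10, n_cases = 30, n_controls = 30,
                   planted = plantedGenes(1, beta = log(3)))
  a <- simulateCohort(cfg, seed = 5)
  b <- simulateCohort(cfg, seed = 5)
  expect_identical(variantRecords(a), variantRecords(b))
  expect_identical(sampleInfo(a), sampleInfo(b))
  expect_identical(cohortMetadata(a)$truth, cohortMetadata(b)$truth)
  c <- simulateCohort(cfg, seed = 6)
  expect_false(identical(variantRecords(a), variantRecords(c)))
})

test_that("cohorts have the requested composition and valid records", {
  co <- cached("simSmall", simulateCohort(
    simConfig(n_genes = 15, n_cases = 40, n_controls = 40), seed = 3))
  s <- sampleInfo(co)
  expect_equal(sum(s$phenotype == "case"), 40)
  expect_equal(sum(s$phenotype == "control"), 40)
  expect_true(all(s$age >= 55 & s$age <= 95))
  v <- variantRecords(co)
  expect_true(all(v$zygosity %in% c("het", "hom")))
  expect_true(all(is.na(v$ea) | (v$ea >= 0 & v$ea <= 100)))
  expect_true(all(!is.na(v$ea[v$variant_class == "missense"])))
  expect_true("APOE" %in% v$gene)
})

test_that("re-estimated MAFs are unbiased for common sites", {
  # one common site observed through many genotypes: carrier counts must
  # recover the MAF within 3 binomial SEs
  cfg <- simConfig(n_genes = 60, n_cases = 150, n_controls = 150,
                   maf_shape1 = 2, maf_shape2 = 5)  # common variants
  co <- simulateCohort(cfg, seed = 23)
  v <- variantRecords(co)
  n <- nrow(sampleInfo(co))
  # allele count per gene x ea (site key): het = 1, hom = 2
  v$alleles <- ifelse(v$zygosity == "hom", 2L, 1L)
  key <- paste(v$gene, v$ea)
  counts <- tapply(v$alleles, key, sum)
  maf_hat <- counts / (2 * n)
  # aggregate check: estimated mean MAF near the Beta(2,5) mean
  expect_lt(abs(mean(maf_hat) - 2 / 7), 0.03)
})

test_that("null cohorts show no systematic case/control carrier gap", {
  co <- cached("simNull200",
               simulateCohort(simConfig(n_genes = 60, n_cases = 150,
                                        n_controls = 150), seed = 29))
  v <- variantRecords(co)
  s <- sampleInfo(co)
  cases <- s$sample_id[s$phenotype == "case"]
  diffs <- vapply(setdiff(unique(v$gene), "APOE"), function(g) {
    carr <- unique(v$sample_id[v$gene == g])
    mean(cases %in% carr) - mean(setdiff(s$sample_id, cases) %in% carr)
  }, numeric(1))
  se <- sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs)), 2 * se + 0.01)
})

test_that("planted dominant effects enrich carriers among cases", {
  cfg <- simConfig(n_genes = 30, n_cases = 300, n_controls = 300,
                   planted = plantedGenes(2, beta = log(3),
                                          carrier_freq = 0.1))
  co <- simulateCohort(cfg, seed = 31)
  tr <- cohortMetadata(co)$truth
  expect_equal(tr$planted$gene, c("RISK01", "RISK02"))
  # logistic expectation: carrier odds tripled among cases
  expect_true(all(tr$carrier_freq_case > tr$carrier_freq_control))
  # independent oracle for P(carrier | case): integrate the liability
  # model over the covariate distribution by Monte Carlo
  withr::local_seed(99)
  nmc <- 2e5
  g1 <- rbinom(nmc, 2, 0.15)
  g2 <- rbinom(nmc, 2, 0.10)
  apoe_pea <- 1 - (1 - 0.85)^g1 * (1 - 0.40)^g2
  age <- pmin(pmax(rnorm(nmc, 74, 6), 55), 95)
  cov <- 1.2 * apoe_pea + 0.04 * (age - mean(age))
  b0 <- tr$intercept
  p_case_carr <- mean(plogis(b0 + log(3) + cov))
  p_case_exp <- 0.1 * p_case_carr / 0.5
  se <- sqrt(p_case_exp * (1 - p_case_exp) / 300)
  expect_lt(abs(tr$carrier_freq_case[1] - p_case_exp), 3 * se + 0.02)
})

test_that("recessive planting produces homozygous high-EA carriers", {
  cfg <- simConfig(n_genes = 20, n_cases = 200, n_controls = 200,
                   planted = plantedGenes(1, mode = "recessive",
                                          beta = log(4),
                                          carrier_freq = 0.1))
  co <- simulateCohort(cfg, seed = 37)
  v <- variantRecords(co)
  hom_high <- v[v$gene == "RISK01" & v$zygosity == "hom" &
                  !is.na(v$ea) & v$ea > 70, ]
  expect_gt(nrow(hom_high), 10)
  tr <- cohortMetadata(co)$truth
  expect_gt(tr$carrier_freq_case, tr$carrier_freq_control)
})

test_that("synthetic networks are seeded, heavy-tailed and modular", {
  net1 <- simulateNetwork(1000, module_size = 25, seed = 41)
  net2 <- simulateNetwork(1000, module_size = 25, seed = 41)
  expect_identical(igraph::as_edgelist(net1$graph),
                   igraph::as_edgelist(net2$graph))
  deg <- igraph::degree(net1$graph)
  expect_gt(max(deg), 5 * median(deg))
  w <- igraph::E(net1$graph)$weight
  expect_true(all(w >= 400 & w <= 999))
  sub <- igraph::induced_subgraph(net1$graph, net1$module)
  expect_gte(igraph::edge_density(sub), 0.1 - 1e-9)
})
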