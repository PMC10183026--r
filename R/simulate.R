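#' @importFrom stats rbinom rpois rbeta runif rnorm plogis
NULL

#' Synthetic-cohort configuration
#'
#' Describes a case/control exome cohort with EA-annotated coding variants:
#' per-gene variant sites with Hardy-Weinberg genotypes at Beta-distributed
#' minor-allele frequencies, EA scores drawn from a mixture with a
#' high-impact tail, planted risk genes whose high-EA carriers have
#' elevated disease odds through a logistic liability (optionally
#' sex-restricted, dominant or recessive), an APOE-like two-site covariate
#' gene, and an age covariate.
#'
#' @param n_genes number of background genes.
#' @param n_cases,n_controls cohort sizes after case/control subsampling.
#' @param sites_per_gene mean of the Poisson site count per gene
#'   (default 8).
#' @param maf_shape1,maf_shape2 Beta parameters of the site MAF
#'   distribution on (0, 0.5\] (default Beta(0.2, 4)).
#' @param ea_tail_weight probability that a missense EA score is drawn from
#'   the high-impact Uniform(70, 100) tail instead of Uniform(0, 100).
#' @param class_probs probabilities of variant classes (missense,
#'   synonymous, stop_or_frameshift, inframe_indel) per site.
#' @param planted data.frame with columns \code{gene} (name; created in
#'   addition to the background genes), \code{mode} (\code{dominant} or
#'   \code{recessive}), \code{beta} (carrier log-odds), \code{ea_cut}
#'   (default 70), \code{sex} (\code{none}, \code{male}, \code{female}),
#'   \code{carrier_freq} (target population carrier frequency of the
#'   planted high-EA risk site, default 0.1).  NULL plants nothing.
#' @param apoe_effect log-odds per unit pEA of the APOE-like gene.
#' @param age_effect log-odds per year of age (centred).
#' @param base_rate target population case fraction the liability
#'   intercept is solved for.
#' @return list with class \code{"simConfig"}.
#' @export
simConfig <- function(n_genes = 100L, n_cases = 200L, n_controls = 200L,
                      sites_per_gene = 8, maf_shape1 = 0.2, maf_shape2 = 4,
                      ea_tail_weight = 0.1,
                      class_probs = c(missense = 0.82, synonymous = 0.12,
                                      stop_or_frameshift = 0.04,
                                      inframe_indel = 0.02),
                      planted = NULL, apoe_effect = 1.2,
                      age_effect = 0.04, base_rate = 0.5) {
  if (!is.null(planted)) {
    planted <- as.data.frame(planted)
    if (!"ea_cut" %in% names(planted)) planted$ea_cut <- 70
    if (!"sex" %in% names(planted)) planted$sex <- "none"
    if (!"carrier_freq" %in% names(planted)) planted$carrier_freq <- 0.1
    .assertChoice(planted$mode, c("dominant", "recessive"), "planted mode")
    .assertChoice(planted$sex, c("none", "male", "female"), "planted sex")
  }
  stopifnot(base_rate > 0, base_rate < 1,
            abs(sum(class_probs) - 1) < 1e-8)
  structure(list(n_genes = as.integer(n_genes),
                 n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 sites_per_gene = sites_per_gene,
                 maf_shape1 = maf_shape1, maf_shape2 = maf_shape2,
                 ea_tail_weight = ea_tail_weight,
                 class_probs = class_probs, planted = planted,
                 apoe_effect = apoe_effect, age_effect = age_effect,
                 base_rate = base_rate),
            class = "simConfig")
}

#' Planted-gene specification helper
#'
#' @param n number of planted genes.
#' @param mode inheritance mode of the planted effect.
#' @param beta carrier log odds ratio.
#' @param ea_cut EA threshold defining the risk carrier.
#' @param sex optional sex restriction of the effect.
#' @param carrier_freq target population carrier frequency.
#' @return data.frame suitable for the \code{planted} field of
#'   [simConfig()].
#' @export
plantedGenes <- function(n, mode = "dominant", beta = log(2.5),
                         ea_cut = 70, sex = "none", carrier_freq = 0.1) {
  data.frame(gene = sprintf("RISK%02d", seq_len(n)), mode = mode,
             beta = beta, ea_cut = ea_cut, sex = sex,
             carrier_freq = carrier_freq, stringsAsFactors = FALSE)
}

# Draw site table: one row per site with gene, class, ea, maf.
.simulateSites <- function(config) {
  genes <- sprintf("G%04d", seq_len(config$n_genes))
  nsites <- pmax(1L, rpois(config$n_genes, config$sites_per_gene))
  site_gene <- rep(genes, nsites)
  n <- length(site_gene)
  cls <- sample(names(config$class_probs), n, replace = TRUE,
                prob = config$class_probs)
  tail <- runif(n) < config$ea_tail_weight
  ea <- ifelse(tail, runif(n, 70, 100), runif(n, 0, 100))
  ea[cls != "missense"] <- NA_real_
  maf <- pmin(rbeta(n, config$maf_shape1, config$maf_shape2), 0.5)
  maf <- pmax(maf, 1e-4)
  sites <- data.frame(gene = site_gene, variant_class = cls, ea = ea,
                      maf = maf, risk_site = FALSE,
                      stringsAsFactors = FALSE)

  # APOE-like covariate gene: two missense sites, one common high-impact
  apoe <- data.frame(gene = "APOE",
                     variant_class = "missense",
                     ea = c(85, 40), maf = c(0.15, 0.1),
                     risk_site = FALSE, stringsAsFactors = FALSE)
  sites <- rbind(sites, apoe)

  pl <- config$planted
  if (!is.null(pl)) {
    for (i in seq_len(nrow(pl))) {
      # one designated high-EA risk site per planted gene, with MAF chosen
      # so the carrier frequency under the planted mode hits the target
      cf <- pl$carrier_freq[i]
      maf_i <- if (pl$mode[i] == "dominant") 1 - sqrt(1 - cf) else sqrt(cf)
      extra_maf <- pmin(rbeta(2L, config$maf_shape1, config$maf_shape2), 0.5)
      block <- data.frame(
        gene = pl$gene[i],
        variant_class = "missense",
        ea = c(runif(1, pmax(pl$ea_cut[i] + 5, 85), 100),
               runif(2L, 0, pl$ea_cut[i] - 5)),
        maf = c(maf_i, pmax(extra_maf, 1e-4)),
        risk_site = c(TRUE, FALSE, FALSE), stringsAsFactors = FALSE)
      sites <- rbind(sites, block)
    }
  }
  sites
}

#' Simulate a case/control exome cohort
#'
#' Generates genotypes for every site under HWE, computes each individual's
#' disease liability
#' \eqn{logit(P(case)) = b_0 + \sum_g \beta_g \cdot carrier_g +
#' \beta_{APOE} \cdot pEA_{APOE} + \beta_{age} (age - \bar{age})},
#' solves the intercept so the expected population case fraction matches
#' \code{base_rate}, samples phenotypes, and subsamples the requested
#' numbers of cases and controls.  Carrier status of a planted gene means
#' carrying its high-EA risk site (heterozygous or homozygous for dominant
#' effects, homozygous only for recessive ones), so the planted signal is
#' recoverable by the thresholded pEA features.
#'
#' @param config a [simConfig()].
#' @param seed integer seed; the whole simulation is reproducible from it.
#' @return An [EamlCohort-class]; \code{cohortMetadata(x)$truth} records the
#'   planted genes, their realized case/control carrier frequencies, and
#'   the simulation seed.
#' @export
simulateCohort <- function(config = simConfig(), seed = 1L) {
  withr::with_seed(seed, .simulateCohortImpl(config, seed))
}

.simulateCohortImpl <- function(config, seed) {
  sites <- .simulateSites(config)
  n_sites <- nrow(sites)
  pl <- config$planted

  # pool large enough that the requested cases and controls exist whp
  need <- max(config$n_cases / config$base_rate,
              config$n_controls / (1 - config$base_rate))
  n_pool <- ceiling(need * 1.4) + 50L

  sex <- sample(c("male", "female"), n_pool, replace = TRUE)
  age <- pmin(pmax(rnorm(n_pool, 74, 6), 55), 95)

  # genotype count matrix would be n_pool x n_sites; draw per site and keep
  # sparse carrier triplets instead
  geno_i <- vector("list", n_sites)
  geno_g <- vector("list", n_sites)
  for (s in seq_len(n_sites)) {
    g <- rbinom(n_pool, 2L, sites$maf[s])
    idx <- which(g > 0L)
    geno_i[[s]] <- idx
    geno_g[[s]] <- g[idx]
  }

  # liability terms
  eta <- rep(0, n_pool)
  carrier_mat <- NULL
  if (!is.null(pl)) {
    carrier_mat <- matrix(FALSE, n_pool, nrow(pl),
                          dimnames = list(NULL, pl$gene))
    risk_rows <- which(sites$risk_site)
    for (i in seq_len(nrow(pl))) {
      s <- risk_rows[match(pl$gene[i], sites$gene[risk_rows])]
      idx <- geno_i[[s]]
      gg <- geno_g[[s]]
      carr <- if (pl$mode[i] == "dominant") idx else idx[gg == 2L]
      ok <- rep(TRUE, length(carr))
      if (pl$sex[i] != "none") ok <- sex[carr] == pl$sex[i]
      carrier_mat[carr, i] <- TRUE
      eta[carr[ok]] <- eta[carr[ok]] + pl$beta[i]
    }
  }

  # APOE-like pEA from its two sites
  apoe_rows <- which(sites$gene == "APOE")
  apoe_lsum <- rep(0, n_pool)
  for (s in apoe_rows) {
    contrib <- geno_g[[s]] * log(1 - sites$ea[s] / 100)
    apoe_lsum[geno_i[[s]]] <- apoe_lsum[geno_i[[s]]] + contrib
  }
  apoe_pea <- 1 - exp(apoe_lsum)
  eta <- eta + config$apoe_effect * apoe_pea +
    config$age_effect * (age - mean(age))

  f <- function(b0) mean(plogis(b0 + eta)) - config$base_rate
  b0 <- uniroot(f, c(-30, 30))$root
  y <- rbinom(n_pool, 1L, plogis(b0 + eta))

  cases <- which(y == 1L)
  controls <- which(y == 0L)
  if (length(cases) < config$n_cases || length(controls) < config$n_controls) {
    stop("base_rate unattainable: pool produced ", length(cases),
         " cases and ", length(controls), " controls")
  }
  keep <- c(sample(cases, config$n_cases),
            sample(controls, config$n_controls))
  ids <- sprintf("S%05d", keep)

  samples <- data.frame(
    sample_id = ids,
    phenotype = ifelse(y[keep] == 1L, "case", "control"),
    sex = sex[keep], age = age[keep],
    apoe_genotype = ifelse(apoe_pea[keep] > 0, "E3/E4", "E3/E3"),
    stringsAsFactors = FALSE)

  # variant records for kept samples
  pos <- match(seq_len(n_pool), keep)  # pool index -> kept row or NA
  recs <- vector("list", n_sites)
  for (s in seq_len(n_sites)) {
    ki <- pos[geno_i[[s]]]
    sel <- !is.na(ki)
    if (!any(sel)) next
    recs[[s]] <- data.frame(
      sample_id = ids[ki[sel]],
      gene = sites$gene[s],
      variant_class = sites$variant_class[s],
      ea = sites$ea[s],
      zygosity = ifelse(geno_g[[s]][sel] == 2L, "hom", "het"),
      stringsAsFactors = FALSE)
  }
  variants <- as.data.frame(data.table::rbindlist(recs))

  truth <- list(seed = seed, base_rate = config$base_rate,
                intercept = b0, planted = pl)
  if (!is.null(pl)) {
    cm <- carrier_mat[keep, , drop = FALSE]
    is_case <- samples$phenotype == "case"
    truth$carrier_freq_case <- colMeans(cm[is_case, , drop = FALSE])
    truth$carrier_freq_control <- colMeans(cm[!is_case, , drop = FALSE])
  }
  EamlCohort(variants, samples, metadata = list(truth = truth))
}

#' Simulate a weighted gene network with a planted module
#'
#' Scale-free background generated by preferential attachment plus extra
#' edges inside a designated module until the module subgraph reaches the
#' requested edge density.  Edge weights are Uniform(400, 999), mimicking
#' combined interaction-confidence scores.
#'
#' @param n_nodes number of nodes (named \code{N0001}...).
#' @param attach_param edges added per node during preferential attachment.
#' @param module_size number of nodes in the planted module (randomly
#'   chosen), or pass explicit node names via \code{module_nodes}.
#' @param module_nodes optional explicit module node names.
#' @param module_density target edge density within the module subgraph.
#' @param seed RNG seed.
#' @return list with \code{graph} (weighted undirected
#'   \code{igraph}) and \code{module} (node names of the planted module).
#' @export
simulateNetwork <- function(n_nodes = 2000L, attach_param = 3L,
                            module_size = 30L, module_nodes = NULL,
                            module_density = 0.1, seed = 1L) {
  withr::with_seed(seed, {
    g <- igraph::sample_pa(n_nodes, m = attach_param, directed = FALSE)
    igraph::V(g)$name <- sprintf("N%04d", seq_len(n_nodes))
    if (is.null(module_nodes)) {
      module_nodes <- sample(igraph::V(g)$name, module_size)
    }
    ms <- length(module_nodes)
    possible <- t(utils::combn(module_nodes, 2L))
    want <- ceiling(module_density * nrow(possible))
    have <- igraph::as_edgelist(
      igraph::induced_subgraph(g, module_nodes))
    key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    existing <- key(have[, 1], have[, 2])
    cand <- which(!(key(possible[, 1], possible[, 2]) %in% existing))
    add <- cand[sample.int(length(cand),
                           max(0L, min(length(cand), want - length(existing))))]
    if (length(add)) {
      g <- igraph::add_edges(g, t(possible[add, , drop = FALSE]))
    }
    g <- igraph::simplify(g)
    igraph::E(g)$weight <- runif(igraph::ecount(g), 400, 999)
  })
  list(graph = g, module = module_nodes)
}
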