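#' @importFrom stats phyper cor
NULL

#' Equal-size case/control subsample
#'
#' Draws \code{n_cases} cases and the same number of controls without
#' replacement, the unit experiment of the down-sampling robustness
#' protocol.
#'
#' @param cohort An [EamlCohort-class].
#' @param n_cases cases (and controls) to keep.
#' @param seed RNG seed.
#' @return An [EamlCohort-class] restricted to the draw.
#' @export
subsampleCohort <- function(cohort, n_cases, seed = 1L) {
  s <- sampleInfo(cohort)
  cases <- s$sample_id[s$phenotype == "case"]
  controls <- s$sample_id[s$phenotype == "control"]
  if (n_cases > length(cases) || n_cases > length(controls)) {
    stop("cannot draw ", n_cases, " cases and controls from ",
         length(cases), " cases / ", length(controls), " controls")
  }
  keep <- withr::with_seed(seed, c(sample(cases, n_cases),
                                   sample(controls, n_cases)))
  cohortSubset(cohort, keep)
}

#' Upper-tail hypergeometric overlap p-value
#'
#' One-tailed probability of observing at least \code{overlap} shared
#' genes between two lists of sizes \code{k_a} and \code{k_b} drawn from a
#' universe of \code{universe} genes (equivalently, a one-tailed Fisher
#' exact test on the overlap table).
#'
#' @param overlap observed intersection size.
#' @param k_a,k_b list sizes.
#' @param universe number of genes in the common universe.
#' @return P(X >= overlap) in (0, 1\].
#' @export
hypergeomOverlapP <- function(overlap, k_a, k_b, universe) {
  if (overlap < 0 || overlap > min(k_a, k_b) || max(k_a, k_b) > universe) {
    stop("inconsistent counts for hypergeometric overlap")
  }
  phyper(overlap - 1, k_a, universe - k_a, k_b, lower.tail = FALSE)
}

#' Agreement between two gene rankings
#'
#' Computes the top-K overlap with its hypergeometric p-value and a
#' Kendall tau-b over the union of the two top-K lists, scoring a gene
#' absent from one ranking's top K as rank K + 1 (so a fully shared,
#' exactly reversed top-K gives tau = -1).
#'
#' @param ranking_a,ranking_b character vectors of genes, best first, over
#'   the same universe.
#' @param top_k list depth (default 50).
#' @param universe universe size for the hypergeometric p (default: number
#'   of genes in \code{ranking_a}).
#' @param tauMode \code{"union"} (default: tau-b over the union of the two
#'   top-K lists, absent rank = K + 1) or \code{"intersection"} (tau-b over
#'   the shared top-K genes only).  Note the union alignment is not
#'   centred at 0 for independent rankings (cross-list pairs are
#'   systematically discordant, pulling the null mean to about -0.5); the
#'   intersection mode has a zero-centred null.
#' @return list with \code{overlap}, \code{hypergeom_p}, \code{kendall_tau}.
#' @export
rankingAgreement <- function(ranking_a, ranking_b, top_k = 50L,
                             universe = length(ranking_a),
                             tauMode = c("union", "intersection")) {
  tauMode <- match.arg(tauMode)
  if (top_k > universe) stop("top_k exceeds the ranking universe")
  ta <- utils::head(ranking_a, top_k)
  tb <- utils::head(ranking_b, top_k)
  ov <- length(intersect(ta, tb))
  p <- hypergeomOverlapP(ov, length(ta), length(tb), universe)
  if (tauMode == "union") {
    un <- union(ta, tb)
    pa <- match(un, ta)
    pb <- match(un, tb)
    pa[is.na(pa)] <- top_k + 1L
    pb[is.na(pb)] <- top_k + 1L
  } else {
    un <- intersect(ta, tb)
    pa <- match(un, ta)
    pb <- match(un, tb)
  }
  tau <- if (length(un) < 2L) NA_real_ else
    suppressWarnings(cor(pa, pb, method = "kendall"))
  if (is.nan(tau)) tau <- NA_real_
  list(overlap = ov, hypergeom_p = p, kendall_tau = tau)
}

#' Down-sampling grid
#'
#' @param sizes case counts, descending (controls matched equal).
#' @param iterations random subsample draws per size (default 10).
#' @param top_k comparison list depth (default 50).
#' @param seed master seed; per-run seeds are derived from it.
#' @return list with class \code{"downsampleGrid"}.
#' @export
downsampleGrid <- function(sizes, iterations = 10L, top_k = 50L, seed = 1L) {
  sizes <- as.integer(sizes)
  if (is.unsorted(rev(sizes))) stop("sizes must be descending")
  structure(list(sizes = sizes, iterations = as.integer(iterations),
                 top_k = as.integer(top_k), seed = as.integer(seed)),
            class = "downsampleGrid")
}

#' Run the down-sampling robustness protocol
#'
#' For every grid size, repeatedly subsamples equal cases/controls,
#' re-ranks the genes on the subsample, and measures agreement with the
#' reference ranking (top-K overlap, hypergeometric p, Kendall tau).  The
#' reference is typically the full-cohort run; any externally produced
#' ranking over the same gene universe may be supplied instead (for
#' side-by-side comparison with other association methods).
#'
#' @param cohort An [EamlCohort-class].
#' @param grid a [downsampleGrid()].
#' @param reference_ranking character vector of genes, best first, from the
#'   reference run.
#' @param rankFun function(cohort, seed) returning a character vector of
#'   genes, best first; defaults to ranking by ensemble mean MCC via
#'   [eamlRank()] in parametric mode.
#' @param universe universe size for the hypergeometric p-values
#'   (default: length of the reference ranking, i.e. genes evaluated in the
#'   reference run).
#' @return data.frame, one row per size x iteration, plus a
#'   \code{"summary"} attribute with mean and standard error of the overlap
#'   per size.
#' @export
runDownsampling <- function(cohort, grid, reference_ranking,
                            rankFun = NULL,
                            universe = length(reference_ranking)) {
  if (is.null(rankFun)) {
    rankFun <- function(co, seed) {
      eamlRank(co, cv = cvConfig(seed = seed), method = "parametric")$gene
    }
  }
  rows <- list()
  for (si in seq_along(grid$sizes)) {
    for (it in seq_len(grid$iterations)) {
      run_seed <- .childSeed(grid$seed, si * 1000L + it)
      sub <- subsampleCohort(cohort, grid$sizes[si], seed = run_seed)
      rk <- rankFun(sub, run_seed)
      ag <- rankingAgreement(reference_ranking, rk, grid$top_k, universe)
      rows[[length(rows) + 1L]] <- data.frame(
        size = grid$sizes[si], iteration = it, overlap = ag$overlap,
        hypergeom_p = ag$hypergeom_p, kendall_tau = ag$kendall_tau)
    }
  }
  out <- do.call(rbind, rows)
  smry <- do.call(rbind, lapply(split(out, out$size), function(d) {
    data.frame(size = d$size[1], mean_overlap = mean(d$overlap),
               se_overlap = sd(d$overlap) / sqrt(nrow(d)))
  }))
  smry <- smry[order(-smry$size), ]
  rownames(smry) <- NULL
  attr(out, "summary") <- smry
  out
}
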