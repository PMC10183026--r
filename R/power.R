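#' @importFrom stats qnorm rbinom uniroot
NULL

#' Power-calculation parameters
#'
#' Parameters of the analytic single-variant case-control power comparator:
#' a 1-df allelic (trend-type) test of risk-allele frequency difference
#' between cases and unaffected controls, under Hardy-Weinberg genotype
#' frequencies and a genotype-relative-risk disease model scaled to the
#' population prevalence.
#'
#' @param alpha two-sided significance level (default 5e-6).
#' @param prevalence population disease probability K (default 0.01).
#' @param daf disease (risk) allele frequency p (default 0.05).
#' @param grr heterozygote genotype relative risk r (default 1.6).
#' @param model genotype-risk model: \code{"additive"} (hom RR = 2r - 1),
#'   \code{"multiplicative"} (r^2), \code{"dominant"} (r) or
#'   \code{"recessive"} (het RR 1, hom RR r).
#' @param n_cases,n_controls sample sizes.
#' @return list with class \code{"powerParams"}.
#' @export
powerParams <- function(alpha = 5e-6, prevalence = 0.01, daf = 0.05,
                        grr = 1.6,
                        model = c("additive", "multiplicative",
                                  "dominant", "recessive"),
                        n_cases = 2500L, n_controls = 2500L) {
  model <- match.arg(model)
  stopifnot(alpha > 0, alpha < 1, prevalence > 0, prevalence < 1,
            daf > 0, daf < 1, grr > 0, n_cases >= 1, n_controls >= 1)
  structure(list(alpha = alpha, prevalence = prevalence, daf = daf,
                 grr = grr, model = model,
                 n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls)),
            class = "powerParams")
}

#' Genotype and allele frequencies by disease status
#'
#' Standard epidemiologic algebra: population genotype frequencies under
#' HWE at the risk-allele frequency; genotype relative risks from the
#' chosen model; the baseline penetrance solved so that the population
#' prevalence constraint holds; case genotype frequencies proportional to
#' frequency times penetrance and (unaffected) control frequencies to
#' frequency times one minus penetrance.
#'
#' @param params a [powerParams()].
#' @param populationControls if TRUE, controls are drawn from the whole
#'   population rather than conditioned on being unaffected.
#' @return list with genotype frequency vectors (\code{pop}, \code{case},
#'   \code{control}; order ref-hom, het, risk-hom), the implied
#'   penetrances, and risk-allele frequencies \code{p_case},
#'   \code{p_control}.
#' @export
genotypeFreqsByStatus <- function(params, populationControls = FALSE) {
  p <- params$daf
  f <- c((1 - p)^2, 2 * p * (1 - p), p^2)
  r <- params$grr
  rr <- switch(params$model,
               additive = c(1, r, 2 * r - 1),
               multiplicative = c(1, r, r^2),
               dominant = c(1, r, r),
               recessive = c(1, 1, r))
  base_pen <- params$prevalence / sum(f * rr)
  pen <- base_pen * rr
  if (any(pen > 1)) {
    stop("implied penetrance exceeds 1; lower prevalence or relative risk")
  }
  case <- f * pen / sum(f * pen)
  control <- if (populationControls) f else f * (1 - pen) / sum(f * (1 - pen))
  alleleFreq <- function(g) g[2] / 2 + g[3]
  list(pop = f, penetrance = pen, case = case, control = control,
       p_case = alleleFreq(case), p_control = alleleFreq(control))
}

#' Analytic power of the allelic case-control test
#'
#' Normal-approximation power of the two-sided 1-df allelic test comparing
#' the case and control risk-allele frequencies.  The test statistic's
#' standard error uses the alternative-hypothesis (unpooled) variance of
#' the two allele-frequency estimates,
#' \deqn{SE = \sqrt{p_a(1-p_a)/(2 n_{cases}) + p_u(1-p_u)/(2 n_{controls})}}
#' and power is
#' \eqn{\Phi(z - z_{1-\alpha/2}) + \Phi(-z - z_{1-\alpha/2})} with
#' \eqn{z = (p_a - p_u)/SE}.  Agreement with a Monte-Carlo rejection-rate
#' oracle is part of the test suite.
#'
#' @param params a [powerParams()].
#' @param populationControls see [genotypeFreqsByStatus()].
#' @return Power in \[0, 1\].
#' @examples
#' assocPower(powerParams(n_cases = 2500, n_controls = 2500))
#' @export
assocPower <- function(params, populationControls = FALSE) {
  fr <- genotypeFreqsByStatus(params, populationControls)
  se <- sqrt(fr$p_case * (1 - fr$p_case) / (2 * params$n_cases) +
             fr$p_control * (1 - fr$p_control) / (2 * params$n_controls))
  z <- (fr$p_case - fr$p_control) / se
  zc <- qnorm(1 - params$alpha / 2)
  pnorm(z - zc) + pnorm(-z - zc)
}

#' Power across a grid of sample sizes
#'
#' Evaluates [assocPower()] at a series of case counts with equal control
#' counts, the comparator curve drawn alongside down-sampling results.
#'
#' @param params a [powerParams()]; its sample sizes are ignored.
#' @param sizes vector of case counts (controls matched equal).
#' @return data.frame with columns \code{n_cases} and \code{power}.
#' @export
powerCurve <- function(params, sizes) {
  pw <- vapply(sizes, function(n) {
    p <- params
    p$n_cases <- as.integer(n)
    p$n_controls <- as.integer(n)
    assocPower(p)
  }, numeric(1))
  data.frame(n_cases = as.integer(sizes), power = pw)
}

#' Monte-Carlo power oracle
#'
#' Empirical rejection rate of the allelic z-test over simulated cohorts:
#' case and control risk-allele counts are drawn binomially at the
#' status-specific allele frequencies and the two-sided test applied.
#' Used as the independent cross-check of [assocPower()].
#'
#' @param params a [powerParams()].
#' @param nsim number of simulated cohorts.
#' @param seed RNG seed.
#' @return Empirical power estimate.
#' @export
simulatePower <- function(params, nsim = 10000L, seed = 1L) {
  fr <- genotypeFreqsByStatus(params)
  na <- 2L * params$n_cases
  nu <- 2L * params$n_controls
  withr::with_seed(seed, {
    xa <- rbinom(nsim, na, fr$p_case)
    xu <- rbinom(nsim, nu, fr$p_control)
  })
  pa <- xa / na
  pu <- xu / nu
  se <- sqrt(pa * (1 - pa) / na + pu * (1 - pu) / nu)
  z <- (pa - pu) / pmax(se, .Machine$double.eps)
  mean(abs(z) > qnorm(1 - params$alpha / 2))
}
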