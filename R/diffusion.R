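#' @importFrom Matrix Diagonal colSums sparseMatrix
#' @importFrom stats shapiro.test
NULL

#' Diffusion configuration
#'
#' @param restart_prob restart probability of the walk in (0, 1\]
#'   (default 0.5; any positive value guarantees convergence).
#' @param tol L1 convergence tolerance of the score vector.
#' @param max_iter iteration cap.
#' @param n_random_sets degree-matched random seed sets for the null
#'   (default 100).
#' @param seed RNG seed.
#' @return list with class \code{"diffusionConfig"}.
#' @export
diffusionConfig <- function(restart_prob = 0.5, tol = 1e-8,
                            max_iter = 1000L, n_random_sets = 100L,
                            seed = 1L) {
  stopifnot(restart_prob > 0, restart_prob <= 1, tol > 0, max_iter >= 1)
  structure(list(restart_prob = restart_prob, tol = tol,
                 max_iter = as.integer(max_iter),
                 n_random_sets = as.integer(n_random_sets),
                 seed = as.integer(seed)),
            class = "diffusionConfig")
}

.normalizedAdjacency <- function(graph) {
  a <- igraph::as_adjacency_matrix(graph, attr =
    if ("weight" %in% igraph::edge_attr_names(graph)) "weight" else NULL,
    sparse = TRUE)
  cs <- Matrix::colSums(a)
  cs[cs == 0] <- 1  # isolated nodes keep zero columns
  w <- a %*% Matrix::Diagonal(x = 1 / cs)
  rownames(w) <- colnames(w) <- igraph::V(graph)$name
  w
}

# Power iteration of the restart walk on a prebuilt column-normalized
# operator; shared by diffuseScores() and the repeated null diffusions of
# diffusionZ().
.diffuseCore <- function(w, seeds, config) {
  nodes <- rownames(w)
  e <- numeric(length(nodes))
  e[match(seeds, nodes)] <- 1 / length(seeds)
  r <- config$restart_prob
  s <- e
  for (i in seq_len(config$max_iter)) {
    s_new <- as.numeric(w %*% s) * (1 - r) + r * e
    # isolated-node leakage (zero columns) is renormalized away
    s_new <- s_new / sum(s_new)
    delta <- sum(abs(s_new - s))
    s <- s_new
    if (delta < config$tol) {
      names(s) <- nodes
      return(s)
    }
  }
  stop("diffusion did not converge in ", config$max_iter,
       " iterations (residual ", format(delta), ")")
}

#' Network diffusion by random walk with restart
#'
#' Propagates signal from a seed gene set over a weighted undirected
#' network by iterating
#' \deqn{s \leftarrow (1 - r) W s + r e}
#' where W is the column-normalized weighted adjacency matrix, e the
#' uniform distribution over the seeds, and r the restart probability.
#' Scores are a probability distribution (sum 1) at every iteration;
#' iteration stops when the L1 change drops below \code{tol}.
#'
#' @param graph weighted undirected \code{igraph} (e.g. from
#'   [readNetwork()]).
#' @param seed_set character vector of seed node names; seeds absent from
#'   the graph are dropped with a warning.
#' @param config a [diffusionConfig()].
#' @return Named numeric vector of node scores summing to 1.
#' @export
diffuseScores <- function(graph, seed_set, config = diffusionConfig()) {
  nodes <- igraph::V(graph)$name
  seeds <- intersect(seed_set, nodes)
  if (!length(seeds)) stop("no seed is present in the graph")
  if (length(seeds) < length(seed_set)) {
    warning(length(seed_set) - length(seeds),
            " seed(s) absent from the graph dropped")
  }
  w <- .normalizedAdjacency(graph)
  .diffuseCore(w, seeds, config)
}

#' Degree-matched random node sets
#'
#' Draws random replacement sets of the same size as the seed set, each
#' seed node replaced by a non-seed node from the same log2-degree bin
#' (widening to neighbouring bins with a warning when a bin has too few
#' non-seed nodes).  Controls for the hub bias of highly connected seed
#' sets.
#'
#' @param graph an \code{igraph}.
#' @param seed_set seed node names.
#' @param n_sets number of random sets.
#' @param seed RNG seed.
#' @return list of character vectors, each disjoint from the seeds.
#' @export
degreeMatchedSets <- function(graph, seed_set, n_sets = 100L, seed = 1L) {
  nodes <- igraph::V(graph)$name
  deg <- igraph::degree(graph)
  names(deg) <- nodes
  seeds <- intersect(seed_set, nodes)
  if (!length(seeds)) stop("no seed is present in the graph")
  bin <- floor(log2(pmax(deg, 1)))
  pool <- setdiff(nodes, seeds)
  pool_by_bin <- split(pool, bin[pool])
  widened <- FALSE
  withr::with_seed(seed, {
    sets <- lapply(seq_len(n_sets), function(i) {
      out <- character(length(seeds))
      used <- character(0)
      for (j in seq_along(seeds)) {
        b <- bin[seeds[j]]
        cand <- setdiff(pool_by_bin[[as.character(b)]], used)
        wb <- 1L
        while (!length(cand)) {  # widen to neighbouring log2-degree bins
          widened <<- TRUE
          cand <- setdiff(unlist(pool_by_bin[as.character((b - wb):(b + wb))],
                                 use.names = FALSE), used)
          wb <- wb + 1L
          if (wb > max(bin) + 1L) stop("cannot degree-match seed ", seeds[j])
        }
        out[j] <- cand[sample.int(length(cand), 1L)]
        used <- c(used, out[j])
      }
      out
    })
  })
  if (widened) warning("some degree bins were widened to find matches")
  sets
}

#' Prioritization AUC of diffusion scores
#'
#' ROC AUC of target versus non-target genes among the non-seed nodes,
#' ranked by diffusion score (midrank ties: constant scores give 0.5).
#'
#' @param node_scores named score vector from [diffuseScores()].
#' @param target_set target node names.
#' @param exclude nodes excluded from the evaluation (normally the seeds).
#' @return AUC in \[0, 1\].
#' @export
prioritizationAUC <- function(node_scores, target_set, exclude = character()) {
  eligible <- setdiff(names(node_scores), exclude)
  is_target <- eligible %in% target_set
  if (!any(is_target)) stop("no eligible target among scored nodes")
  .aucRank(node_scores[eligible], is_target)
}

#' Diffusion connectivity z-score
#'
#' Measures how specifically a seed gene set diffuses to a target set:
#' the observed seeds-to-targets prioritization AUC is compared with the
#' AUCs of \code{n_random_sets} degree-matched random seed sets, giving
#' \eqn{z = (AUC - mean(AUC_{random})) / sd(AUC_{random})}.  The random
#' AUC distribution is tested for normality (Shapiro-Wilk) and the p-value
#' reported, not enforced.
#'
#' @param graph weighted undirected \code{igraph}.
#' @param from_set seed node names (signal origin).
#' @param to_set target node names.
#' @param config a [diffusionConfig()].
#' @return list with \code{auc}, \code{random_aucs}, \code{z},
#'   \code{shapiro_p}, and \code{node_scores} of the observed diffusion.
#' @export
diffusionZ <- function(graph, from_set, to_set,
                       config = diffusionConfig()) {
  w <- .normalizedAdjacency(graph)
  seeds <- intersect(from_set, igraph::V(graph)$name)
  if (!length(seeds)) stop("no seed is present in the graph")
  if (length(seeds) < length(from_set)) {
    warning(length(from_set) - length(seeds),
            " seed(s) absent from the graph dropped")
  }
  scores <- .diffuseCore(w, seeds, config)
  auc <- prioritizationAUC(scores, to_set, exclude = seeds)
  rand_sets <- degreeMatchedSets(graph, seeds, config$n_random_sets,
                                 seed = config$seed)
  random_aucs <- vapply(rand_sets, function(rs) {
    s <- .diffuseCore(w, rs, config)
    prioritizationAUC(s, to_set, exclude = rs)
  }, numeric(1))
  z <- (auc - mean(random_aucs)) / sd(random_aucs)
  shap <- tryCatch(shapiro.test(random_aucs)$p.value,
                   error = function(e) NA_real_)
  list(auc = auc, random_aucs = random_aucs, z = z, shapiro_p = shap,
       node_scores = scores)
}
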