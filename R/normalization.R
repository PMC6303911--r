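# Both propagation scores are linear in the 0/1 input indicator y over
# the m compound nodes: score_i = sum_j K_ij y_j. The influence matrix K
# (nodes x compounds) therefore determines the exact permutation-null
# moments. For diffusion K holds the compound columns of the grounded
# Laplacian inverse; for pagerank K holds the single-source personalized
# PageRank vectors (to be divided by the input size n by the caller,
# since the uniform restart carries weight 1/n per input compound).
influence_matrix <- function(g, method = c("diffusion", "pagerank"),
                             damping = 0.85) {
  method <- match.arg(method)
  compounds <- kg_nodes(g, "compound")
  nodes <- igraph::V(g)$name
  if (method == "diffusion") {
    Lg <- grounded_laplacian(g)
    E <- Matrix::sparseMatrix(i = match(compounds, nodes),
                              j = seq_along(compounds),
                              x = 1, dims = c(length(nodes),
                                              length(compounds)))
    K <- as.matrix(Matrix::solve(Lg, E))
  } else {
    op <- pagerank_operator(g, damping)
    E <- Matrix::sparseMatrix(i = match(compounds, op$names),
                              j = seq_along(compounds),
                              x = 1, dims = c(op$n, length(compounds)))
    K <- pagerank_solve(op, E)
    nodes <- op$names
  }
  dimnames(K) <- list(nodes, compounds)
  K
}

#' Exact null moments of the propagation scores
#'
#' Under the permutation null — `n` input compounds drawn uniformly
#' without replacement from the `m` compound nodes — each node's raw
#' score is a linear statistic of the sampled indicator, so its null mean
#' and standard deviation have closed forms:
#' \deqn{\mu_i = \frac{n}{m} \sum_j K_{ij}, \qquad
#'       \sigma_i^2 = \frac{n(m-n)}{m(m-1)}
#'                    \sum_j (K_{ij} - \bar K_i)^2,}
#' where `K` is the per-compound influence matrix of the method. These
#' moments feed the parametric z-score normalization, replacing Monte
#' Carlo permutations.
#'
#' @param g A valid `knowledge_graph`.
#' @param method `"diffusion"` or `"pagerank"`.
#' @param n Input size, between 1 and the number of compound nodes.
#' @param damping PageRank damping (ignored for diffusion).
#' @return Object of class `nm_moments`: data.frame with columns `id`,
#'   `mu`, `sigma`, and attributes `method`, `n`, `damping`.
#' @export
parametric_moments <- function(g, method = c("diffusion", "pagerank"),
                               n, damping = 0.85) {
  method <- match.arg(method)
  m <- length(kg_nodes(g, "compound"))
  if (n < 1 || n > m) {
    stop("input size n must satisfy 1 <= n <= ", m)
  }
  K <- influence_matrix(g, method, damping)
  if (method == "pagerank") K <- K / n
  mu <- (n / m) * rowSums(K)
  if (m == 1 || n == m) {
    sigma <- rep(0, nrow(K))
  } else {
    Kbar <- rowMeans(K)
    sigma <- sqrt(n * (m - n) / (m * (m - 1)) * rowSums((K - Kbar)^2))
  }
  out <- data.frame(id = rownames(K), mu = mu, sigma = sigma,
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(out, method = method, n = n, damping = damping,
            class = c("nm_moments", "data.frame"))
}

# A node whose null standard deviation vanishes cannot be distinguished
# from the null; relative tolerance guards against numerical zeroes.
sigma_is_zero <- function(sigma, mu) {
  sigma <= 1e-12 * pmax(abs(mu), 1)
}

#' Parametric p-scores from z-scores
#'
#' Standardizes each observed raw score against its permutation-null
#' moments and maps the z-score into \[0, 1\] through the upper tail of
#' the standard normal CDF: `pscore = 1 - pnorm(z)`. Large raw scores
#' give small p-scores. Nodes with a degenerate null (`sigma = 0`)
#' receive p-score 1: they are uninformative and ranked last. p-scores
#' rank the nodes; they are not hypothesis-test p-values and are not
#' multiplicity-adjusted.
#'
#' @param observed Raw score vector from [diffusion_raw()] or
#'   [pagerank_raw()].
#' @param moments An `nm_moments` object computed for the same method
#'   and input size.
#' @return Named numeric p-score vector with attributes `method` and
#'   `approx = "normality"`.
#' @export
zscore_pscores <- function(observed, moments) {
  if (!inherits(moments, "nm_moments")) stop("moments must be nm_moments")
  if (!identical(score_method(observed), attr(moments, "method"))) {
    stop("method mismatch between scores (", score_method(observed),
         ") and moments (", attr(moments, "method"), ")")
  }
  if (!identical(as.integer(attr(observed, "n_input")),
                 as.integer(attr(moments, "n")))) {
    stop("input size mismatch between scores and moments")
  }
  mu <- setNames(moments$mu, moments$id)[names(observed)]
  sigma <- setNames(moments$sigma, moments$id)[names(observed)]
  z <- (observed - mu) / sigma
  p <- pnorm(z, lower.tail = FALSE)
  p[sigma_is_zero(sigma, mu)] <- 1
  structure(setNames(as.numeric(p), names(observed)),
            method = score_method(observed), approx = "normality")
}

# Deterministic sampling helper: runs expr under a temporary RNG state
# seeded with `seed`, restoring the caller's stream afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Raw null scores for `niter` uniformly drawn size-n inputs, computed in
# one multi-right-hand-side solve. Returns a nodes x niter matrix.
null_score_matrix <- function(g, method, n, niter, damping = 0.85) {
  compounds <- kg_nodes(g, "compound")
  m <- length(compounds)
  draws <- replicate(niter, sample.int(m, n))
  draws <- matrix(draws, nrow = n)
  if (method == "diffusion") {
    nodes <- igraph::V(g)$name
    Lg <- grounded_laplacian(g)
    Y <- Matrix::sparseMatrix(
      i = match(compounds, nodes)[as.vector(draws)],
      j = rep(seq_len(niter), each = n),
      x = 1, dims = c(length(nodes), niter))
    out <- as.matrix(Matrix::solve(Lg, Y))
    rownames(out) <- nodes
  } else {
    op <- pagerank_operator(g, damping)
    Y <- Matrix::sparseMatrix(
      i = match(compounds, op$names)[as.vector(draws)],
      j = rep(seq_len(niter), each = n),
      x = 1 / n, dims = c(op$n, niter))
    out <- pagerank_solve(op, Y)
    rownames(out) <- op$names
  }
  out
}

#' Monte Carlo p-scores from simulated permutations
#'
#' Draws `niter` random inputs of the observed size (uniformly, without
#' replacement, from all compound nodes), recomputes the raw scores for
#' each, and reports the add-one empirical upper-tail p-value per node:
#' \deqn{pscore_i = \frac{1 + \#\{ \mathrm{null}_i \ge
#'   \mathrm{observed}_i\}}{1 + niter}.}
#' The add-one estimator keeps p-scores strictly positive. Results are
#' reproducible for a fixed `seed`.
#'
#' @param g A valid `knowledge_graph`.
#' @param observed Raw score vector from [diffusion_raw()] or
#'   [pagerank_raw()].
#' @param niter Number of Monte Carlo permutations (default 1000).
#' @param seed Integer seed for the permutation draws.
#' @param damping PageRank damping (ignored for diffusion).
#' @return Named numeric p-score vector with attributes `method`,
#'   `approx = "simulation"`, `niter`, `seed`.
#' @export
simulation_pscores <- function(g, observed, niter = 1000, seed = 1,
                               damping = 0.85) {
  stopifnot(niter >= 1)
  method <- score_method(observed)
  if (!method %in% c("diffusion", "pagerank")) {
    stop("simulation null applies to diffusion or pagerank scores")
  }
  n <- attr(observed, "n_input")
  nulls <- with_seed(seed,
                     null_score_matrix(g, method, n, niter, damping))
  nulls <- nulls[names(observed), , drop = FALSE]
  exceed <- rowSums(nulls >= observed)
  p <- (1 + exceed) / (1 + niter)
  structure(setNames(as.numeric(p), names(observed)),
            method = method, approx = "simulation",
            niter = niter, seed = seed)
}
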