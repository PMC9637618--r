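#' Rank bounds for the extended rank likelihood
#'
#' Encodes, for every variable, the weak ordering of its observed values as
#' integer level codes (1 = smallest observed level, ascending; 0 = missing).
#' A cell's latent value must exceed the largest current latent among cells
#' at strictly lower levels and stay below the smallest current latent among
#' cells at strictly higher levels; ties impose no mutual constraint and
#' missing cells are unbounded.
#'
#' @param table a [cohort_table()] (one sex stratum) or a plain numeric
#'   matrix of subjects x variables with `NA` for missing.
#' @return a `rank_bounds` object with `codes` (n x p integer matrix),
#'   `n_levels`, and `nodes`.
#' @export
compute_rank_bounds <- function(table) {
  values <- if (is.matrix(table)) table else table$values
  if (is.null(colnames(values)))
    colnames(values) <- paste0("v", seq_len(ncol(values)))
  nodes <- colnames(values)
  codes <- matrix(0L, nrow(values), ncol(values),
                  dimnames = dimnames(values))
  n_levels <- integer(ncol(values))
  for (j in seq_len(ncol(values))) {
    v <- values[, j]
    lev <- sort(unique(v[!is.na(v)]))
    if (length(lev) < 2)
      stop("degenerate variable '", nodes[j],
           "': fewer than 2 distinct observed values")
    codes[, j] <- ifelse(is.na(v), 0L, match(v, lev))
    n_levels[j] <- length(lev)
  }
  structure(list(codes = codes, n_levels = n_levels, nodes = nodes,
                 n = nrow(values)), class = "rank_bounds")
}

#' Per-cell truncation window given an instantiated latent matrix
#'
#' Used mainly to verify the rank-constraint semantics: for observed cells
#' the window is (max latent over strictly lower levels, min latent over
#' strictly higher levels); missing cells get `(-Inf, Inf)`.
#'
#' @param bounds a [compute_rank_bounds()] result.
#' @param Z numeric latent matrix of matching dimension.
#' @return list of matrices `lower` and `upper`.
#' @export
latent_bounds <- function(bounds, Z) {
  lower <- upper <- matrix(NA_real_, bounds$n, length(bounds$nodes))
  for (j in seq_along(bounds$nodes)) {
    cj <- bounds$codes[, j]
    for (i in seq_len(bounds$n)) {
      if (cj[i] == 0L) {
        lower[i, j] <- -Inf; upper[i, j] <- Inf
      } else {
        lo <- Z[cj > 0L & cj < cj[i], j]
        hi <- Z[cj > cj[i], j]
        lower[i, j] <- if (length(lo)) max(lo) else -Inf
        upper[i, j] <- if (length(hi)) min(hi) else Inf
      }
    }
  }
  list(lower = lower, upper = upper)
}

#' Partial correlations from a precision matrix
#'
#' `P[i, j] = -K[i, j] / sqrt(K[i, i] * K[j, j])` off the diagonal, zero on
#' it.
#'
#' @param K symmetric positive-definite matrix.
#' @return the symmetric partial-correlation matrix with zero diagonal.
#' @export
partials_from_precision <- function(K) {
  K <- as.matrix(K)
  if (!isSymmetric(K, tol = 1e-8)) stop("K must be symmetric")
  ev <- min(eigen((K + t(K)) / 2, symmetric = TRUE, only.values = TRUE)$values)
  if (ev <= 0) stop("K must be positive definite")
  d <- sqrt(diag(K))
  P <- -K / outer(d, d)
  diag(P) <- 0
  (P + t(P)) / 2
}

#' Gibbs sampler for the copula graphical model
#'
#' Alternates (a) single-site latent updates, each cell redrawn from its
#' univariate conditional Gaussian truncated to its rank window (missing
#' cells from the untruncated conditional — posterior-predictive
#' imputation), sweeping variables then subjects in a fixed column-major
#' order, and (b) a conjugate Wishart redraw of the precision matrix. The
#' prior is `K ~ Wishart(df = p + 2, scale = I)` (weakly informative,
#' proper) unless overridden. Only ranks of the data enter the sampler, so
#' output is invariant — bit for bit at a fixed seed — under strictly
#' monotone transforms of any margin.
#'
#' @param table a [cohort_table()] for one stratum, or a plain numeric
#'   matrix of subjects x variables.
#' @param n_draws retained draws (default 5000).
#' @param burn_in discarded initial sweeps (default 500).
#' @param thin keep every `thin`-th post-burn-in sweep (default 1).
#' @param prior list with `df` (degrees of freedom, default `p + 2`) and
#'   `scale` (prior scale matrix, default identity).
#' @param seed mandatory integer seed.
#' @return a `posterior_sample`: arrays `partials` and `precision`
#'   (`p x p x n_draws`), node names and chain metadata.
#' @export
gibbs_sample <- function(table, n_draws = 5000, burn_in = 500, thin = 1,
                         prior = NULL, seed) {
  if (missing(seed)) stop("seed is mandatory for reproducibility")
  bounds <- compute_rank_bounds(table)
  p <- length(bounds$nodes)
  n <- bounds$n
  if (n <= p)
    warning("fewer subjects (", n, ") than recommended for ", p,
            " variables")
  if (is.null(prior)) prior <- list()
  prior_df <- if (is.null(prior$df)) p + 2 else prior$df
  prior_scale <- if (is.null(prior$scale)) diag(p) else as.matrix(prior$scale)
  # Wishart(df, V): full conditional scale is (V^{-1} + Z'Z)^{-1}
  prior_rate <- solve(prior_scale)

  # normal-scores initialization consistent with the rank windows
  Z0 <- matrix(0, n, p)
  for (j in seq_len(p)) {
    obs <- bounds$codes[, j] > 0L
    r <- rank(bounds$codes[obs, j], ties.method = "average")
    Z0[obs, j] <- stats::qnorm(r / (sum(obs) + 1))
  }
  set.seed(seed)
  res <- gibbs_copula_cpp(bounds$codes, bounds$n_levels, Z0,
                          as.integer(n_draws), as.integer(burn_in),
                          as.integer(thin), prior_df, prior_rate)
  structure(list(partials = res$partials, precision = res$precision,
                 nodes = bounds$nodes, n_draws = as.integer(n_draws),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 seed = as.integer(seed), n_subjects = n),
            class = "posterior_sample")
}

#' @export
print.posterior_sample <- function(x, ...) {
  cat("posterior_sample: ", length(x$nodes), " nodes, ", x$n_draws,
      " retained draws (burn-in ", x$burn_in, ", thin ", x$thin,
      ", seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

edge_index <- function(nodes) {
  p <- length(nodes)
  ij <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
  data.frame(node_i = nodes[ij[, 1]], node_j = nodes[ij[, 2]],
             i = ij[, 1], j = ij[, 2], stringsAsFactors = FALSE)
}

# retained draws of one edge as a vector
edge_draws <- function(sample, i, j) sample$partials[i, j, ]

# split-chain potential scale reduction, per edge
split_rhat <- function(sample) {
  ed <- edge_index(sample$nodes)
  vapply(seq_len(nrow(ed)), function(k) {
    x <- edge_draws(sample, ed$i[k], ed$j[k])
    m <- length(x) %/% 2
    halves <- list(x[seq_len(m)], x[m + seq_len(m)])
    W <- mean(vapply(halves, stats::var, 0))
    B <- m * stats::var(vapply(halves, mean, 0))
    if (W <= 0) return(1)
    sqrt(((m - 1) / m * W + B / m) / W)
  }, 0)
}

#' Credible-interval edge selection
#'
#' Computes per-edge posterior means and equal-tailed credible intervals at
#' `level`; an edge is selected iff its interval excludes zero, and the
#' selected partial-correlation matrix zeroes all other entries. Warns when
#' any edge's split-chain potential scale reduction exceeds 1.1.
#'
#' @param sample a [gibbs_sample()] result with at least 100 retained draws.
#' @param level credible level in (0, 1), default 0.95.
#' @return a `network_estimate` with `mean_partials`, `ci_lower`,
#'   `ci_upper`, `adjacency` and `selected_partials` matrices.
#' @export
select_edges <- function(sample, level = 0.95) {
  if (!is.numeric(level) || level <= 0 || level >= 1)
    stop("level must lie in (0, 1)")
  if (sample$n_draws < 100) stop("need at least 100 retained draws")
  nodes <- sample$nodes
  p <- length(nodes)
  alpha <- (1 - level) / 2
  mean_p <- apply(sample$partials, c(1, 2), mean)
  lo <- apply(sample$partials, c(1, 2), stats::quantile, probs = alpha)
  hi <- apply(sample$partials, c(1, 2), stats::quantile, probs = 1 - alpha)
  diag(mean_p) <- diag(lo) <- diag(hi) <- 0
  adj <- (lo > 0) | (hi < 0)
  diag(adj) <- FALSE
  sel <- mean_p * adj
  dimnames(mean_p) <- dimnames(lo) <- dimnames(hi) <- dimnames(adj) <-
    dimnames(sel) <- list(nodes, nodes)
  rh <- split_rhat(sample)
  if (any(rh > 1.1))
    warning(sum(rh > 1.1), " edge(s) with split-chain Rhat > 1.1; ",
            "consider longer chains")
  structure(list(mean_partials = mean_p, ci_lower = lo, ci_upper = hi,
                 adjacency = adj, selected_partials = sel, level = level,
                 nodes = nodes, n_draws = sample$n_draws,
                 rhat = stats::setNames(rh, paste(edge_index(nodes)$node_i,
                                                  edge_index(nodes)$node_j,
                                                  sep = "--"))),
            class = "network_estimate")
}

#' @export
print.network_estimate <- function(x, ...) {
  cat("network_estimate: ", length(x$nodes), " nodes, ",
      sum(x$adjacency) / 2, " selected edges at ", x$level * 100,
      "% credibility\n", sep = "")
  invisible(x)
}

#' Edge list of a network estimate
#'
#' @param estimate a [select_edges()] result.
#' @return data frame with one row per unordered node pair.
#' @export
network_edge_list <- function(estimate) {
  ed <- edge_index(estimate$nodes)
  data.frame(node_i = ed$node_i, node_j = ed$node_j,
             mean = estimate$mean_partials[cbind(ed$i, ed$j)],
             ci_lower = estimate$ci_lower[cbind(ed$i, ed$j)],
             ci_upper = estimate$ci_upper[cbind(ed$i, ed$j)],
             selected = estimate$adjacency[cbind(ed$i, ed$j)],
             stringsAsFactors = FALSE)
}

#' Posterior draws in long format (draw, node_i, node_j, value)
#'
#' @param sample a [gibbs_sample()] result.
#' @return data frame suitable for CSV audit export.
#' @export
draws_to_long <- function(sample) {
  ed <- edge_index(sample$nodes)
  do.call(rbind, lapply(seq_len(nrow(ed)), function(k) {
    data.frame(draw = seq_len(sample$n_draws), node_i = ed$node_i[k],
               node_j = ed$node_j[k],
               value = edge_draws(sample, ed$i[k], ed$j[k]),
               stringsAsFactors = FALSE)
  }))
}
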