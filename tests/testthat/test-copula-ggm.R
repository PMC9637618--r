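test_that("rank bounds encode the observed weak ordering", {
  # total order: each latent sits between its rank neighbours
  m <- cbind(a = c(1, 2, 3), b = c(0, 0, 5))
  b <- compute_rank_bounds(m)
  expect_equal(b$codes[, "a"], c(1L, 2L, 3L))
  expect_equal(b$codes[, "b"], c(1L, 1L, 2L))
  Z <- cbind(c(-1, 0, 1), c(-0.3, 0.1, 2))
  lb <- latent_bounds(b, Z)
  expect_equal(lb$lower[, 1], c(-Inf, -1, 0))
  expect_equal(lb$upper[, 1], c(0, 1, Inf))
  # tied zeros unconstrained w.r.t. each other, both below the third
  expect_equal(lb$upper[, 2], c(2, 2, Inf))
  expect_equal(lb$lower[, 2], c(-Inf, -Inf, 0.1))

  expect_error(compute_rank_bounds(cbind(a = c(1, 1, 1), b = 1:3)),
               "degenerate variable 'a'")
  # missing cells are unbounded
  m2 <- cbind(a = c(1, NA, 3))
  b2 <- compute_rank_bounds(cbind(m2, b = 1:3))
  lb2 <- latent_bounds(b2, Z)
  expect_equal(lb2$lower[2, 1], -Inf)
  expect_equal(lb2$upper[2, 1], Inf)
})

test_that("rank bounds imply rank agreement for any conforming latents", {
  # brute force: draw latents consistent with bounds, compare rank orders
  set.seed(5)
  for (r in 1:20) {
    v <- sample(0:3, 8, replace = TRUE)  # tie-heavy column
    m <- cbind(a = v, b = rnorm(8))
    b <- compute_rank_bounds(m)
    # build latents level by level so they respect the ordering
    z <- numeric(8)
    for (lev in seq_len(b$n_levels[1]))
      z[b$codes[, 1] == lev] <- lev + runif(sum(b$codes[, 1] == lev))
    ro <- rank(v, ties.method = "average")
    rz <- rank(z, ties.method = "average")
    # observed ranks equal latent ranks up to ties
    expect_true(all(tapply(rz, ro, mean)[as.character(sort(unique(ro)))] ==
                      sort(unique(ro))))
    lb <- latent_bounds(b, cbind(z, m[, 2]))
    expect_true(all(z > lb$lower[, 1] & z < lb$upper[, 1]))
  }
})

test_that("partials_from_precision matches analytic and regression oracles", {
  expect_equal(partials_from_precision(diag(3)), matrix(0, 3, 3))
  K <- matrix(c(2, -1, -1, 2), 2)
  expect_equal(partials_from_precision(K)[1, 2], 0.5)
  expect_error(partials_from_precision(matrix(c(1, 2, 0, 1), 2)),
               "symmetric")
  expect_error(partials_from_precision(matrix(c(1, 2, 2, 1), 2)),
               "positive definite")

  # regression-residual oracle on random 4x4 precision matrices
  set.seed(8)
  for (r in 1:5) {
    A <- matrix(rnorm(16), 4)
    K <- crossprod(A) + 4 * diag(4)
    S <- solve(K)
    P <- partials_from_precision(K)
    for (i in 1:3) for (j in (i + 1):4) {
      others <- setdiff(1:4, c(i, j))
      # partial covariance of (i, j) given the rest
      Sc <- S[c(i, j), c(i, j)] - S[c(i, j), others] %*%
        solve(S[others, others]) %*% S[others, c(i, j)]
      expect_equal(P[i, j], cov2cor(Sc)[1, 2], tolerance = 1e-10)
    }
  }
})

test_that("gibbs_sample recovers independence and needs a seed", {
  X <- gauss_matrix(500, diag(2), seed = 21)
  fit <- gibbs_sample(X, n_draws = 400, burn_in = 200, seed = 1)
  expect_lt(abs(mean(fit$partials[1, 2, ])), 0.1)
  expect_error(gibbs_sample(X, n_draws = 10, burn_in = 5), "seed")
  expect_warning(gibbs_sample(gauss_matrix(3, diag(4), seed = 2),
                              n_draws = 10, burn_in = 5, seed = 1),
                 "fewer subjects")
})

test_that("every retained precision draw is symmetric positive definite", {
  X <- gauss_matrix(120, random_pd_cor(4, 31), seed = 32)
  fit <- gibbs_sample(X, n_draws = 150, burn_in = 100, seed = 3)
  for (k in seq(1, 150, by = 10)) {
    K <- fit$precision[, , k]
    expect_equal(K, t(K), tolerance = 1e-12)
    expect_gt(min(eigen(K, only.values = TRUE)$values), 0)
    P <- fit$partials[, , k]
    expect_true(all(abs(P[upper.tri(P)]) < 1))
    expect_equal(diag(P), rep(0, 4))
  }
})

test_that("the sampler is rank-invariant bit-for-bit at fixed seed", {
  X <- gauss_matrix(150, random_pd_cor(3, 77), seed = 78)
  f1 <- gibbs_sample(X, n_draws = 60, burn_in = 30, seed = 9)
  Y <- X
  Y[, 1] <- exp(Y[, 1])           # strictly increasing
  Y[, 3] <- qlogis(pnorm(Y[, 3])) # another strictly increasing map
  f2 <- gibbs_sample(Y, n_draws = 60, burn_in = 30, seed = 9)
  expect_identical(f1$partials, f2$partials)
  expect_identical(f1$precision, f2$precision)
})

test_that("missing cells are imputed without derailing the fit", {
  R <- random_pd_cor(4, 55)
  X <- gauss_matrix(400, R, seed = 56)
  Xm <- X
  set.seed(57)
  Xm[sample(length(Xm), 0.1 * length(Xm))] <- NA
  f_full <- gibbs_sample(X, n_draws = 500, burn_in = 200, seed = 5)
  f_miss <- gibbs_sample(Xm, n_draws = 500, burn_in = 200, seed = 5)
  pm_full <- apply(f_full$partials, c(1, 2), mean)
  pm_miss <- apply(f_miss$partials, c(1, 2), mean)
  expect_lt(max(abs(pm_full - pm_miss)), 0.08)
})

test_that("select_edges applies the CI rule exactly", {
  # constant draws at 0.3: degenerate CI [0.3, 0.3], selected
  s <- constant_sample(matrix(c(0, 0.3, 0.3, 0), 2))
  est <- select_edges(s)
  expect_equal(est$ci_lower[1, 2], 0.3)
  expect_equal(est$ci_upper[1, 2], 0.3)
  expect_true(est$adjacency[1, 2])
  expect_equal(est$selected_partials[1, 2], 0.3)

  # draws symmetric around zero: not selected, selected value zeroed
  d <- draws_sample(2, list("1_2" = c(seq(-1, 1, length.out = 200))), 200)
  est2 <- select_edges(d)
  expect_false(est2$adjacency[1, 2])
  expect_equal(est2$selected_partials[1, 2], 0)
  expect_lt(est2$ci_lower[1, 2], 0)
  expect_gt(est2$ci_upper[1, 2], 0)

  expect_error(select_edges(s, level = 1.2), "level")
  expect_error(select_edges(constant_sample(matrix(0, 2, 2), n_draws = 50)),
               "100 retained draws")

  # invariant: selected iff CI excludes zero, on a real fit
  X <- gauss_matrix(150, random_pd_cor(5, 91), seed = 92)
  est3 <- select_edges(gibbs_sample(X, n_draws = 300, burn_in = 150,
                                    seed = 7))
  excl <- est3$ci_lower > 0 | est3$ci_upper < 0
  diag(excl) <- FALSE
  expect_identical(est3$adjacency, excl)
  expect_identical(est3$adjacency, t(est3$adjacency))
})

test_that("a strong edge is detected with high power", {
  R <- correlation_from_partials(rbind(c(0, 0.4), c(0.4, 0)))
  hits <- vapply(1:10, function(r) {
    X <- gauss_matrix(600, R, seed = 600 + r)
    est <- select_edges(gibbs_sample(X, n_draws = 300, burn_in = 150,
                                     seed = r))
    est$adjacency[1, 2]
  }, NA)
  expect_gte(mean(hits), 0.95)
})

test_that("edge list and long-draw exports are structurally sound", {
  X <- gauss_matrix(100, random_pd_cor(4, 13), seed = 14)
  fit <- gibbs_sample(X, n_draws = 120, burn_in = 60, seed = 2)
  est <- select_edges(fit)
  el <- network_edge_list(est)
  expect_equal(nrow(el), 6)
  expect_equal(sum(el$selected), sum(est$adjacency) / 2)
  long <- draws_to_long(fit)
  expect_equal(nrow(long), 6 * 120)
  expect_equal(long$value[long$node_i == "v1" & long$node_j == "v2" &
                            long$draw == 5], fit$partials[1, 2, 5])
})
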