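# shared fixtures, all generated in code

# Gaussian data matrix with a known correlation structure
gauss_matrix <- function(n, R, seed) {
  set.seed(seed)
  X <- matrix(rnorm(n * ncol(R)), n) %*% chol(R)
  colnames(X) <- paste0("v", seq_len(ncol(R)))
  X
}

random_pd_cor <- function(p, seed) {
  set.seed(seed)
  A <- matrix(rnorm(p * p), p)
  cov2cor(crossprod(A) + p * diag(p))
}

# a tiny but valid 11-node cohort (fast to fit at reduced draws)
small_fixture <- function(seed = 42, n = 80) {
  generate_wave1(fixture_config(seed = seed,
                                n_per_sex = c(male = n, female = n)))
}

# hand-built 4-subject cohort values hitting every measurement level
toy_values <- function() {
  m <- cbind(IL6 = c(0, 1.2, 3.1, 0.4), IL8 = c(2, 5, 1, 7),
             IL10 = c(0, 0, 1.1, 2.2), IL12 = c(0.5, 0, 0.7, 1),
             CRP = c(1, 2, NA, 4), depression = c(0, 3, 7, 15),
             cognition = c(-0.2, 0.5, -1.1, 0.3),
             education = c(1, 3, 5, 2), alcohol = c(1, 6, 2, 4),
             cvd_risk = c(10, 20, 30, 15), apoe4 = c(0, 1, 0, 1))
  m
}

toy_cohort <- function() {
  cohort_table(toy_values(), sex = c("male", "female", "male", "female"),
               age = c(71, 80, 85, 90))
}

write_toy_csv <- function(path, values = toy_values(),
                          sex = c("male", "female", "male", "female")) {
  df <- data.frame(subject = paste0("s", seq_len(nrow(values))), sex = sex,
                   age = 70 + seq_len(nrow(values)), wave = 1,
                   values, check.names = FALSE)
  write.csv(df, path, row.names = FALSE, na = "")
  path
}

# posterior_sample with prescribed constant edge draws, for exact oracles
constant_sample <- function(P, n_draws = 200) {
  p <- nrow(P)
  nodes <- if (is.null(rownames(P))) paste0("v", 1:p) else rownames(P)
  arr <- array(P, c(p, p, n_draws))
  structure(list(partials = arr, precision = array(diag(p), c(p, p, n_draws)),
                 nodes = nodes, n_draws = as.integer(n_draws),
                 burn_in = 0L, thin = 1L, seed = 0L, n_subjects = 0L),
            class = "posterior_sample")
}

# sample with arbitrary per-edge draw vectors (list keyed "i_j")
draws_sample <- function(p, draws, n_draws) {
  arr <- array(0, c(p, p, n_draws))
  for (key in names(draws)) {
    ij <- as.integer(strsplit(key, "_")[[1]])
    arr[ij[1], ij[2], ] <- arr[ij[2], ij[1], ] <- draws[[key]]
  }
  structure(list(partials = arr, precision = array(diag(p), c(p, p, n_draws)),
                 nodes = paste0("v", 1:p), n_draws = as.integer(n_draws),
                 burn_in = 0L, thin = 1L, seed = 0L, n_subjects = 0L),
            class = "posterior_sample")
}
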