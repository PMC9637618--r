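test_that("margin specs validate their parameters", {
  expect_error(margin_spec("zero_inflated_lognormal", p_zero = 1.2),
               "p_zero")
  expect_error(margin_spec("ordinal_cutpoints", cutpoints = c(0, 0, 1)),
               "strictly increasing")
  expect_error(margin_spec("gaussian", nonsense = 1), "unknown parameter")
})

test_that("correlation_from_partials inverts the partial map", {
  expect_equal(correlation_from_partials(matrix(0, 4, 4)), diag(4))
  # two variables: partial equals marginal correlation
  P2 <- matrix(c(0, 0.6, 0.6, 0), 2)
  expect_equal(correlation_from_partials(P2)[1, 2], 0.6, tolerance = 1e-12)
  # round trip on a random sparse 11x11
  set.seed(3)
  P <- matrix(0, 11, 11)
  idx <- which(upper.tri(P))
  on <- sample(idx, 8)
  P[on] <- runif(8, -0.3, 0.3)
  P <- P + t(P)
  R <- correlation_from_partials(P)
  expect_equal(partials_from_precision(solve(R)), P, tolerance = 1e-10)
  # invalid inputs
  expect_error(correlation_from_partials(matrix(c(0, 1, 2, 0), 2)),
               "symmetric")
  Pbad <- matrix(0.9, 3, 3); diag(Pbad) <- 0
  expect_error(correlation_from_partials(Pbad), "positive definite")
})

test_that("true_network returns configured matrices and rejects bad input", {
  gc <- fixture_config(seed = 1)
  expect_error(true_network(gc, "other"), "unknown sex")
  Pf <- true_network(gc, "female")
  expect_equal(Pf["depression", "cognition"], -0.3)
  expect_equal(true_network(gc, "male")["depression", "cognition"], 0)
  expect_equal(unname(partials_from_precision(solve(gc$latent_cor$female))),
               unname(Pf), tolerance = 1e-10)
  asym <- matrix(0, 11, 11); asym[1, 2] <- 0.2
  expect_error(generator_config(true_partials = list(male = asym,
                                                     female = asym),
                                seed = 1),
               "symmetric")
})

test_that("generate_wave1 is deterministic and matches its margin targets", {
  gc <- fixture_config(seed = 500, n_per_sex = c(male = 600, female = 600),
                       missing_rate = 0)
  w1 <- generate_wave1(gc)
  w1b <- generate_wave1(gc)
  expect_identical(w1$values, w1b$values)
  expect_identical(w1$age, w1b$age)

  # zero-inflation fractions within 3 SE of configured probabilities
  for (v in c("IL10", "IL12")) {
    p0 <- gc$margins[[v]]$p_zero
    frac <- mean(w1$values[, v] == 0)
    expect_lt(abs(frac - p0), 3 * sqrt(p0 * (1 - p0) / 1200))
  }
  expect_true(all(w1$age >= 70 & w1$age <= 90))
  expect_true(all(w1$values[, "depression"] %in% 0:15))
  expect_true(all(w1$values[, "education"] %in% 1:5))
})

test_that("a zero network yields near-independent observed variables", {
  gc <- generator_config(n_per_sex = c(male = 1000, female = 1000),
                         true_partials = list(male = matrix(0, 11, 11),
                                              female = matrix(0, 11, 11)),
                         missing_rate = 0, seed = 77)
  w1 <- generate_wave1(gc)
  sp <- cor(w1$values[w1$sex == "male", ], method = "spearman")
  expect_lt(mean(abs(sp[upper.tri(sp)])), 0.05)
})

test_that("monotone margins preserve latent rank correlations", {
  gc <- fixture_config(seed = 88, n_per_sex = c(male = 2500, female = 2500),
                       missing_rate = 0)
  w1 <- generate_wave1(gc)
  Z <- attr(w1, "latents")
  idx <- w1$sex == "female"
  # compare on continuous margins (ties on ordinal margins blur Spearman)
  for (v in c("IL8", "CRP", "cognition", "cvd_risk")) {
    for (w in c("IL6", "cognition")) {
      if (v == w) next
      s_obs <- cor(w1$values[idx, v], w1$values[idx, w],
                   method = "spearman")
      s_lat <- cor(Z[idx, v], Z[idx, w], method = "spearman")
      expect_lt(abs(s_obs - s_lat), 0.03)
    }
  }
})

test_that("simulate_attrition reproduces configured dropout behaviour", {
  base <- fixture_config(seed = 9, n_per_sex = c(male = 700, female = 700))
  # flat attrition: dropout fraction near the intercept probability
  gc <- generator_config(n_per_sex = base$n_per_sex,
                         true_partials = base$true_partials,
                         attrition = list(intercept = qlogis(0.2), age = 0,
                                          depression = 0, cognition = 0),
                         seed = 9)
  w1 <- generate_wave1(gc)
  w2 <- simulate_attrition(w1, gc)
  drop_frac <- 1 - nrow(w2$values) / nrow(w1$values)
  expect_lt(abs(drop_frac - 0.2), 3 * sqrt(0.2 * 0.8 / 1400))
  expect_identical(generate_wave1(gc)$values,  w1$values)
  expect_identical(simulate_attrition(w1, gc)$values, w2$values)

  # flat attrition is independent of every variable (point-biserial)
  comp <- attr(w2, "completer")
  for (v in c("IL6", "depression", "cognition")) {
    x <- w1$values[, v]
    ok <- !is.na(x)
    expect_lt(abs(cor(x[ok], as.numeric(comp[ok]))), 0.08)
  }

  # positive depression coefficient: completers less depressed (sign check)
  gc2 <- generator_config(n_per_sex = base$n_per_sex,
                          true_partials = base$true_partials,
                          attrition = list(intercept = qlogis(0.2), age = 0,
                                           depression = 0.4, cognition = 0),
                          seed = 10)
  deltas <- vapply(1:3, function(r) {
    gcr <- generator_config(n_per_sex = base$n_per_sex,
                            true_partials = base$true_partials,
                            attrition = gc2$attrition, seed = 10 + r)
    w1r <- generate_wave1(gcr)
    cr <- attr(simulate_attrition(w1r, gcr), "completer")
    dep <- w1r$values[, "depression"]
    mean(dep[cr], na.rm = TRUE) - mean(dep[!cr], na.rm = TRUE)
  }, 0)
  expect_true(all(deltas < 0))

  # frozen traits are copied across waves
  m <- match(w2$subject, w1$subject)
  expect_identical(w2$values[, "education"], w1$values[m, "education"])
  expect_identical(w2$values[, "apoe4"], w1$values[m, "apoe4"])
  expect_error(simulate_attrition(toy_cohort(), gc), "latents")
})

test_that("zero wave-2 shift leaves paired cognition tests null-calibrated", {
  # flat attrition: with dropout informative on cognition, regression to
  # the mean makes completers' paired differences genuinely nonzero, so
  # the calibration statement concerns non-informative dropout
  hits <- 0
  n_rep <- 12
  base <- fixture_config(seed = 1)
  for (r in seq_len(n_rep)) {
    gc <- generator_config(n_per_sex = c(male = 150, female = 150),
                           true_partials = base$true_partials,
                           attrition = list(intercept = qlogis(0.15),
                                            age = 0, depression = 0,
                                            cognition = 0),
                           seed = 300 + r)
    w1 <- generate_wave1(gc)
    w2 <- simulate_attrition(w1, gc)
    res <- paired_wave_ttest(w1, w2, "cognition")
    if (res$p < 0.05) hits <- hits + 1
  }
  expect_lte(hits / n_rep, 0.10 + 1e-9)
})

test_that("generator configs round-trip through YAML", {
  gc <- fixture_config(seed = 77, n_per_sex = c(male = 120, female = 130))
  path <- tempfile(fileext = ".yaml")
  write_generator_config(gc, path)
  back <- read_generator_config(path)
  expect_equal(back$true_partials$female, gc$true_partials$female,
               ignore_attr = TRUE)
  expect_equal(back$n_per_sex, gc$n_per_sex)
  expect_equal(back$attrition, gc$attrition)
  expect_equal(back$margins$IL10$p_zero, gc$margins$IL10$p_zero)
  expect_identical(generate_wave1(back)$values, generate_wave1(gc)$values)
  # the bundled scenario file parses and matches the in-code fixture
  bundled <- system.file("extdata", "fixture_scenario.yaml",
                         package = "rankggm")
  expect_true(nzchar(bundled))
  gb <- read_generator_config(bundled)
  expect_equal(gb$true_partials$male, fixture_config(seed = 2024)$true_partials$male,
               ignore_attr = TRUE)
})
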