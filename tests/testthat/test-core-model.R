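test_that("event times map position k to k/(N+1) and reject bad permutations", {
  t2 <- event_times(c(2, 1))
  expect_equal(unname(t2), c(1 / 3, 2 / 3))
  expect_equal(names(t2), c("2", "1"))
  expect_equal(unname(event_times(1L)), 0.5)
  expect_true(all(diff(event_times(sample(6))) > 0))
  expect_error(event_times(c(1, 1)), "permutation")
  expect_error(event_times(c(2, 3)), "permutation")
})

test_that("admissibility respects within-biomarker threshold order", {
  es <- zscore_event_set(list(c(1, 2), 1), z_max = c(3, 2))
  expect_true(is_admissible_sequence(c(1, 2, 3), es))
  expect_true(is_admissible_sequence(c(3, 1, 2), es))
  expect_false(is_admissible_sequence(c(2, 1, 3), es)) # z=2 before z=1
  expect_false(is_admissible_sequence(c(1, 2), es))
  set.seed(7)
  for (r in 1:25) {
    es_r <- zscore_event_set(list(c(1, 2, 3), c(1, 2), 1), z_max = c(5, 3, 2))
    expect_true(is_admissible_sequence(random_admissible_sequence(es_r), es_r))
  }
})

test_that("random admissible sequences cover the space uniformly", {
  es <- zscore_event_set(list(c(1, 2), 1), z_max = c(3, 2))
  adm <- enumerate_admissible_sequences(es)
  expect_equal(nrow(adm), 3) # 3!/2 orderings of {z11, z12, z21}
  set.seed(42)
  keys <- replicate(6000, seq_key(random_admissible_sequence(es)))
  freq <- table(keys) / length(keys)
  expect_setequal(names(freq), apply(adm, 1, seq_key))
  expect_true(all(abs(freq - 1 / 3) < 0.03))
})

test_that("trajectories are piecewise linear through the event points", {
  es <- zscore_event_set(list(c(1, 2)), z_max = 3)
  sq <- c(1, 2) # events at t = 1/3 and 2/3
  expect_equal(trajectory_value(es, sq, 1, 1 / 6), 0.5)
  expect_equal(trajectory_value(es, sq, 1, 0.5), 1.5)
  expect_equal(trajectory_value(es, sq, 1, 1), 3)
  expect_equal(trajectory_value(es, sq, 1, 0), 0)
  expect_equal(trajectory_value(es, sq, 1, c(1 / 3, 2 / 3)), c(1, 2))
  tg <- seq(0, 1, length.out = 301)
  g <- trajectory_value(es, sq, 1, tg)
  expect_true(all(diff(g) >= -1e-12)) # non-decreasing
  expect_error(trajectory_value(es, sq, 1, 1.5), "\\[0, 1\\]")
  # multi-biomarker: each trajectory hits its own events
  es2 <- zscore_event_set(list(c(1, 2), 1), z_max = c(3, 2))
  sq2 <- c(3, 1, 2) # bm2:z1 at t=1/4, bm1:z1 at 2/4, bm1:z2 at 3/4
  expect_equal(trajectory_value(es2, sq2, 2, 0.25), 1)
  expect_equal(trajectory_value(es2, sq2, 1, 0.5), 1)
  expect_equal(trajectory_value(es2, sq2, 1, 0.75), 2)
})

test_that("stage likelihoods peak at the generating stage", {
  es <- zscore_event_set(list(c(1, 2), 1), z_max = c(3, 2))
  sq <- c(1, 3, 2)
  N <- 3
  # subject sitting exactly at the midpoint of stage 2, tight noise
  t_mid <- (2 + 0.5) / (N + 1)
  x <- vapply(1:2, function(i) trajectory_value(es, sq, i, t_mid), numeric(1))
  sl <- stage_likelihood_matrix(matrix(x, 1), es, sq, sigma = 0.05)
  expect_equal(unname(which.max(sl[1, ])), 3) # stage index 2 is column 3
  # high-resolution quadrature oracle agrees on the argmax
  sl_hr <- stage_likelihood_matrix(matrix(x, 1), es, sq, sigma = 0.05, K = 1000)
  expect_equal(which.max(sl[1, ]), which.max(sl_hr[1, ]))
  # baseline subject: everything at zero peaks at stage 0
  sl0 <- stage_likelihood_matrix(matrix(c(0, 0), 1), es, sq, sigma = 0.3)
  expect_equal(unname(which.max(sl0[1, ])), 1)
  expect_true(all(sl >= 0))
  expect_true(all(is.finite(sl)))
  expect_error(stage_likelihood_matrix(matrix(x, 1), es, sq, sigma = 0),
               "positive")
})

test_that("default quadrature converges to high-order quadrature", {
  set.seed(3)
  # gentle trajectories: per-entry agreement at 1e-4 between K = 100 and
  # K = 1000 on random 3-biomarker instances
  es <- simple_event_set(3)
  for (r in 1:5) {
    sq <- random_admissible_sequence(es)
    X <- matrix(rnorm(5 * 3, 1, 1.5), 5, 3)
    a <- stage_likelihood_matrix(X, es, sq, K = 100)
    b <- stage_likelihood_matrix(X, es, sq, K = 1000)
    expect_lt(max(abs(a - b) / b), 1e-4)
  }
  # steep terminal segments (z 3 -> 5): midpoint error grows with the
  # squared slope but stays inside the 1e-3 working tolerance
  es2 <- zscore_event_set(list(c(1, 2), c(1, 3), 1), z_max = c(3, 5, 2))
  for (r in 1:5) {
    sq <- random_admissible_sequence(es2)
    X <- matrix(rnorm(5 * 3, 1, 1.5), 5, 3)
    a <- stage_likelihood_matrix(X, es2, sq, K = 100)
    b <- stage_likelihood_matrix(X, es2, sq, K = 1000)
    expect_lt(max(abs(a - b) / b), 1e-3)
  }
})

test_that("sequence log likelihood matches a dense trapezoid oracle", {
  set.seed(4)
  es <- zscore_event_set(list(1), z_max = 2)
  x <- matrix(0.7, 1, 1) # J = 1, N = 1, on-trajectory value
  # matched resolution validates the likelihood formula itself
  ll <- sequence_log_likelihood(x, es, 1L, K = 5e4)$log_likelihood
  oracle <- trapezoid_loglik(x, es, 1L, n_points = 1e5)
  expect_lt(abs(ll - oracle) / abs(oracle), 1e-6)
  # the default quadrature order stays within working tolerance
  ll10 <- sequence_log_likelihood(x, es, 1L)$log_likelihood
  expect_lt(abs(ll10 - oracle) / abs(oracle), 1e-3)
})

test_that("log likelihood is additive over subjects and order invariant", {
  set.seed(5)
  es <- zscore_event_set(list(c(1, 2), 1), z_max = c(3, 2))
  sq <- c(1, 3, 2)
  X <- matrix(rnorm(8 * 2, 1, 1), 8, 2)
  ll <- sequence_log_likelihood(X, es, sq)$log_likelihood
  expect_equal(sequence_log_likelihood(rbind(X, X), es, sq)$log_likelihood,
               2 * ll)
  perm <- sample(8)
  expect_equal(sequence_log_likelihood(X[perm, ], es, sq)$log_likelihood, ll)
})

test_that("stage posteriors are proper distributions", {
  set.seed(6)
  es <- zscore_event_set(list(c(1, 2), 1), z_max = c(3, 2))
  X <- matrix(rnorm(20 * 2, 1, 2), 20, 2)
  res <- sequence_log_likelihood(X, es, c(3, 1, 2))
  expect_true(all(res$stage_posterior >= 0))
  expect_equal(unname(rowSums(res$stage_posterior)), rep(1, 20),
               tolerance = 1e-10)
})

test_that("missing values are marginalised out of the likelihood", {
  es <- zscore_event_set(list(1, 1), z_max = c(2, 2))
  sq <- c(1, 2)
  x <- matrix(c(0.5, NA), 1, 2)
  ll <- sequence_log_likelihood(x, es, sq, K = 2e4)$log_likelihood
  oracle <- trapezoid_loglik(x, es, sq, n_points = 6e4)
  expect_lt(abs(ll - oracle), 1e-6)
  # a fully missing subject contributes log(1) = 0
  x2 <- matrix(NA_real_, 1, 2)
  expect_equal(sequence_log_likelihood(x2, es, sq)$log_likelihood, 0)
})

test_that("mixture likelihood reduces correctly in degenerate cases", {
  set.seed(8)
  es <- zscore_event_set(list(c(1, 2), 1), z_max = c(3, 2))
  X <- matrix(rnorm(10 * 2, 1, 1), 10, 2)
  sq <- c(1, 3, 2)
  m1 <- sustain_model(es, sq)
  single <- sequence_log_likelihood(X, es, sq)
  mix1 <- mixture_log_likelihood(X, m1)
  expect_identical(mix1$log_likelihood, single$log_likelihood)
  # identical components with f = (1/2, 1/2) change nothing
  m2 <- sustain_model(es, rbind(sq, sq), fractions = c(0.5, 0.5))
  expect_equal(mixture_log_likelihood(X, m2)$log_likelihood,
               single$log_likelihood, tolerance = 1e-12)
  # subtype relabelling with matching fractions leaves the likelihood alone
  sq_b <- c(3, 1, 2)
  m_ab <- sustain_model(es, rbind(sq, sq_b), fractions = c(0.3, 0.7))
  m_ba <- sustain_model(es, rbind(sq_b, sq), fractions = c(0.7, 0.3))
  expect_equal(mixture_log_likelihood(X, m_ab)$log_likelihood,
               mixture_log_likelihood(X, m_ba)$log_likelihood,
               tolerance = 1e-12)
  expect_equal(rowSums(mixture_log_likelihood(X, m_ab)$subtype_posterior),
               rep(1, 10), tolerance = 1e-10)
  expect_error(sustain_model(es, rbind(sq, sq_b), fractions = c(0.6, 0.6)),
               "sum to 1")
})

test_that("well-separated subtypes give confident posteriors", {
  es <- simple_event_set(4)
  fwd <- 1:4
  bwd <- 4:1
  cfg <- simulation_config(es, rbind(fwd, bwd), n_subjects = 40,
                           sigma = 0.1, seed = 9,
                           stage_distribution = list(type = "pointmass",
                                                     t = 0.5, weights = 1))
  sim <- simulate_cohort(cfg)
  m <- sustain_model(es, rbind(fwd, bwd), fractions = c(0.5, 0.5),
                     sigma = 0.1)
  post <- mixture_log_likelihood(sim$data, m)$subtype_posterior
  from1 <- which(sim$truth$subtype == 1)
  expect_true(all(post[from1, 1] > 0.99))
})

test_that("models survive a JSON round trip", {
  es <- zscore_event_set(list(c(1, 2), 1), z_max = c(3, 2),
                         biomarker_names = c("hippocampus", "ventricles"))
  m <- sustain_model(es, rbind(c(1, 3, 2), c(3, 1, 2)),
                     fractions = c(0.4, 0.6), sigma = c(1, 1.5))
  path <- tempfile(fileext = ".json")
  write_sustain_model(m, path, seed = 123)
  m2 <- read_sustain_model(path)
  expect_equal(m2$sequences, m$sequences)
  expect_equal(m2$fractions, m$fractions)
  expect_equal(m2$sigma, m$sigma)
  expect_equal(m2$event_set$events$z, m$event_set$events$z)
  expect_equal(m2$event_set$biomarker_names, m$event_set$biomarker_names)
})
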