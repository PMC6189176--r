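test_that("a flat likelihood yields a near-uniform positional distribution", {
  es <- simple_event_set(3)
  # one fully missing subject: every sequence has identical likelihood
  X <- matrix(NA_real_, 1, 3)
  m <- sustain_model(es, c(1, 2, 3))
  mc <- mcmc_sample(X, m, n_samples = 1e5, seed = 30, thin = 20)
  pos <- positional_distribution(mc)$matrices[[1]]
  expect_equal(unname(rowSums(pos)), rep(1, 3), tolerance = 1e-12)
  expect_true(all(abs(pos - 1 / 3) < 0.03))
  # goodness of fit of sequence frequencies to uniform over all 6 orders
  keys <- apply(mc$sequences[, 1, ], 1, seq_key)
  gof <- suppressWarnings(stats::chisq.test(table(keys), p = rep(1 / 6, 6)))
  expect_gt(gof$p.value, 0.01)
})

test_that("the sampler matches the exact enumeration posterior", {
  es <- simple_event_set(3)
  sim <- one_cluster_sim(es, c(2, 1, 3), J = 12, sigma = 1, seed = 31)
  exact <- enumeration_posterior(sim$data, es)
  fit <- fit_single_cluster(sim$data, es, n_restarts = 5, seed = 32)
  mc <- mcmc_sample(sim$data, fit$model, n_samples = 5e4, seed = 33)
  keys <- apply(mc$sequences[, 1, ], 1, seq_key)
  tv <- tv_distance(keys, apply(exact$sequences, 1, seq_key), exact$prob)
  expect_lt(tv, 0.05)
})

test_that("chains are reproducible under a fixed seed", {
  es <- simple_event_set(3)
  sim <- one_cluster_sim(es, c(1, 2, 3), J = 10, sigma = 1, seed = 34)
  m <- sustain_model(es, c(1, 2, 3))
  a <- mcmc_sample(sim$data, m, n_samples = 2000, seed = 35)
  b <- mcmc_sample(sim$data, m, n_samples = 2000, seed = 35)
  expect_identical(a$sequences, b$sequences)
  expect_identical(a$log_likelihoods, b$log_likelihoods)
  expect_true(all(is.finite(a$log_likelihoods)))
})

test_that("sampled fractions stay on the simplex", {
  es <- simple_event_set(3)
  cfg <- simulation_config(es, rbind(c(1, 2, 3), c(3, 2, 1)),
                           n_subjects = 40, sigma = 0.5, seed = 36)
  sim <- simulate_cohort(cfg)
  m <- sustain_model(es, rbind(c(1, 2, 3), c(3, 2, 1)),
                     fractions = c(0.5, 0.5))
  mc <- mcmc_sample(sim$data, m, n_samples = 5000, seed = 37)
  expect_equal(rowSums(mc$fractions), rep(1, nrow(mc$fractions)),
               tolerance = 1e-12)
  expect_true(all(mc$fractions >= 0))
  expect_true(mc$acceptance_rate > 0 && mc$acceptance_rate <= 1)
  for (s in c(1, nrow(mc$fractions)))
    for (c in 1:2)
      expect_true(is_admissible_sequence(mc$sequences[s, c, ], es))
})

test_that("positional summaries behave on hand-built sample sets", {
  es <- simple_event_set(3)
  # all samples identical -> one-hot
  seqs <- array(rep(c(2, 3, 1), each = 5), dim = c(5, 1, 3))
  mc <- structure(list(sequences = seqs, event_set = es), class = "sustain_mcmc")
  pos <- positional_distribution(mc)$matrices[[1]]
  expect_equal(unname(pos[2, 1]), 1)
  expect_equal(unname(pos[3, 2]), 1)
  expect_equal(unname(pos[1, 3]), 1)
  expect_equal(sum(pos), 3)
  # two swapped orders in equal proportion -> 0.5/0.5 on the swapped events
  seqs2 <- array(NA_real_, dim = c(4, 1, 3))
  seqs2[1:2, 1, ] <- rep(c(1, 2, 3), each = 2)
  seqs2[3:4, 1, ] <- rep(c(2, 1, 3), each = 2)
  mc2 <- structure(list(sequences = seqs2, event_set = es),
                   class = "sustain_mcmc")
  pos2 <- positional_distribution(mc2)$matrices[[1]]
  expect_equal(unname(pos2[1, 1:2]), c(0.5, 0.5))
  expect_equal(unname(pos2[2, 1:2]), c(0.5, 0.5))
  expect_equal(unname(pos2[3, 3]), 1)
  expect_equal(unname(rowSums(pos2)), rep(1, 3), tolerance = 1e-12)
})

test_that("cumulative severity weights grow from 0 to 1 with stage", {
  es <- zscore_event_set(list(c(1, 2), 1), z_max = c(3, 2))
  m <- sustain_model(es, c(1, 3, 2))
  pos <- positional_distribution(m)
  w0 <- cumulative_severity_encoding(pos, 1, 0)
  expect_true(all(w0 == 0, na.rm = TRUE))
  wN <- cumulative_severity_encoding(pos, 1, 3)
  expect_equal(unname(wN["bm1", "z2"]), 1) # maximal retained z reached
  expect_equal(unname(wN["bm2", "z1"]), 1)
  prev <- w0
  for (k in 1:3) {
    w <- cumulative_severity_encoding(pos, 1, k)
    expect_true(all(w - prev >= -1e-12, na.rm = TRUE))
    prev <- w
  }
  # one-hot model: bm1 z1 occurs at position 1
  w1 <- cumulative_severity_encoding(pos, 1, 1)
  expect_equal(unname(w1["bm1", "z1"]), 1)
  expect_equal(unname(w1["bm2", "z1"]), 0)
})

test_that("likelihood traces mix on a small problem", {
  es <- simple_event_set(4)
  sim <- one_cluster_sim(es, c(1, 2, 3, 4), J = 40, sigma = 1, seed = 38)
  fit <- fit_single_cluster(sim$data, es, n_restarts = 5, seed = 39)
  mc <- mcmc_sample(sim$data, fit$model, n_samples = 2e4, seed = 40)
  ac <- stats::acf(mc$log_likelihoods, lag.max = 100, plot = FALSE)
  expect_lt(abs(ac$acf[101]), 0.5)
})

test_that("sample export writes a readable compressed table", {
  es <- simple_event_set(3)
  sim <- one_cluster_sim(es, c(1, 2, 3), J = 10, sigma = 1, seed = 41)
  m <- sustain_model(es, c(1, 2, 3))
  mc <- mcmc_sample(sim$data, m, n_samples = 50, seed = 42)
  path <- tempfile(fileext = ".csv.gz")
  write_mcmc_samples(mc, path)
  back <- read.csv(path)
  expect_equal(nrow(back), 50)
  expect_equal(back$s1_pos1, mc$sequences[, 1, 1])
  expect_equal(back$log_likelihood, mc$log_likelihoods)
})
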