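test_that("greedy repositioning finds the global optimum on small problems", {
  es <- simple_event_set(4)
  sim <- one_cluster_sim(es, c(2, 4, 1, 3), J = 200, sigma = 0.2, seed = 10)
  oracle <- exhaustive_ml_sequence(sim$data, es)
  set.seed(11)
  opt <- optimise_sequence_greedy(sim$data, es, random_admissible_sequence(es))
  expect_equal(opt$sequence, unname(oracle$sequence))
  expect_equal(opt$sequence, c(2, 4, 1, 3)) # truth at this noise level
  expect_equal(opt$log_likelihood, oracle$log_likelihood, tolerance = 1e-10)
  # fixed point: restarting from the optimum changes nothing
  again <- optimise_sequence_greedy(sim$data, es, opt$sequence)
  expect_equal(again$sequence, opt$sequence)
  expect_equal(again$n_passes, 1)
})

test_that("greedy ascent is monotone from random starts", {
  set.seed(12)
  es <- zscore_event_set(list(c(1, 2), 1, 1), z_max = c(3, 2, 2))
  sim <- one_cluster_sim(es, c(1, 3, 4, 2), J = 30, sigma = 1, seed = 13)
  for (r in 1:8) {
    s0 <- random_admissible_sequence(es)
    ll0 <- sequence_log_likelihood(sim$data, es, s0)$log_likelihood
    opt <- optimise_sequence_greedy(sim$data, es, s0)
    expect_gte(opt$log_likelihood, ll0)
    expect_true(all(diff(opt$trace) >= -1e-8))
    expect_true(is_admissible_sequence(opt$sequence, es))
  }
})

test_that("single-cluster fitting is seeded and reproducible", {
  es <- simple_event_set(4)
  sim <- one_cluster_sim(es, c(1, 2, 3, 4), J = 50, sigma = 0.5, seed = 14)
  f1 <- fit_single_cluster(sim$data, es, n_restarts = 1, seed = 99)
  f2 <- fit_single_cluster(sim$data, es, n_restarts = 1, seed = 99)
  expect_identical(f1$model$sequences, f2$model$sequences)
  expect_identical(f1$log_likelihood, f2$log_likelihood)
  f3 <- fit_single_cluster(sim$data, es, n_restarts = 5, seed = 99)
  expect_length(f3$restart_loglik, 5)
  expect_equal(f3$log_likelihood, max(f3$restart_loglik))
  expect_equal(
    mixture_log_likelihood(sim$data, f3$model)$log_likelihood,
    f3$log_likelihood)
})

test_that("fraction updates are the posterior means and never hurt", {
  set.seed(15)
  es <- zscore_event_set(list(c(1, 2), 1), z_max = c(3, 2))
  adm <- enumerate_admissible_sequences(es)
  for (r in 1:10) {
    X <- matrix(rnorm(30 * 2, runif(1, 0, 2), 1), 30, 2)
    pick <- sample(nrow(adm), 2)
    f0 <- runif(1, 0.2, 0.8)
    m <- sustain_model(es, adm[pick, ], fractions = c(f0, 1 - f0))
    before <- mixture_log_likelihood(X, m)$log_likelihood
    f_new <- update_fractions(X, m)
    expect_equal(sum(f_new), 1, tolerance = 1e-12)
    m$fractions <- f_new
    after <- mixture_log_likelihood(X, m)$log_likelihood
    expect_gte(after, before - 1e-9)
  }
})

test_that("splitting a cluster of identical subjects brings no gain", {
  es <- simple_event_set(3)
  X <- matrix(rep(c(0.8, 0.4, 0.1), each = 24), 24, 3)
  f1 <- fit_single_cluster(X, es, n_restarts = 4, seed = 16)
  cand <- split_cluster_em(X, f1$model, 1, n_restarts = 3, seed = 17)
  expect_s3_class(cand, "sustain_fit")
  expect_lte(cand$log_likelihood, f1$log_likelihood + 1e-6)
  expect_equal(sum(cand$model$fractions), 1, tolerance = 1e-12)
})

test_that("split-cluster E-M recovers two planted subtypes", {
  es <- simple_event_set(4)
  cfg <- simulation_config(es, rbind(1:4, 4:1), n_subjects = 160,
                           sigma = 0.5, seed = 18)
  sim <- simulate_cohort(cfg)
  f1 <- fit_single_cluster(sim$data, es, n_restarts = 5, seed = 19)
  cand <- split_cluster_em(sim$data, f1$model, 1, n_restarts = 5, seed = 20)
  expect_gt(cand$log_likelihood, f1$log_likelihood)
  # accuracy among subjects past onset; the very earliest and the fully
  # progressed are intrinsically ambiguous between subtypes
  rep <- recovery_report(sim, cand, t_min = 0.2)
  expect_gte(rep$assignment_accuracy, 0.75)
  # fitted orderings close to the planted ones (one-hot similarity)
  pos_fit <- positional_distribution(cand$model)
  sims <- sapply(1:2, function(ct) {
    one_hot <- positional_distribution(
      sustain_model(es, sim$sequences[ct, , drop = FALSE]))
    max(sapply(pos_fit$matrices, function(m)
      bhattacharyya_event_similarity(one_hot$matrices[[1]], m)))
  })
  expect_true(all(sims >= 0.9))
})

test_that("refusing to split clusters with fewer than two subjects", {
  es <- simple_event_set(3)
  set.seed(21)
  # all mass in cluster 1: cluster 2's ordering fits nothing
  X <- matrix(rnorm(20 * 3, 0, 0.2), 20, 3)
  m <- sustain_model(es, rbind(c(1, 2, 3), c(3, 2, 1)),
                     fractions = c(0.99, 0.01))
  post <- mixture_log_likelihood(X, m)$subtype_posterior
  empty <- which.min(colSums(post))
  if (sum(max.col(post) == empty) < 2) {
    cand <- split_cluster_em(X, m, empty, n_restarts = 2, seed = 22)
    expect_s3_class(cand, "sustain_split_infeasible")
  } else succeed("cluster not empty under this draw")
})

test_that("hierarchical fitting is monotone in C and degenerates to C = 1", {
  es <- simple_event_set(4)
  cfg <- simulation_config(es, rbind(1:4, 4:1), n_subjects = 120,
                           sigma = 0.5, seed = 23)
  sim <- simulate_cohort(cfg)
  h1 <- fit_hierarchical(sim$data, es, C_max = 1, n_restarts = 4, seed = 24)
  s1 <- fit_single_cluster(sim$data, es, n_restarts = 4, seed = 24)
  expect_identical(h1[[1]]$model$sequences, s1$model$sequences)
  expect_identical(h1[[1]]$log_likelihood, s1$log_likelihood)
  fits <- fit_hierarchical(sim$data, es, C_max = 3, n_restarts = 4, seed = 25)
  lls <- vapply(fits, `[[`, numeric(1), "log_likelihood")
  expect_true(all(diff(lls) >= -1e-8))
  for (C in seq_along(fits))
    expect_equal(sum(fits[[C]]$model$fractions), 1, tolerance = 1e-10)
})

test_that("multi-restart fitting attains the enumeration optimum", {
  es <- simple_event_set(4)
  hits <- 0
  for (trial in 1:5) {
    sim <- one_cluster_sim(es, c(3, 1, 4, 2), J = 100, sigma = 0.5,
                           seed = 100 + trial)
    fit <- fit_single_cluster(sim$data, es, n_restarts = 10,
                              seed = 200 + trial)
    oracle <- exhaustive_ml_sequence(sim$data, es)
    if (identical(fit$model$sequences[1, ], unname(oracle$sequence)))
      hits <- hits + 1
  }
  expect_gte(hits, 4)
})
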