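# Independent oracles and small fixtures used across the suite.

# Trapezoid-rule evaluation of the single-sequence log likelihood:
# log P(X|S) = sum_j log int_0^1 prod_i N(x_ij; g_i(t), sigma_i) dt,
# computed with a dense uniform grid and base-R dnorm. Deliberately
# independent of the package's quadrature kernel.
trapezoid_loglik <- function(X, event_set, sequence, sigma = NULL,
                             n_points = 1e5) {
  X <- if (inherits(X, "biomarker_dataset")) X$values else as.matrix(X)
  I <- ncol(X)
  if (is.null(sigma)) sigma <- rep(1, I)
  tg <- seq(0, 1, length.out = n_points + 1)
  G <- vapply(seq_len(I), function(i)
    trajectory_value(event_set, sequence, i, tg), numeric(n_points + 1))
  sum(vapply(seq_len(nrow(X)), function(j) {
    ld <- rowSums(vapply(seq_len(I), function(i) {
      if (is.na(X[j, i])) rep(0, n_points + 1)
      else dnorm(X[j, i], G[, i], sigma[i], log = TRUE)
    }, numeric(n_points + 1)))
    m <- max(ld)
    f <- exp(ld - m)
    m + log(sum((f[-1] + f[-length(f)]) / 2) / n_points)
  }, numeric(1)))
}

# Exhaustive maximum-likelihood sequence over all admissible orderings.
exhaustive_ml_sequence <- function(data, event_set, sigma = NULL, K = 10) {
  seqs <- enumerate_admissible_sequences(event_set)
  lls <- apply(seqs, 1, function(s)
    sequence_log_likelihood(data, event_set, s, sigma = sigma,
                            K = K)$log_likelihood)
  list(sequence = seqs[which.max(lls), ], log_likelihood = max(lls),
       all_loglik = lls, sequences = seqs)
}

# Exact posterior over admissible sequences under a flat prior.
enumeration_posterior <- function(data, event_set, sigma = NULL, K = 10) {
  ex <- exhaustive_ml_sequence(data, event_set, sigma = sigma, K = K)
  w <- exp(ex$all_loglik - max(ex$all_loglik))
  list(sequences = ex$sequences, prob = w / sum(w))
}

seq_key <- function(s) paste(s, collapse = "-")

# Event set with one z = 1 event per biomarker (N = n distinct biomarkers,
# all n! orderings admissible).
simple_event_set <- function(n, z_max = 2) {
  zscore_event_set(rep(list(1), n), z_max = rep(z_max, n),
                   biomarker_names = paste0("bm", seq_len(n)))
}

# Deterministic small cohort from one true sequence.
one_cluster_sim <- function(event_set, sequence, J, sigma = 1, seed = 1) {
  cfg <- simulation_config(event_set, matrix(sequence, 1), n_subjects = J,
                           sigma = sigma, seed = seed)
  simulate_cohort(cfg)
}

# Total-variation distance between an empirical distribution over sequence
# keys and an exact one.
tv_distance <- function(emp_keys, exact_keys, exact_prob) {
  tab <- table(emp_keys) / length(emp_keys)
  p_emp <- as.numeric(tab[exact_keys])
  p_emp[is.na(p_emp)] <- 0
  extra <- setdiff(names(tab), exact_keys)
  0.5 * (sum(abs(p_emp - exact_prob)) + sum(tab[extra]))
}

# Best-permutation label accuracy for cluster assignments (subtype identity
# is arbitrary).
best_perm_accuracy <- function(pred, truth, n_labels = max(pred, truth,
                                                           na.rm = TRUE)) {
  perms <- sustainr:::all_permutations(n_labels)
  max(vapply(perms, function(p) mean(p[pred] == truth, na.rm = TRUE),
             numeric(1)))
}
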