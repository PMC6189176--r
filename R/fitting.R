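#' Greedy optimisation of one sequence
#'
#' Coordinate ascent over event positions: each z-score event in turn is
#' tried at every admissible position with the order of the remaining
#' events fixed, and moved to the likelihood-maximising position. Passes
#' repeat until no event moves. Exact ties keep the current position, so
#' the ascent is strictly monotone and terminates.
#'
#' When `log_other`/`log_fraction` are supplied the objective is the full
#' mixture log likelihood `sum_j log(exp(log_other_j) + f_c P(x_j | S_c))`,
#' which is what the mixture E-M uses to update one subtype's sequence
#' while the other subtypes are held fixed.
#'
#' @param data a [biomarker_dataset()] or matrix.
#' @param event_set a [zscore_event_set()].
#' @param sequence admissible starting sequence.
#' @param sigma per-biomarker noise SD (default 1).
#' @param K quadrature points per stage (default 10).
#' @param log_other per-subject log likelihood contributed by the other
#'   mixture components (default `-Inf`: single-sequence objective).
#' @param log_fraction log mixture fraction of this component (default 0).
#' @param max_passes cap on full passes (default 100).
#' @return A list with `sequence`, `log_likelihood` (the objective at the
#'   optimum), `trace` (objective after each pass, non-decreasing) and
#'   `n_passes`.
#' @export
optimise_sequence_greedy <- function(data, event_set, sequence, sigma = NULL,
                                     K = 10, log_other = NULL,
                                     log_fraction = 0, max_passes = 100) {
  data <- check_data_model(data, event_set)
  if (!is_admissible_sequence(sequence, event_set))
    stop("starting `sequence` is not an admissible event ordering")
  a <- model_args(event_set, sigma, K)
  J <- nrow(data$values)
  if (is.null(log_other)) log_other <- rep(-Inf, J)
  if (length(log_other) != J) stop("`log_other` must have one entry per subject")
  cpp_optimise_sequence(data$values, as.integer(sequence), a$ev_bio, a$ev_z,
                        a$zmax, a$sigma, a$K, as.numeric(log_other),
                        log_fraction, as.integer(max_passes))
}

new_fit_result <- function(model, log_likelihood, restart_loglik, seed, trace,
                           config = list()) {
  structure(list(model = model, log_likelihood = log_likelihood,
                 restart_loglik = restart_loglik, seed = seed, trace = trace,
                 config = config),
            class = "sustain_fit")
}

#' @export
print.sustain_fit <- function(x, ...) {
  cat("fitted model, log likelihood", format(x$log_likelihood), "\n")
  if (length(x$restart_loglik) > 1)
    cat(sprintf("  %d restarts, spread best-worst = %.4g\n",
                length(x$restart_loglik),
                max(x$restart_loglik) - min(x$restart_loglik)))
  print(x$model)
  invisible(x)
}

#' Fit a single-subtype progression model
#'
#' Runs the greedy sequence optimiser from `n_restarts` uniformly random
#' admissible starting orders and keeps the best. All restart likelihoods
#' are recorded so convergence across start points can be inspected.
#'
#' @inheritParams optimise_sequence_greedy
#' @param n_restarts number of random starting sequences (default 25).
#' @param seed optional integer seed; when given, results are reproducible.
#' @return A `sustain_fit` with a one-subtype [sustain_model()], the best
#'   log likelihood, per-restart log likelihoods and the best restart's
#'   convergence trace.
#' @export
fit_single_cluster <- function(data, event_set, sigma = NULL, n_restarts = 25,
                               seed = NULL, K = 10, max_passes = 100) {
  stopifnot(n_restarts >= 1)
  if (!is.null(seed)) set.seed(seed)
  data <- check_data_model(data, event_set)
  best <- NULL
  lls <- numeric(n_restarts)
  for (r in seq_len(n_restarts)) {
    s0 <- random_admissible_sequence(event_set)
    opt <- optimise_sequence_greedy(data, event_set, s0, sigma = sigma, K = K,
                                    max_passes = max_passes)
    lls[r] <- opt$log_likelihood
    if (is.null(best) || opt$log_likelihood > best$log_likelihood) best <- opt
  }
  model <- sustain_model(event_set, best$sequence, fractions = 1, sigma = sigma)
  new_fit_result(model, best$log_likelihood, lls, seed, best$trace,
                 config = list(n_restarts = n_restarts, K = K,
                               max_passes = max_passes))
}

#' Update mixture fractions (E-M M-step)
#'
#' Sets each fraction to the mean over subjects of the per-subject subtype
#' posterior. As the exact M-step for mixture weights this never decreases
#' the mixture likelihood.
#'
#' @param data a [biomarker_dataset()] or matrix.
#' @param model a [sustain_model()].
#' @param K quadrature points per stage.
#' @return Updated fraction vector (sums to 1).
#' @export
update_fractions <- function(data, model, K = 10) {
  post <- mixture_log_likelihood(data, model, K = K)$subtype_posterior
  f <- colMeans(post)
  f / sum(f)
}

# alternate sequence and fraction updates until the mixture log likelihood
# stops improving; monotone by construction
em_refine <- function(data, model, K = 10, tol = 1e-6, max_iter = 100,
                      max_passes = 100) {
  data <- check_data_model(data, model$event_set)
  C <- nrow(model$sequences)
  cur <- mixture_log_likelihood(data, model, K = K)
  trace <- cur$log_likelihood
  for (iter in seq_len(max_iter)) {
    for (c in seq_len(C)) {
      lf <- log(model$fractions)
      if (C > 1) {
        W <- sweep(cur$subtype_loglik[, -c, drop = FALSE], 2, lf[-c], "+")
        log_other <- apply(W, 1, logsumexp)
      } else log_other <- rep(-Inf, nrow(data$values))
      opt <- optimise_sequence_greedy(data, model$event_set,
                                      model$sequences[c, ],
                                      sigma = model$sigma, K = K,
                                      log_other = log_other,
                                      log_fraction = lf[c],
                                      max_passes = max_passes)
      model$sequences[c, ] <- opt$sequence
      cur <- mixture_log_likelihood(data, model, K = K)
    }
    f <- colMeans(cur$subtype_posterior)
    model$fractions <- f / sum(f)
    cur <- mixture_log_likelihood(data, model, K = K)
    trace <- c(trace, cur$log_likelihood)
    n <- length(trace)
    if (trace[n] - trace[n - 1] < tol) break
  }
  list(model = model, log_likelihood = cur$log_likelihood, trace = trace)
}

#' Split one cluster of a fitted model
#'
#' Generates a candidate model with one extra subtype by splitting cluster
#' `cluster`: subjects hard-assigned (maximum posterior) to that cluster are
#' randomly bipartitioned, a single-subtype model is fitted to each half,
#' the pair initialises a two-subtype E-M on the cluster's subjects, and
#' the resulting pair replaces the original cluster before the full model
#' is refined by alternating sequence and fraction updates. The whole
#' procedure restarts from `n_restarts` random bipartitions and the best
#' full-model likelihood wins.
#'
#' @param data a [biomarker_dataset()] or matrix.
#' @param model fitted [sustain_model()] with `C - 1` subtypes.
#' @param cluster index of the cluster to split.
#' @param n_restarts random bipartitions to try (default 25).
#' @param seed optional integer seed.
#' @param K quadrature points per stage.
#' @param tol,max_iter E-M convergence controls.
#' @return A `sustain_fit` for the `C`-subtype candidate, or an object of
#'   class `sustain_split_infeasible` when the cluster holds fewer than two
#'   subjects under hard assignment.
#' @export
split_cluster_em <- function(data, model, cluster, n_restarts = 25,
                             seed = NULL, K = 10, tol = 1e-6, max_iter = 100) {
  stopifnot(inherits(model, "sustain_model"))
  if (!is.null(seed)) set.seed(seed)
  data <- check_data_model(data, model$event_set)
  C0 <- nrow(model$sequences)
  mix <- mixture_log_likelihood(data, model, K = K)
  hard <- max.col(mix$subtype_posterior, ties.method = "first")
  members <- which(hard == cluster)
  if (length(members) < 2)
    return(structure(list(cluster = cluster, n_members = length(members)),
                     class = "sustain_split_infeasible"))
  sub <- subset_dataset(data, members)
  es <- model$event_set
  best <- NULL
  lls <- numeric(n_restarts)
  for (r in seq_len(n_restarts)) {
    repeat {
      grp <- runif(length(members)) < 0.5
      if (any(grp) && any(!grp)) break
    }
    halves <- lapply(list(which(grp), which(!grp)), function(idx) {
      optimise_sequence_greedy(subset_dataset(sub, idx), es,
                               random_admissible_sequence(es),
                               sigma = model$sigma, K = K)$sequence
    })
    two <- sustain_model(es, rbind(halves[[1]], halves[[2]]),
                         fractions = c(mean(grp), mean(!grp)),
                         sigma = model$sigma)
    two <- em_refine(sub, two, K = K, tol = tol, max_iter = max_iter)$model
    seqs <- model$sequences[-cluster, , drop = FALSE]
    seqs <- rbind(seqs, two$sequences)
    f0 <- model$fractions[-cluster]
    f0 <- c(f0, model$fractions[cluster] * two$fractions)
    cand <- sustain_model(es, seqs, fractions = f0 / sum(f0),
                          sigma = model$sigma)
    ref <- em_refine(data, cand, K = K, tol = tol, max_iter = max_iter)
    lls[r] <- ref$log_likelihood
    if (is.null(best) || ref$log_likelihood > best$log_likelihood) best <- ref
  }
  new_fit_result(best$model, best$log_likelihood, lls, seed, best$trace,
                 config = list(n_restarts = n_restarts, K = K,
                               split_cluster = cluster))
}

#' Hierarchical fitting over increasing subtype counts
#'
#' Fits models with `C = 1 ... C_max` subtypes. The one-subtype model comes
#' from [fit_single_cluster()]; each `C`-subtype model is initialised from
#' the best `(C-1)`-subtype model by splitting each of its clusters in turn
#' ([split_cluster_em()]) and keeping the highest-likelihood candidate.
#' Should every candidate fall below the `(C-1)` likelihood (the split E-M
#' can only guarantee monotonicity from its own starting point), the model
#' falls back to duplicating the largest cluster with its fraction halved,
#' which reproduces the `(C-1)` likelihood exactly, so the in-sample
#' likelihood is non-decreasing in `C`.
#'
#' @inheritParams fit_single_cluster
#' @param C_max maximum number of subtypes.
#' @param tol,max_iter E-M convergence controls.
#' @return A list of `sustain_fit` objects indexed by `C`, of class
#'   `sustain_fit_list`. If every split at some `C` is infeasible the list
#'   is truncated with a warning.
#' @export
fit_hierarchical <- function(data, event_set, C_max, sigma = NULL,
                             n_restarts = 25, seed = NULL, K = 10,
                             tol = 1e-6, max_iter = 100) {
  stopifnot(C_max >= 1)
  if (!is.null(seed)) set.seed(seed)
  data <- check_data_model(data, event_set)
  fits <- vector("list", C_max)
  fits[[1]] <- fit_single_cluster(data, event_set, sigma = sigma,
                                  n_restarts = n_restarts, K = K)
  if (C_max > 1) for (C in 2:C_max) {
    prev <- fits[[C - 1]]$model
    cands <- lapply(seq_len(C - 1), function(c) {
      split_cluster_em(data, prev, c, n_restarts = n_restarts, K = K,
                       tol = tol, max_iter = max_iter)
    })
    ok <- !vapply(cands, inherits, logical(1), "sustain_split_infeasible")
    if (!any(ok)) {
      warning("all cluster splits infeasible at C = ", C,
              "; returning models up to C = ", C - 1)
      fits <- fits[seq_len(C - 1)]
      break
    }
    cands <- cands[ok]
    best <- cands[[which.max(vapply(cands, `[[`, numeric(1), "log_likelihood"))]]
    if (best$log_likelihood < fits[[C - 1]]$log_likelihood) {
      big <- which.max(prev$fractions)
      seqs <- rbind(prev$sequences, prev$sequences[big, ])
      f <- prev$fractions
      f <- c(f, f[big] / 2)
      f[big] <- f[big] / 2
      dup <- sustain_model(event_set, seqs, fractions = f, sigma = sigma)
      best <- new_fit_result(dup, fits[[C - 1]]$log_likelihood,
                             best$restart_loglik, seed,
                             fits[[C - 1]]$trace,
                             config = list(duplicated_cluster = big))
    }
    fits[[C]] <- best
  }
  structure(fits, class = "sustain_fit_list")
}

#' @export
print.sustain_fit_list <- function(x, ...) {
  cat("hierarchical fits, C = 1 ..", length(x), "\n")
  for (C in seq_along(x))
    cat(sprintf("  C = %d: log likelihood %s\n", C,
                format(x[[C]]$log_likelihood)))
  invisible(x)
}
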