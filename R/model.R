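#' Construct a subtype progression model
#'
#' A model is a mixture of `C` event orderings over a shared event set:
#' each subtype `c` has a sequence `S_c` (a permutation of the events) and a
#' mixture fraction `f_c`, plus a per-biomarker Gaussian noise level
#' `sigma`. With a single subtype this reduces to a plain event-based
#' progression model.
#'
#' @param event_set a [zscore_event_set()].
#' @param sequences integer matrix with one admissible sequence per row (a
#'   single sequence may be given as a vector).
#' @param fractions mixture proportions, one per subtype; must be
#'   non-negative and sum to 1 (tolerance 1e-8). Defaults to uniform.
#' @param sigma per-biomarker noise standard deviation in z-score units;
#'   defaults to 1 for every biomarker, the control-population standard
#'   deviation after z-scoring.
#' @return An object of class `sustain_model`.
#' @export
sustain_model <- function(event_set, sequences, fractions = NULL, sigma = NULL) {
  stopifnot(inherits(event_set, "zscore_event_set"))
  if (is.vector(sequences)) sequences <- matrix(sequences, nrow = 1)
  sequences <- matrix(as.integer(sequences), nrow = nrow(sequences))
  C <- nrow(sequences)
  if (ncol(sequences) != event_set$n_events)
    stop("sequences must have one column per event")
  for (c in seq_len(C))
    if (!is_admissible_sequence(sequences[c, ], event_set))
      stop("sequence ", c, " is not an admissible event ordering")
  if (is.null(fractions)) fractions <- rep(1 / C, C)
  if (length(fractions) != C) stop("one fraction per subtype required")
  if (any(fractions < 0)) stop("fractions must be non-negative")
  if (abs(sum(fractions) - 1) > 1e-8)
    stop("fractions must sum to 1 (got ", format(sum(fractions)), ")")
  I <- event_set$n_biomarkers
  if (is.null(sigma)) sigma <- rep(1, I)
  if (length(sigma) == 1L) sigma <- rep(sigma, I)
  if (length(sigma) != I || any(sigma <= 0))
    stop("`sigma` must be a positive value per biomarker")
  structure(list(event_set = event_set, sequences = sequences,
                 fractions = as.numeric(fractions), sigma = as.numeric(sigma)),
            class = "sustain_model")
}

#' @export
print.sustain_model <- function(x, ...) {
  C <- nrow(x$sequences)
  cat("subtype progression model:", C, if (C == 1) "subtype," else "subtypes,",
      x$event_set$n_events, "events\n")
  ev <- x$event_set$events
  for (c in seq_len(C)) {
    lab <- paste0(ev$biomarker_name[x$sequences[c, ]], ":z",
                  ev$z[x$sequences[c, ]])
    cat(sprintf("  subtype %d (f = %.3f): %s\n", c, x$fractions[c],
                paste(lab, collapse = " > ")))
  }
  invisible(x)
}

#' Piecewise-linear biomarker trajectory
#'
#' Evaluates `g_i(t)`: zero at `t = 0`, passing linearly through each of the
#' biomarker's z-score events at their sequence-determined times, and
#' reaching `z_max_i` at `t = 1`. Continuous and non-decreasing.
#'
#' @param event_set a [zscore_event_set()].
#' @param sequence admissible event ordering.
#' @param biomarker biomarker index (or name).
#' @param t model time(s) in `[0, 1]`.
#' @return Numeric vector of trajectory values, one per element of `t`.
#' @examples
#' es <- zscore_event_set(list(c(1, 2)), z_max = 3)
#' trajectory_value(es, c(1, 2), 1, c(1 / 6, 0.5, 1)) # 0.5 1.5 3.0
#' @export
trajectory_value <- function(event_set, sequence, biomarker, t) {
  if (is.character(biomarker))
    biomarker <- match(biomarker, event_set$biomarker_names)
  if (is.na(biomarker) || biomarker < 1 || biomarker > event_set$n_biomarkers)
    stop("unknown biomarker")
  if (any(t < 0 | t > 1)) stop("`t` must lie in [0, 1]")
  if (!is_admissible_sequence(sequence, event_set))
    stop("`sequence` is not an admissible event ordering")
  N <- event_set$n_events
  times <- seq_len(N) / (N + 1)
  in_bio <- event_set$events$biomarker[sequence] == biomarker
  kt <- c(0, times[in_bio], 1)
  kz <- c(0, event_set$events$z[sequence][in_bio], event_set$z_max[biomarker])
  approx(kt, kz, xout = t, method = "linear", ties = "ordered")$y
}

# shared unpacking for the C++ kernels
model_args <- function(event_set, sigma, K) {
  if (is.null(sigma)) sigma <- rep(1, event_set$n_biomarkers)
  if (length(sigma) == 1L) sigma <- rep(sigma, event_set$n_biomarkers)
  if (any(sigma <= 0)) stop("`sigma` must be strictly positive")
  if (K < 1) stop("quadrature order `K` must be at least 1")
  list(ev_bio = as.integer(event_set$events$biomarker),
       ev_z = as.numeric(event_set$events$z),
       zmax = as.numeric(event_set$z_max),
       sigma = as.numeric(sigma), K = as.integer(K))
}

check_data_model <- function(data, event_set) {
  data <- as_dataset(data)
  if (ncol(data$values) != event_set$n_biomarkers)
    stop("data columns do not align with the event set's biomarkers")
  data
}

#' Per-stage data likelihood matrix
#'
#' For one sequence, returns the `J x (N+1)` matrix whose entry `(j, k)` is
#' the integral of the product of per-biomarker normal densities over the
#' stage-`k` time interval (columns are stages `0..N`). The integral is
#' approximated by a composite midpoint rule with `K` points per stage.
#' Stage 0 means no event has completed.
#'
#' @param data a [biomarker_dataset()] or matrix.
#' @param event_set a [zscore_event_set()].
#' @param sequence admissible event ordering.
#' @param sigma per-biomarker noise SD (default 1).
#' @param K quadrature points per stage (default 10).
#' @param log return log likelihoods instead of likelihoods.
#' @return `J x (N+1)` matrix; with attribute `subject_loglik` holding the
#'   per-subject log marginal `log P(x_j | S)`.
#' @export
stage_likelihood_matrix <- function(data, event_set, sequence, sigma = NULL,
                                    K = 10, log = FALSE) {
  data <- check_data_model(data, event_set)
  if (!is_admissible_sequence(sequence, event_set))
    stop("`sequence` is not an admissible event ordering")
  a <- model_args(event_set, sigma, K)
  out <- cpp_stage_loglik(data$values, as.integer(sequence), a$ev_bio, a$ev_z,
                          a$zmax, a$sigma, a$K)
  if (!log) {
    slk <- attr(out, "subject_loglik")
    out <- exp(out)
    attr(out, "subject_loglik") <- slk
  }
  colnames(out) <- paste0("stage", 0:event_set$n_events)
  rownames(out) <- data$subject_ids
  out
}

#' Log likelihood of the data under one sequence
#'
#' Computes `log P(X | S)`, summing over subjects the log of the
#' stage-integrated density, together with each subject's posterior
#' distribution over stages (uniform stage prior).
#'
#' @inheritParams stage_likelihood_matrix
#' @return A list with `log_likelihood` (scalar), `subject_loglik` (length
#'   `J`) and `stage_posterior` (`J x (N+1)` matrix, rows summing to 1).
#' @export
sequence_log_likelihood <- function(data, event_set, sequence, sigma = NULL,
                                    K = 10) {
  stage <- stage_likelihood_matrix(data, event_set, sequence, sigma = sigma,
                                   K = K, log = TRUE)
  subject <- attr(stage, "subject_loglik")
  post <- exp(stage - subject) # rows of stage already sum (in log) to subject
  attr(post, "subject_loglik") <- NULL
  list(log_likelihood = sum(subject), subject_loglik = subject,
       stage_posterior = post)
}

#' Log likelihood of the data under a subtype mixture
#'
#' Computes `log P(X | M) = sum_j log sum_c f_c P(x_j | S_c)` together with
#' the per-subject subtype posterior. With a single subtype the result
#' equals [sequence_log_likelihood()].
#'
#' @param data a [biomarker_dataset()] or matrix.
#' @param model a [sustain_model()].
#' @param K quadrature points per stage (default 10).
#' @return A list with `log_likelihood`, `subject_loglik` (length `J`),
#'   `subtype_loglik` (`J x C` matrix of `log P(x_j | S_c)`) and
#'   `subtype_posterior` (`J x C`, rows summing to 1).
#' @export
mixture_log_likelihood <- function(data, model, K = 10) {
  stopifnot(inherits(model, "sustain_model"))
  data <- check_data_model(data, model$event_set)
  a <- model_args(model$event_set, model$sigma, K)
  C <- nrow(model$sequences)
  if (abs(sum(model$fractions) - 1) > 1e-8)
    stop("model fractions must sum to 1")
  L <- vapply(seq_len(C), function(c) {
    cpp_subject_loglik(data$values, model$sequences[c, ], a$ev_bio, a$ev_z,
                       a$zmax, a$sigma, a$K)
  }, numeric(nrow(data$values)))
  L <- matrix(L, ncol = C)
  if (C == 1L) {
    subject <- L[, 1]
    post <- matrix(1, nrow(L), 1)
  } else {
    W <- sweep(L, 2, log(model$fractions), "+")
    subject <- apply(W, 1, logsumexp)
    post <- exp(W - subject)
  }
  list(log_likelihood = sum(subject), subject_loglik = subject,
       subtype_loglik = L, subtype_posterior = post)
}

#' Serialise a model to JSON
#'
#' Writes the event table, sequences, fractions, noise levels and metadata
#' (seed, package version) so a fit can be reloaded or applied to new
#' subjects.
#'
#' @param model a [sustain_model()].
#' @param path output file path.
#' @param seed optional seed recorded in the metadata.
#' @export
write_sustain_model <- function(model, path, seed = NULL) {
  stopifnot(inherits(model, "sustain_model"))
  es <- model$event_set
  obj <- list(
    events = es$events[, c("biomarker", "biomarker_name", "z")],
    z_max = es$z_max,
    biomarker_names = es$biomarker_names,
    sequences = model$sequences,
    fractions = model$fractions,
    sigma = model$sigma,
    metadata = list(seed = seed,
                    version = as.character(utils::packageVersion("sustainr")))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a model from JSON
#'
#' @param path file written by [write_sustain_model()].
#' @return A [sustain_model()].
#' @export
read_sustain_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  z_list <- split(obj$events$z, obj$events$biomarker)
  es <- zscore_event_set(z_list[order(as.integer(names(z_list)))],
                         z_max = obj$z_max,
                         biomarker_names = obj$biomarker_names)
  seqs <- matrix(as.integer(obj$sequences), ncol = es$n_events)
  sustain_model(es, seqs, fractions = obj$fractions, sigma = obj$sigma)
}
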