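#' Subtypes-only comparator: Gaussian mixture clustering
#'
#' Clusters subjects on the similarity of their biomarker profiles without
#' modelling disease stage: a mixture of Gaussians with unknown per-cluster
#' mean and per-dimension variance (diagonal covariance; full covariance
#' behind a flag). The number of clusters is chosen with the same
#' cross-validated information criterion and parsimony rule as the
#' progression model, so the two are directly comparable. Fitting uses
#' the mclust implementation of mixture E-M.
#'
#' @param data a [biomarker_dataset()] or matrix (conventionally restricted
#'   to a single diagnostic group).
#' @param C_max maximum number of clusters.
#' @param n_folds folds for the CVIC (default 10).
#' @param seed optional integer seed for folds and E-M initialisation.
#' @param diagonal use diagonal covariance (default `TRUE`); `FALSE` allows
#'   full covariance.
#' @return An object of class `subtypes_only_fit`: the selected mclust
#'   model, `cvic` per cluster count, `selected_C`, per-subject `posterior`
#'   matrix and cluster assignment.
#' @export
fit_subtypes_only <- function(data, C_max, n_folds = 10, seed = NULL,
                              diagonal = TRUE) {
  data <- as_dataset(data)
  X <- data$values
  if (anyNA(X)) stop("the Gaussian-mixture comparator needs complete data")
  J <- nrow(X)
  if (C_max > J) stop("more clusters than subjects")
  if (!is.null(seed)) set.seed(seed)
  model_name <- if (diagonal) "VVI" else "VVV"
  folds <- make_folds(J, n_folds)
  oos <- matrix(NA_real_, n_folds, C_max)
  for (fd in seq_len(n_folds)) {
    test <- folds[[fd]]
    train <- setdiff(seq_len(J), test)
    for (C in seq_len(C_max)) {
      fit <- gmm_fit(X[train, , drop = FALSE], C, model_name)
      if (is.null(fit)) next
      dens <- mclust::dens(data = X[test, , drop = FALSE],
                           modelName = fit$modelName,
                           parameters = fit$parameters, logarithm = TRUE)
      oos[fd, C] <- sum(dens)
    }
  }
  cvic <- -2 * colSums(oos)
  names(cvic) <- paste0("C", seq_len(C_max))
  selected_C <- select_n_subtypes(cvic)
  final <- gmm_fit(X, selected_C, model_name)
  if (is.null(final)) stop("mixture fit failed at the selected cluster count")
  post <- if (selected_C == 1) matrix(1, J, 1) else final$z
  structure(list(model = final, cvic = cvic, oos_loglik = oos,
                 selected_C = selected_C, posterior = post,
                 cluster = max.col(post, ties.method = "first"),
                 model_name = model_name, seed = seed),
            class = "subtypes_only_fit")
}

# mclust fit with graceful degradation when a model is singular
gmm_fit <- function(X, C, model_name) {
  fit <- tryCatch(
    suppressWarnings(mclust::Mclust(X, G = C, modelNames = model_name,
                                    verbose = FALSE)),
    error = function(e) NULL)
  if (is.null(fit) && model_name == "VVI")
    fit <- tryCatch(
      suppressWarnings(mclust::Mclust(X, G = C, modelNames = "EEI",
                                      verbose = FALSE)),
      error = function(e) NULL)
  fit
}

#' @export
print.subtypes_only_fit <- function(x, ...) {
  cat("subtypes-only Gaussian mixture:", x$selected_C,
      "cluster(s) selected by CVIC\n")
  print(round(x$cvic, 2))
  invisible(x)
}

#' Stages-only comparator: single-sequence progression model
#'
#' The stages-only model is the progression model with exactly one
#' subtype: all subjects are assumed to sample a single common event
#' ordering, so stage heterogeneity is modelled but subtype heterogeneity
#' is not. Delegates to [fit_single_cluster()]; identical to
#' [fit_hierarchical()] with `C_max = 1`.
#'
#' @inheritParams fit_single_cluster
#' @return A `sustain_fit` with a one-subtype model.
#' @export
fit_stages_only <- function(data, event_set, sigma = NULL, n_restarts = 25,
                            seed = NULL, K = 10) {
  fit_single_cluster(data, event_set, sigma = sigma, n_restarts = n_restarts,
                     seed = seed, K = K)
}
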