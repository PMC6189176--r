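#' Ten-fold cross-validation of the subtype count
#'
#' Partitions subjects into folds (seeded, optionally stratified by a
#' label), refits the hierarchical model on each training set and evaluates
#' every candidate subtype count on the held-out subjects. The
#' cross-validation information criterion is
#' `CVIC(C) = -2 * sum over folds of the out-of-sample log likelihood`,
#' and the subtype count is chosen by [select_n_subtypes()].
#'
#' @param data a [biomarker_dataset()] or matrix.
#' @param event_set a [zscore_event_set()].
#' @param C_max maximum number of subtypes considered.
#' @param n_folds number of folds (default 10).
#' @param seed optional integer seed controlling the fold assignment and
#'   the per-fold fitting.
#' @param n_restarts restarts per fold fit; fold fits commonly use fewer
#'   restarts than the headline fit.
#' @param stratify_by optional per-subject label; folds then balance label
#'   frequencies.
#' @param sigma,K,tol,max_iter passed to [fit_hierarchical()].
#' @return An object of class `sustain_cv`: `folds` (list of test index
#'   vectors), `fold_fits` (per fold, a `sustain_fit_list`),
#'   `oos_loglik` (folds x C matrix), `cvic` (per C), `selected_C`.
#' @export
cross_validate <- function(data, event_set, C_max, n_folds = 10, seed = NULL,
                           n_restarts = 25, stratify_by = NULL, sigma = NULL,
                           K = 10, tol = 1e-6, max_iter = 100) {
  stopifnot(n_folds >= 2)
  if (!is.null(seed)) set.seed(seed)
  data <- check_data_model(data, event_set)
  J <- nrow(data$values)
  if (J < n_folds) stop("need at least one subject per fold")
  folds <- make_folds(J, n_folds, stratify_by)
  fold_fits <- vector("list", n_folds)
  oos <- matrix(NA_real_, n_folds, C_max)
  for (fd in seq_len(n_folds)) {
    test <- folds[[fd]]
    train <- setdiff(seq_len(J), test)
    fits <- fit_hierarchical(subset_dataset(data, train), event_set,
                             C_max = C_max, sigma = sigma,
                             n_restarts = n_restarts, K = K, tol = tol,
                             max_iter = max_iter)
    fold_fits[[fd]] <- fits
    test_data <- subset_dataset(data, test)
    for (C in seq_along(fits))
      oos[fd, C] <- mixture_log_likelihood(test_data, fits[[C]]$model,
                                           K = K)$log_likelihood
  }
  cvic <- -2 * colSums(oos)
  names(cvic) <- paste0("C", seq_len(C_max))
  structure(list(folds = folds, fold_fits = fold_fits, oos_loglik = oos,
                 cvic = cvic, selected_C = select_n_subtypes(cvic),
                 seed = seed, n_folds = n_folds),
            class = "sustain_cv")
}

#' @export
print.sustain_cv <- function(x, ...) {
  cat("cross-validation over", length(x$folds), "folds\n")
  for (C in seq_along(x$cvic))
    cat(sprintf("  C = %d: CVIC = %.2f%s\n", C, x$cvic[C],
                if (C == x$selected_C) "  <- selected" else ""))
  invisible(x)
}

make_folds <- function(J, n_folds, stratify_by = NULL) {
  if (is.null(stratify_by)) {
    idx <- sample(J)
    return(unname(split(idx, rep_len(seq_len(n_folds), J))))
  }
  if (length(stratify_by) != J) stop("`stratify_by` must cover every subject")
  folds <- vector("list", n_folds)
  for (lev in unique(stratify_by)) {
    idx <- sample(which(stratify_by == lev))
    parts <- split(idx, rep_len(seq_len(n_folds), length(idx)))
    for (fd in seq_along(parts)) folds[[fd]] <- c(folds[[fd]], parts[[fd]])
  }
  folds
}

#' Choose the number of subtypes from CVIC values
#'
#' Parsimony rule: the smallest subtype count whose CVIC lies within 6 of
#' the minimum CVIC is selected, so a more complex model must beat the
#' simpler one by at least 6 CVIC units (3 log-likelihood units) to be
#' preferred.
#'
#' @param cvic numeric vector of CVIC values indexed by `C = 1, 2, ...`
#'   (`NA` entries are skipped).
#' @return Selected subtype count (integer).
#' @examples
#' select_n_subtypes(c(210, 203, 201)) # 2
#' @export
select_n_subtypes <- function(cvic) {
  if (length(cvic) < 1 || all(is.na(cvic))) stop("no CVIC values")
  ok <- which(!is.na(cvic) & (cvic - min(cvic, na.rm = TRUE)) < 6)
  unname(ok[1])
}

pos_matrices <- function(x) {
  if (inherits(x, "positional_distribution")) return(x$matrices)
  if (inherits(x, c("sustain_mcmc", "sustain_model")))
    return(positional_distribution(x)$matrices)
  if (is.matrix(x)) return(list(x))
  if (is.list(x)) return(x)
  stop("cannot interpret positional distributions from class ", class(x)[1])
}

#' Bhattacharyya similarity between two progression patterns
#'
#' For each event, the Bhattacharyya coefficient
#' `sum_k sqrt(p_k * q_k)` between its two positional distributions; the
#' returned similarity is the mean over events. Ranges from 0 (disjoint
#' positional support for every event) to 1 (identical distributions).
#'
#' @param pos_a,pos_b positional distributions for one subtype each: an
#'   `N x N` event x position probability matrix (rows summing to 1), or a
#'   [positional_distribution()] holding a single subtype.
#' @return Similarity in `[0, 1]`.
#' @examples
#' p <- diag(3)
#' bhattacharyya_event_similarity(p, p) # 1
#' @export
bhattacharyya_event_similarity <- function(pos_a, pos_b) {
  a <- pos_matrices(pos_a)
  b <- pos_matrices(pos_b)
  if (length(a) != 1 || length(b) != 1)
    stop("supply the positional distribution of a single subtype on each side")
  a <- a[[1]]; b <- b[[1]]
  if (!all(dim(a) == dim(b)))
    stop("positional distributions are over different event sets")
  mean(rowSums(sqrt(a * b)))
}

# greedy maximum-similarity matching of fold subtypes to reference subtypes
match_subtypes <- function(ref_mats, fold_mats) {
  n_ref <- length(ref_mats)
  n_fold <- length(fold_mats)
  sim <- matrix(NA_real_, n_ref, n_fold)
  for (i in seq_len(n_ref)) for (j in seq_len(n_fold))
    sim[i, j] <- bhattacharyya_event_similarity(ref_mats[[i]], fold_mats[[j]])
  match <- rep(NA_integer_, n_ref)
  matched_sim <- rep(NA_real_, n_ref)
  s <- sim
  for (step in seq_len(min(n_ref, n_fold))) {
    ij <- arrayInd(which.max(s), dim(s))
    match[ij[1]] <- ij[2]
    matched_sim[ij[1]] <- sim[ij[1], ij[2]]
    s[ij[1], ] <- -Inf
    s[, ij[2]] <- -Inf
  }
  list(match = match, similarity = matched_sim)
}

#' Cross-validation similarity of subtype progression patterns
#'
#' Measures how consistently each subtype's progression pattern re-emerges
#' across cross-validation folds: each full-data subtype is paired with its
#' most similar fold subtype (greedy maximum-similarity matching) and the
#' CVS is the mean matched [bhattacharyya_event_similarity()] over folds.
#'
#' @param full_samples positional information for the full-data model: a
#'   [mcmc_sample()] result, [positional_distribution()] or fitted model.
#' @param fold_samples list with one such object per fold.
#' @return Numeric vector of CVS values, one per full-data subtype, in
#'   `[0, 1]`. Folds offering fewer subtypes than the full model leave the
#'   unmatched subtypes out of the mean, with a warning.
#' @export
cross_validation_similarity <- function(full_samples, fold_samples) {
  ref <- pos_matrices(full_samples)
  per_fold <- matrix(NA_real_, length(fold_samples), length(ref))
  for (fd in seq_along(fold_samples)) {
    fm <- pos_matrices(fold_samples[[fd]])
    per_fold[fd, ] <- match_subtypes(ref, fm)$similarity
  }
  if (anyNA(per_fold))
    warning("some folds had fewer subtypes than the full model; ",
            "unmatched subtypes excluded from the mean")
  cvs <- colMeans(per_fold, na.rm = TRUE)
  names(cvs) <- paste0("subtype", seq_along(ref))
  cvs
}
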