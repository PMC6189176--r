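#' Configure a synthetic cohort
#'
#' Describes a ground-truth generative scenario: an event set, true subtype
#' sequences and mixture fractions, a cohort size, a stage (disease time)
#' distribution, per-biomarker noise, an optional equicorrelated noise
#' structure and an optional fraction of outlier subjects unrelated to any
#' progression pattern.
#'
#' @param event_set a [zscore_event_set()].
#' @param sequences true sequences, one per row; or the number of subtypes
#'   to draw as random admissible sequences at simulation time.
#' @param fractions subtype mixture proportions (default uniform).
#' @param n_subjects cohort size `J`.
#' @param stage_distribution distribution of disease time `t` on `[0, 1]`:
#'   `list(type = "uniform")` (default, matching the model's uniform
#'   prior), `list(type = "truncnorm", mean =, sd =)`, or
#'   `list(type = "pointmass", t =, weights =)` to emulate diagnostic-group
#'   structure.
#' @param sigma per-biomarker noise SD (default 1, the control-population
#'   SD after z-scoring).
#' @param rho equicorrelation of the noise across biomarkers in `[0, 1)`
#'   (single shared factor; default 0).
#' @param outlier_fraction fraction of subjects drawn from an unrelated
#'   noise model in `[0, 1)` (default 0).
#' @param seed optional integer seed stored with the config.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(event_set, sequences, fractions = NULL,
                              n_subjects,
                              stage_distribution = list(type = "uniform"),
                              sigma = 1, rho = 0, outlier_fraction = 0,
                              seed = NULL) {
  stopifnot(inherits(event_set, "zscore_event_set"))
  if (is.matrix(sequences)) {
    for (c in seq_len(nrow(sequences)))
      if (!is_admissible_sequence(sequences[c, ], event_set))
        stop("true sequence ", c, " is not admissible")
    C <- nrow(sequences)
  } else {
    C <- as.integer(sequences)
    if (C < 1) stop("need at least one subtype")
    sequences <- NULL
  }
  if (is.null(fractions)) fractions <- rep(1 / C, C)
  if (length(fractions) != C || abs(sum(fractions) - 1) > 1e-8)
    stop("fractions must sum to 1 with one entry per subtype")
  I <- event_set$n_biomarkers
  if (length(sigma) == 1L) sigma <- rep(sigma, I)
  if (any(sigma <= 0)) stop("sigma must be positive")
  if (rho < 0 || rho >= 1) stop("rho must be in [0, 1)")
  if (outlier_fraction < 0 || outlier_fraction >= 1)
    stop("outlier_fraction must be in [0, 1)")
  if (!stage_distribution$type %in% c("uniform", "truncnorm", "pointmass"))
    stop("unknown stage distribution type")
  structure(list(event_set = event_set, sequences = sequences, n_subtypes = C,
                 fractions = fractions, n_subjects = as.integer(n_subjects),
                 stage_distribution = stage_distribution, sigma = sigma,
                 rho = rho, outlier_fraction = outlier_fraction, seed = seed),
            class = "simulation_config")
}

draw_stage_time <- function(n, dist) {
  switch(dist$type,
    uniform = runif(n),
    truncnorm = {
      # inverse-CDF sampling of a normal truncated to [0, 1]
      lo <- stats::pnorm(0, dist$mean, dist$sd)
      hi <- stats::pnorm(1, dist$mean, dist$sd)
      stats::qnorm(lo + runif(n) * (hi - lo), dist$mean, dist$sd)
    },
    pointmass = {
      k <- sample.int(length(dist$t), n, replace = TRUE, prob = dist$weights)
      dist$t[k]
    })
}

#' Simulate a cohort from known progression patterns
#'
#' Each non-outlier subject draws a subtype from the mixture fractions and
#' a disease time from the stage distribution; the observation is the
#' subtype's trajectory value at that time plus (optionally
#' equicorrelated) Gaussian noise. Outlier subjects follow no progression
#' pattern: standard noise around zero with an independent standard-normal
#' shift per biomarker, plus the cohort noise. The ground truth (subtype,
#' time and discrete stage per subject) is returned alongside the data.
#'
#' @param config a [simulation_config()].
#' @param seed optional integer seed (overrides the config's).
#' @return A list with `data` (a [biomarker_dataset()], labels holding the
#'   true subtype), `truth` (data frame: `subject_id`, `subtype` (`NA` for
#'   outliers), `t`, `stage`), `sequences` (the true sequences) and
#'   `config`.
#' @export
simulate_cohort <- function(config, seed = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (is.null(seed)) seed <- config$seed
  if (!is.null(seed)) set.seed(seed)
  es <- config$event_set
  I <- es$n_biomarkers
  N <- es$n_events
  J <- config$n_subjects
  C <- config$n_subtypes
  seqs <- config$sequences
  if (is.null(seqs))
    seqs <- t(vapply(seq_len(C), function(c) random_admissible_sequence(es),
                     integer(N)))
  subtype <- sample.int(C, J, replace = TRUE, prob = config$fractions)
  t <- draw_stage_time(J, config$stage_distribution)
  outlier <- runif(J) < config$outlier_fraction
  X <- matrix(NA_real_, J, I, dimnames = list(NULL, es$biomarker_names))
  for (c in seq_len(C)) {
    idx <- which(subtype == c & !outlier)
    if (!length(idx)) next
    for (i in seq_len(I))
      X[idx, i] <- trajectory_value(es, seqs[c, ], i, t[idx])
  }
  out_idx <- which(outlier)
  for (j in out_idx)
    X[j, ] <- rnorm(I) # standard noise around 0, random per-biomarker shift
  # equicorrelated Gaussian noise via a shared standard-normal factor
  shared <- rnorm(J)
  eps <- matrix(rnorm(J * I), J, I)
  rho <- config$rho
  noise <- sqrt(rho) * shared %o% rep(1, I) + sqrt(1 - rho) * eps
  X <- X + sweep(noise, 2, config$sigma, "*")
  subtype[outlier] <- NA_integer_
  t[outlier] <- NA_real_
  stage <- integer(J)
  for (j in seq_len(J)) {
    if (outlier[j]) { stage[j] <- NA_integer_; next }
    stage[j] <- sum(seq_len(N) / (N + 1) <= t[j])
  }
  ids <- sprintf("sim%04d", seq_len(J))
  truth <- data.frame(subject_id = ids, subtype = subtype, t = t,
                      stage = stage, stringsAsFactors = FALSE)
  data <- biomarker_dataset(X, subject_ids = ids,
                            labels = ifelse(is.na(subtype), "outlier",
                                            paste0("subtype", subtype)))
  list(data = data, truth = truth, sequences = seqs, config = config)
}

#' Canonical two-subtype benchmark scenario
#'
#' The package's reference validation scenario: 5 biomarkers with events at
#' z = 1, 2, 3 (15 events, terminal z 5), two equally sized subtypes, 500
#' subjects, unit noise, uniform stages. The subtypes sweep the biomarkers
#' in opposite orders, each biomarker passing through its three thresholds
#' in turn before the next biomarker starts — emulating phenotypes that are
#' distinguished by which regions become abnormal first, as observed
#' subtypes in neurodegenerative disease are. These are the conditions
#' under which parameter recovery is validated end to end.
#'
#' @param n_subjects cohort size (default 500).
#' @param outlier_fraction fraction of unrelated outlier subjects
#'   (default 0).
#' @param seed optional integer seed stored in the config.
#' @return A [simulation_config()].
#' @export
canonical_scenario <- function(n_subjects = 500, outlier_fraction = 0,
                               seed = NULL) {
  es <- zscore_event_set(c(1, 2, 3), z_max = 5, n_biomarkers = 5)
  id <- function(b) 3L * (b - 1L) + 1:3 # events of biomarker b, z = 1, 2, 3
  fwd <- as.integer(unlist(lapply(1:5, id)))
  rev_ <- as.integer(unlist(lapply(5:1, id)))
  simulation_config(es, rbind(fwd, rev_), fractions = c(0.5, 0.5),
                    n_subjects = n_subjects, sigma = 1,
                    outlier_fraction = outlier_fraction, seed = seed)
}

#' Recovery metrics against simulation ground truth
#'
#' Compares a fitted model (and optionally MCMC samples, assignments and a
#' cross-validation result) with the generative truth of a simulated
#' cohort. Subtype identities are arbitrary, so the subject-level accuracy
#' is maximised over subtype permutations, and the same permutation then
#' scores fractions and positional similarity.
#'
#' @param truth the `truth` data frame (and `sequences`) from
#'   [simulate_cohort()]: pass the whole simulation list.
#' @param fit a `sustain_fit` (or `sustain_model`).
#' @param samples optional [mcmc_sample()] result for positional similarity
#'   against the one-hot true sequences.
#' @param assignments optional [assign_subjects()] result; used for the
#'   subject-level accuracy and the stage-vs-time Spearman correlation.
#' @param cv optional [cross_validate()] result for selected-count
#'   correctness.
#' @param t_min restrict accuracy to subjects with true `t` above this
#'   value (early subjects carry little subtype information; default 0).
#' @return A list of metrics: `assignment_accuracy`, `permutation`,
#'   `fraction_error`, `positional_similarity` (per true subtype),
#'   `stage_spearman`, `selected_C`, `selected_C_correct` (entries `NULL`
#'   when their inputs were not supplied).
#' @export
recovery_report <- function(truth, fit, samples = NULL, assignments = NULL,
                            cv = NULL, t_min = 0) {
  sim <- truth
  truth_df <- sim$truth
  true_seqs <- sim$sequences
  C_true <- nrow(true_seqs)
  model <- if (inherits(fit, "sustain_fit")) fit$model else fit
  C_fit <- nrow(model$sequences)
  perms <- all_permutations(max(C_true, C_fit))
  out <- list()

  pred <- NULL
  if (!is.null(assignments))
    pred <- assignments$table$ml_subtype
  else if (C_fit >= 1 && !is.null(sim$data)) {
    mix <- mixture_log_likelihood(sim$data, model)
    pred <- max.col(mix$subtype_posterior, ties.method = "first")
  }
  keep <- !is.na(truth_df$subtype) & !is.na(truth_df$t) & truth_df$t > t_min
  best_perm <- NULL
  if (!is.null(pred)) {
    accs <- vapply(perms, function(p) {
      mapped <- p[pred[keep]]
      mean(mapped == truth_df$subtype[keep])
    }, numeric(1))
    best_perm <- perms[[which.max(accs)]]
    out$assignment_accuracy <- max(accs)
    out$permutation <- best_perm
  }
  if (!is.null(best_perm) && C_fit == C_true) {
    f_est <- numeric(C_true)
    f_est[best_perm[seq_len(C_fit)]] <- model$fractions
    true_f <- sim$config$fractions
    out$fraction_error <- max(abs(f_est - true_f))
  }
  if (!is.null(samples)) {
    pos <- positional_distribution(samples)
    es <- model$event_set
    N <- es$n_events
    one_hot <- lapply(seq_len(C_true), function(c) {
      m <- matrix(0, N, N)
      m[cbind(true_seqs[c, ], seq_len(N))] <- 1
      m
    })
    sim_mat <- matrix(NA_real_, C_true, length(pos$matrices))
    for (ct in seq_len(C_true)) for (cf in seq_along(pos$matrices))
      sim_mat[ct, cf] <- bhattacharyya_event_similarity(one_hot[[ct]],
                                                        pos$matrices[[cf]])
    if (!is.null(best_perm) && length(pos$matrices) == C_true) {
      out$positional_similarity <- vapply(seq_len(C_true), function(ct) {
        cf <- which(best_perm == ct)
        sim_mat[ct, cf]
      }, numeric(1))
    } else {
      out$positional_similarity <- apply(sim_mat, 1, max)
    }
  }
  if (!is.null(assignments)) {
    ok <- !is.na(truth_df$t)
    out$stage_spearman <- suppressWarnings(
      cor(truth_df$t[ok], assignments$table$expected_stage[ok],
          method = "spearman"))
  }
  if (!is.null(cv)) {
    out$selected_C <- cv$selected_C
    out$selected_C_correct <- cv$selected_C == C_true
  }
  out
}
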