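#' Per-subject subtyping and staging
#'
#' For each subject, the posterior probability of belonging to each subtype
#' and stage is averaged over the MCMC posterior on sequences and fractions
#' (rather than evaluated only at the maximum-likelihood model), so model
#' uncertainty propagates into the assignments. Per sample, the joint
#' weight of subtype `c` and stage `k` is `f_c` times the stage-`k` data
#' integral under `S_c`, normalised per subject; the reported joint
#' posterior is the sample average. The maximum-likelihood subtype is the
#' argmax of the stage-marginalised subtype probability; the stage
#' posterior is then read off under that subtype (renormalised), reported
#' both as its argmax (`ml_stage`) and its mean (`expected_stage`).
#'
#' Strength of assignment compares the pooled probability of being at
#' stage 2 or earlier (too little abnormality to tell subtypes apart)
#' with each subtype's probability summed over stages 3 and above; see
#' [strength_of_assignment()].
#'
#' @param data a [biomarker_dataset()] or matrix.
#' @param samples a [mcmc_sample()] result (or a `sustain_model`, in which
#'   case the single model is used without uncertainty averaging).
#' @param max_samples cap on the number of (evenly thinned) MCMC samples
#'   used for the average (default 200).
#' @param K quadrature points per stage.
#' @return An object of class `sustain_assignment`: a data frame `table`
#'   with one row per subject (`subject_id`, `ml_subtype`, `ml_stage`,
#'   `expected_stage`, per-subtype probabilities, `strength`,
#'   `strongly_assigned`), plus the full `joint` array
#'   (subjects x subtypes x stages) and `subtype_prob` matrix. Subjects
#'   with every biomarker missing get `NA` assignments and are flagged.
#' @export
assign_subjects <- function(data, samples, max_samples = 200, K = 10) {
  if (inherits(samples, "sustain_model")) {
    model_list <- list(list(sequences = samples$sequences,
                            fractions = samples$fractions))
    es <- samples$event_set
    sigma <- samples$sigma
  } else {
    stopifnot(inherits(samples, "sustain_mcmc"))
    es <- samples$event_set
    sigma <- samples$sigma
    n_store <- dim(samples$sequences)[1]
    take <- unique(round(seq(1, n_store, length.out = min(max_samples, n_store))))
    model_list <- lapply(take, function(s) {
      list(sequences = matrix(samples$sequences[s, , ],
                              nrow = dim(samples$sequences)[2]),
           fractions = samples$fractions[s, ])
    })
  }
  data <- check_data_model(data, es)
  a <- model_args(es, sigma, K)
  J <- nrow(data$values)
  N <- es$n_events
  C <- nrow(model_list[[1]]$sequences)
  joint <- array(0, dim = c(J, C, N + 1))
  for (ml in model_list) {
    per <- array(NA_real_, dim = c(J, C, N + 1))
    for (c in seq_len(C)) {
      st <- cpp_stage_loglik(data$values, as.integer(ml$sequences[c, ]),
                             a$ev_bio, a$ev_z, a$zmax, a$sigma, a$K)
      lf <- if (ml$fractions[c] > 0) log(ml$fractions[c]) else -Inf
      per[, c, ] <- st + lf
    }
    # normalise per subject in log space, then accumulate
    for (j in seq_len(J)) {
      v <- per[j, , ]
      tot <- logsumexp(v)
      joint[j, , ] <- joint[j, , ] + exp(v - tot)
    }
  }
  joint <- joint / length(model_list)
  all_missing <- rowSums(!is.na(data$values)) == 0
  subtype_prob <- apply(joint, c(1, 2), sum)
  ml_subtype <- max.col(subtype_prob, ties.method = "first")
  stage_prob <- matrix(NA_real_, J, N + 1)
  for (j in seq_len(J)) {
    sp <- joint[j, ml_subtype[j], ]
    stage_prob[j, ] <- sp / sum(sp)
  }
  ml_stage <- max.col(stage_prob, ties.method = "first") - 1L
  expected_stage <- as.vector(stage_prob %*% (0:N))
  strength <- strength_from_joint(joint)
  tab <- data.frame(subject_id = data$subject_ids,
                    ml_subtype = ml_subtype, ml_stage = ml_stage,
                    expected_stage = expected_stage,
                    stringsAsFactors = FALSE)
  for (c in seq_len(C)) tab[[paste0("prob_subtype", c)]] <- subtype_prob[, c]
  tab$strength <- strength$strength
  tab$strongly_assigned <- strength$strongly_assigned
  if (any(all_missing)) {
    tab$ml_subtype[all_missing] <- NA_integer_
    tab$ml_stage[all_missing] <- NA_integer_
    tab$expected_stage[all_missing] <- NA_real_
    tab$strength[all_missing] <- NA_real_
    tab$strongly_assigned[all_missing] <- NA
  }
  tab$all_missing <- all_missing
  structure(list(table = tab, joint = joint, subtype_prob = subtype_prob,
                 stage_prob = stage_prob, event_set = es),
            class = "sustain_assignment")
}

#' @export
print.sustain_assignment <- function(x, ...) {
  cat("assignments for", nrow(x$table), "subjects,",
      ncol(x$subtype_prob), "subtype(s)\n")
  cat(sprintf("  strongly assigned: %.1f%%\n",
              100 * mean(x$table$strongly_assigned, na.rm = TRUE)))
  print(head(x$table, 5))
  invisible(x)
}

strength_from_joint <- function(joint) {
  N <- dim(joint)[3] - 1
  if (N < 3)
    stop("strength of assignment needs at least 3 events: it compares the ",
         "probability of stage <= 2 with per-subtype mass over stages 3+")
  late <- apply(joint[, , 4:(N + 1), drop = FALSE], c(1, 2), sum)
  strength <- apply(late, 1, max)
  list(strength = strength, strongly_assigned = strength > 0.5,
       p_early = 1 - rowSums(late))
}

#' Strength of assignment to a subtype
#'
#' A subject at stage 2 or earlier shows too little abnormality to carry
#' subtype information, so the pooled probability of stage <= 2 is compared
#' with each subtype's probability summed over stages 3 and above. The
#' strength is the maximum of the per-subtype late-stage probabilities and
#' an assignment is "strong" when that maximum is strictly greater than
#' one half.
#'
#' @param x a `sustain_assignment`, a joint subjects x subtypes x stages
#'   probability array, or (for a single subject) a subtypes x stages
#'   matrix.
#' @return A list with `strength`, `strongly_assigned` and `p_early`
#'   (probability of stage <= 2), each with one entry per subject.
#' @examples
#' # P(stage<=2) = 0.10; subtype A beyond stage 2: 0.60; subtype B: 0.30
#' j <- matrix(0, 2, 4) # subtypes x stages 0..3
#' j[, 1] <- 0.05
#' j[1, 4] <- 0.60
#' j[2, 4] <- 0.30
#' strength_of_assignment(j)$strength # 0.6, strongly assigned
#' @export
strength_of_assignment <- function(x) {
  if (inherits(x, "sustain_assignment")) return(strength_from_joint(x$joint))
  if (is.matrix(x)) x <- array(x, dim = c(1, dim(x)))
  strength_from_joint(x)
}

#' Threshold-based subtype classification
#'
#' Uses the per-subject subtype probabilities to predict a class label: a
#' subject is assigned to a subtype when that subtype's probability exceeds
#' its threshold, the highest-probability qualifying subtype winning;
#' subjects qualifying nowhere stay unassigned (counted as errors). With
#' all thresholds zero this reduces to argmax assignment. Per-subtype
#' thresholds absorb different amounts of within-subtype heterogeneity.
#'
#' When `thresholds` is `NULL` they are optimised: within each of
#' `n_folds` cross-validation folds a grid search (step `grid_step`)
#' maximises balanced accuracy on the training subjects, and the reported
#' accuracy is out-of-sample. The subtype-to-class correspondence is the
#' accuracy-maximising permutation, chosen on training data.
#'
#' @param assignments a `sustain_assignment` or a subjects x subtypes
#'   probability matrix.
#' @param labels true class labels (factor or vector), as many classes as
#'   subtypes.
#' @param thresholds fixed per-subtype thresholds in `[0, 1]`, or `NULL`
#'   to optimise them by cross-validation.
#' @param n_folds folds for the threshold optimisation (default 10).
#' @param seed optional integer seed for the folds.
#' @param grid_step threshold grid resolution (default 0.05).
#' @return A list with `confusion` (true class x predicted), `balanced_accuracy`,
#'   `per_class_accuracy`, `thresholds` (per fold when optimised),
#'   `mapping` (subtype index per class level) and `predicted`.
#' @export
threshold_classify <- function(assignments, labels, thresholds = NULL,
                               n_folds = 10, seed = NULL, grid_step = 0.05) {
  probs <- if (inherits(assignments, "sustain_assignment"))
    assignments$subtype_prob else as.matrix(assignments)
  if (is.null(labels)) stop("`labels` are required")
  labels <- factor(labels)
  if (anyNA(labels)) stop("`labels` must be complete")
  C <- ncol(probs)
  if (nlevels(labels) != C)
    stop("need as many classes as subtypes (", C, ")")
  J <- nrow(probs)
  if (length(labels) != J) stop("one label per subject required")

  if (!is.null(thresholds)) {
    if (any(thresholds < 0 | thresholds > 1)) stop("thresholds must be in [0, 1]")
    mapping <- best_mapping(probs, labels, thresholds)
    pred <- predict_threshold(probs, thresholds, mapping, levels(labels))
    return(classification_report(labels, pred, thresholds, mapping))
  }

  if (!is.null(seed)) set.seed(seed)
  folds <- make_folds(J, n_folds, stratify_by = labels)
  pred <- factor(rep(NA_character_, J),
                 levels = c(levels(labels), "unassigned"))
  fold_thresholds <- matrix(NA_real_, length(folds), C)
  for (fd in seq_along(folds)) {
    test <- folds[[fd]]
    train <- setdiff(seq_len(J), test)
    opt <- optimise_thresholds(probs[train, , drop = FALSE], labels[train],
                               grid_step)
    fold_thresholds[fd, ] <- opt$thresholds
    pred[test] <- predict_threshold(probs[test, , drop = FALSE],
                                    opt$thresholds, opt$mapping,
                                    levels(labels))
  }
  out <- classification_report(labels, pred, fold_thresholds, NULL)
  out$fold_thresholds <- fold_thresholds
  out
}

# assign to highest-probability subtype among those clearing their threshold
predict_threshold <- function(probs, thresholds, mapping, class_levels) {
  J <- nrow(probs)
  pred <- rep("unassigned", J)
  for (j in seq_len(J)) {
    ok <- which(probs[j, ] > thresholds)
    if (length(ok)) {
      c_win <- ok[which.max(probs[j, ok])]
      pred[j] <- class_levels[match(c_win, mapping)]
    }
  }
  factor(pred, levels = c(class_levels, "unassigned"))
}

balanced_accuracy <- function(labels, pred) {
  mean(vapply(levels(labels), function(lv) {
    idx <- labels == lv
    mean(as.character(pred[idx]) == lv)
  }, numeric(1)))
}

# permutation of subtypes to class levels maximising balanced accuracy
best_mapping <- function(probs, labels, thresholds) {
  C <- ncol(probs)
  perms <- all_permutations(C)
  best <- NULL; best_acc <- -Inf
  for (p in perms) {
    pred <- predict_threshold(probs, thresholds, p, levels(labels))
    acc <- balanced_accuracy(labels, pred)
    if (acc > best_acc) { best_acc <- acc; best <- p }
  }
  best
}

optimise_thresholds <- function(probs, labels, grid_step) {
  C <- ncol(probs)
  grid <- seq(0, 1, by = grid_step)
  best_thr <- rep(0, C)
  best_map <- best_mapping(probs, labels, best_thr)
  pred <- predict_threshold(probs, best_thr, best_map, levels(labels))
  best_acc <- balanced_accuracy(labels, pred)
  # coordinate ascent over per-subtype thresholds (full grid per coordinate)
  for (sweep in 1:2) {
    for (c in seq_len(C)) {
      for (th in grid) {
        thr <- best_thr; thr[c] <- th
        map <- best_mapping(probs, labels, thr)
        pred <- predict_threshold(probs, thr, map, levels(labels))
        acc <- balanced_accuracy(labels, pred)
        if (acc > best_acc) {
          best_acc <- acc; best_thr <- thr; best_map <- map
        }
      }
    }
  }
  list(thresholds = best_thr, mapping = best_map, accuracy = best_acc)
}

classification_report <- function(labels, pred, thresholds, mapping) {
  conf <- table(true = labels, predicted = pred)
  per_class <- vapply(levels(labels), function(lv)
    mean(as.character(pred[labels == lv]) == lv), numeric(1))
  list(confusion = conf, balanced_accuracy = mean(per_class),
       per_class_accuracy = per_class, thresholds = thresholds,
       mapping = mapping, predicted = pred)
}

all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    sub <- all_permutations(n - 1)
    for (s in sub) out[[length(out) + 1L]] <- c(i, setdiff(seq_len(n), i)[s])
  }
  out
}

#' Write assignments to CSV
#'
#' @param assignments a `sustain_assignment`.
#' @param path output file path.
#' @export
write_assignments_csv <- function(assignments, path) {
  stopifnot(inherits(assignments, "sustain_assignment"))
  write.csv(assignments$table, path, row.names = FALSE)
  invisible(path)
}
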