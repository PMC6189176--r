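#' Fit a control-referenced adjustment
#'
#' Per biomarker, a linear model of the raw measurement on the supplied
#' covariates (age, sex, education, genotype dose, ...) is fitted within
#' the control subjects; covariates whose coefficient is significant at
#' `alpha` (per-covariate t-test, no multiplicity correction) are retained
#' and the model is refitted with only those. The residual mean and
#' standard deviation on controls define the z-scoring, so after
#' [to_zscores()] the control population has mean 0 and SD 1 on every
#' biomarker.
#'
#' @param raw data frame (or matrix) of raw measurements plus covariate
#'   columns.
#' @param biomarkers character vector naming the biomarker columns.
#' @param controls logical vector flagging the control subjects (at least
#'   10 required).
#' @param covariates character vector naming covariate columns (may be
#'   empty); must be complete for controls.
#' @param alpha significance level for the covariate screen (default 0.05).
#' @return An object of class `control_adjustment`: per biomarker the
#'   retained covariates and coefficients, the control residual mean/SD,
#'   and a usability flag (biomarkers with zero control variance are
#'   flagged unusable).
#' @export
fit_control_adjustment <- function(raw, biomarkers, controls,
                                   covariates = character(0), alpha = 0.05) {
  raw <- as.data.frame(raw)
  if (!all(biomarkers %in% names(raw))) stop("unknown biomarker column(s)")
  if (!all(covariates %in% names(raw))) stop("unknown covariate column(s)")
  controls <- as.logical(controls)
  if (sum(controls) < 10)
    stop("at least 10 control subjects are required (got ", sum(controls), ")")
  ctl <- raw[controls, , drop = FALSE]
  if (length(covariates)) {
    if (anyNA(ctl[covariates]))
      stop("covariates must be complete for control subjects")
    if (!all(vapply(raw[covariates], is.numeric, logical(1))))
      stop("covariates must be numeric (code sex as 0/1, genotype as a dose)")
  }
  per_bm <- lapply(biomarkers, function(bm) {
    y <- ctl[[bm]]
    keep <- !is.na(y)
    if (sd(y[keep]) == 0 || sum(keep) < 3)
      return(list(usable = FALSE, covariates = character(0),
                  coef = numeric(0), mean = NA_real_, sd = NA_real_))
    retained <- character(0)
    if (length(covariates)) {
      fml <- stats::as.formula(paste0("`", bm, "` ~ ",
                                      paste0("`", covariates, "`",
                                             collapse = " + ")))
      fit <- lm(fml, data = ctl)
      pv <- summary(fit)$coefficients[, "Pr(>|t|)"]
      pv <- pv[setdiff(names(pv), "(Intercept)")]
      sig <- names(pv)[pv < alpha]
      retained <- covariates[vapply(covariates, function(cv)
        any(startsWith(sig, cv) | startsWith(sig, paste0("`", cv, "`"))),
        logical(1))]
    }
    if (length(retained)) {
      fml <- stats::as.formula(paste0("`", bm, "` ~ ",
                                      paste0("`", retained, "`",
                                             collapse = " + ")))
      fit <- lm(fml, data = ctl)
      cf <- coef(fit)
      res <- stats::residuals(fit) + cf["(Intercept)"]
      cf <- cf[setdiff(names(cf), "(Intercept)")]
    } else {
      cf <- numeric(0)
      res <- y[keep]
    }
    list(usable = TRUE, covariates = retained, coef = cf,
         mean = mean(res), sd = sd(res))
  })
  names(per_bm) <- biomarkers
  structure(list(biomarkers = biomarkers, covariates = covariates,
                 per_biomarker = per_bm, alpha = alpha),
            class = "control_adjustment")
}

#' @export
print.control_adjustment <- function(x, ...) {
  cat("control adjustment for", length(x$biomarkers), "biomarkers\n")
  for (bm in x$biomarkers) {
    p <- x$per_biomarker[[bm]]
    if (!p$usable) { cat(" ", bm, ": unusable (zero control variance)\n"); next }
    cat(sprintf("  %-16s mean %.3f sd %.3f%s\n", bm, p$mean, p$sd,
                if (length(p$covariates))
                  paste0("  ~ ", paste(p$covariates, collapse = " + "))
                else ""))
  }
  invisible(x)
}

#' Convert raw measurements to control-referenced z-scores
#'
#' Subtracts the retained covariate effects, centres and scales by the
#' control residual mean and SD, and (for biomarkers where disease means
#' decline, e.g. regional volumes) flips the sign so abnormality always
#' increases: a value two control SDs *below* the control mean becomes
#' `z = +2`. The transform is affine per biomarker. Applying it to an
#' already z-scored dataset is an error.
#'
#' @param raw data frame of raw measurements plus covariate columns.
#' @param adjustment a [fit_control_adjustment()] result.
#' @param decline_direction logical, recycled per biomarker: `TRUE` where
#'   lower raw values mean more abnormal (sign flip applied).
#' @param subject_ids,labels optional, passed to [biomarker_dataset()].
#' @return A [biomarker_dataset()] of z-scores (unusable biomarkers
#'   dropped), tagged so a second application errors.
#' @export
to_zscores <- function(raw, adjustment, decline_direction = TRUE,
                       subject_ids = NULL, labels = NULL) {
  stopifnot(inherits(adjustment, "control_adjustment"))
  if (inherits(raw, "biomarker_dataset") || isTRUE(attr(raw, "zscored")))
    stop("input already z-scored; the transform must not be applied twice")
  raw <- as.data.frame(raw)
  if (!all(adjustment$biomarkers %in% names(raw)))
    stop("raw data lack biomarker column(s) the adjustment was fitted on")
  usable <- vapply(adjustment$per_biomarker, `[[`, logical(1), "usable")
  bms <- adjustment$biomarkers[usable]
  flip <- rep_len(decline_direction, length(bms))
  Z <- matrix(NA_real_, nrow(raw), length(bms),
              dimnames = list(NULL, bms))
  for (i in seq_along(bms)) {
    p <- adjustment$per_biomarker[[bms[i]]]
    y <- raw[[bms[i]]]
    if (length(p$coef)) {
      for (cv in names(p$coef)) {
        col <- gsub("^`|`$", "", cv)
        y <- y - p$coef[[cv]] * as.numeric(raw[[col]])
      }
    }
    z <- (y - p$mean) / p$sd
    Z[, i] <- if (flip[i]) -z else z
  }
  out <- biomarker_dataset(Z, subject_ids = subject_ids, labels = labels)
  attr(out, "zscored") <- TRUE
  out
}

#' Select z-score events from patient counts
#'
#' For each biomarker, the candidate thresholds (default 1, 2, 3) are kept
#' only when at least `min_count` patients exceed them; since exceedance
#' sets are nested, the retained thresholds are always a prefix of the
#' candidates. The terminal z-score is 2, 3 or 5 according to whether the
#' largest retained threshold is 1, 2 or 3. Biomarkers retaining no events
#' are dropped with a warning.
#'
#' @param data a z-scored [biomarker_dataset()] or matrix.
#' @param patient_mask logical vector flagging the subjects counted as
#'   patients (e.g. mutation carriers, or all non-controls).
#' @param candidate_z candidate thresholds (default `c(1, 2, 3)`).
#' @param min_count minimum number of patients exceeding a threshold for
#'   the event to be kept (default 10).
#' @param z_max_map terminal z-score when the largest retained threshold is
#'   the 1st, 2nd, ... candidate (default `c(2, 3, 5)`).
#' @return A [zscore_event_set()] over the retained biomarkers, with the
#'   kept biomarker indices in attribute `kept_biomarkers`.
#' @export
select_events <- function(data, patient_mask, candidate_z = c(1, 2, 3),
                          min_count = 10, z_max_map = c(2, 3, 5)) {
  data <- as_dataset(data)
  patient_mask <- as.logical(patient_mask)
  if (!any(patient_mask)) stop("`patient_mask` selects no subjects")
  if (length(z_max_map) != length(candidate_z))
    stop("`z_max_map` must give a terminal z per candidate threshold")
  X <- data$values[patient_mask, , drop = FALSE]
  z_list <- list(); zmax <- numeric(0); kept <- integer(0)
  for (i in seq_len(ncol(X))) {
    counts <- vapply(candidate_z, function(z) sum(X[, i] > z, na.rm = TRUE),
                     numeric(1))
    keep <- counts >= min_count
    if (!any(keep)) next
    r <- max(which(keep)) # nested exceedance => prefix
    z_list[[length(z_list) + 1L]] <- candidate_z[seq_len(r)]
    zmax <- c(zmax, z_max_map[r])
    kept <- c(kept, i)
  }
  if (!length(kept))
    stop("no biomarker retained any z-score event at min_count = ", min_count)
  if (length(kept) < ncol(X))
    warning("dropped biomarker(s) with no retained events: ",
            paste(data$biomarker_names[-kept], collapse = ", "))
  es <- zscore_event_set(z_list, z_max = zmax,
                         biomarker_names = data$biomarker_names[kept])
  attr(es, "kept_biomarkers") <- kept
  es
}

#' Log hemispheric asymmetry index
#'
#' Derived feature for paired left/right measurements: the absolute
#' left-right difference divided by their sum, log transformed to improve
#' normality. Computed on raw values before z-scoring.
#'
#' @param left,right positive numeric vectors of paired measurements.
#' @param eps floor applied inside the log to keep perfectly symmetric
#'   values finite (default 1e-6).
#' @return Numeric vector of log asymmetry values.
#' @export
hemispheric_asymmetry <- function(left, right, eps = 1e-6) {
  if (any(left <= 0 | right <= 0, na.rm = TRUE))
    stop("asymmetry needs strictly positive paired measurements")
  log(pmax(abs(left - right) / (left + right), eps))
}

#' Serialise a control adjustment to JSON
#'
#' @param adjustment a [fit_control_adjustment()] result.
#' @param path output file path.
#' @export
write_control_adjustment <- function(adjustment, path) {
  stopifnot(inherits(adjustment, "control_adjustment"))
  obj <- list(biomarkers = adjustment$biomarkers,
              covariates = adjustment$covariates,
              alpha = adjustment$alpha,
              per_biomarker = lapply(adjustment$per_biomarker, function(p)
                list(usable = p$usable, covariates = p$covariates,
                     coef = as.list(p$coef), mean = p$mean, sd = p$sd)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a control adjustment from JSON
#'
#' @param path file written by [write_control_adjustment()].
#' @return A `control_adjustment`.
#' @export
read_control_adjustment <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  per <- lapply(obj$per_biomarker, function(p)
    list(usable = p$usable, covariates = as.character(p$covariates),
         coef = unlist(p$coef), mean = p$mean, sd = p$sd))
  structure(list(biomarkers = obj$biomarkers,
                 covariates = as.character(obj$covariates),
                 per_biomarker = per, alpha = obj$alpha),
            class = "control_adjustment")
}
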