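#' Validate a pipeline run configuration
#'
#' Collects and validates everything a full run needs before any compute
#' starts: input paths, the control/patient mask columns, covariates,
#' candidate z-scores, fitting and MCMC controls, and the output
#' directory. The validated config (plus a hash) is echoed into every
#' output's metadata so runs are reproducible and auditable.
#'
#' @param input path to the input CSV (see [read_biomarker_csv()]).
#' @param output_dir directory for outputs (created if absent).
#' @param control_col name of the 0/1 control-indicator column; `NULL` when
#'   the input is already z-scored.
#' @param patient_col optional 0/1 column defining the patients counted in
#'   event selection; defaults to the complement of the controls.
#' @param covariates covariate column names regressed out of controls.
#' @param candidate_z,min_count event-selection controls (see
#'   [select_events()]).
#' @param C_max,n_restarts,em_tol,em_max_iter fitting controls.
#' @param n_mcmc,n_folds MCMC chain length and cross-validation folds.
#' @param K quadrature points per stage.
#' @param seed integer seed used for every stochastic step.
#' @return A validated list of class `run_config` with a `hash` field.
#' @export
run_config <- function(input, output_dir = ".", control_col = NULL,
                       patient_col = NULL, covariates = character(0),
                       candidate_z = c(1, 2, 3), min_count = 10, C_max = 3,
                       n_restarts = 25, em_tol = 1e-6, em_max_iter = 100,
                       n_mcmc = 1e6, n_folds = 10, K = 10, seed = 1) {
  cfg <- list(input = input, output_dir = output_dir,
              control_col = control_col, patient_col = patient_col,
              covariates = covariates, candidate_z = candidate_z,
              min_count = min_count, C_max = as.integer(C_max),
              n_restarts = as.integer(n_restarts), em_tol = em_tol,
              em_max_iter = as.integer(em_max_iter),
              n_mcmc = as.integer(n_mcmc), n_folds = as.integer(n_folds),
              K = as.integer(K), seed = as.integer(seed))
  if (!is.null(input) && !file.exists(input))
    stop("input file not found: ", input)
  stopifnot(cfg$C_max >= 1, cfg$n_restarts >= 1, cfg$n_mcmc >= 1,
            cfg$n_folds >= 2, cfg$K >= 1, cfg$min_count >= 1)
  cfg$hash <- config_hash(cfg)
  class(cfg) <- "run_config"
  cfg
}

# order-independent short hash of the config for output provenance
config_hash <- function(cfg) {
  cfg$hash <- NULL
  s <- jsonlite::toJSON(cfg[order(names(cfg))], auto_unbox = TRUE)
  sprintf("%08x", sum(utf8ToInt(as.character(s)) *
                        (seq_len(nchar(s)) %% 97 + 1)) %% .Machine$integer.max)
}

load_run_input <- function(cfg) {
  df <- read.csv(cfg$input, check.names = FALSE, na.strings = c("", "NA"))
  if (!is.null(cfg$control_col) && !cfg$control_col %in% names(df))
    stop("configuration error: control column '", cfg$control_col,
         "' not present in the input")
  if (!is.null(cfg$patient_col) && !cfg$patient_col %in% names(df))
    stop("configuration error: patient column '", cfg$patient_col,
         "' not present in the input")
  df
}

run_log <- function(log_lines, stage, t0, seed) {
  c(log_lines, sprintf("%s: %.2fs (seed %d)", stage,
                       as.numeric(Sys.time()) - t0, seed))
}

#' Run the full fitting pipeline
#'
#' Preprocessing (when a control column is configured), event selection,
#' hierarchical model fitting, MCMC sampling and positional summaries, with
#' all artefacts written to the configured output directory: `model.json`,
#' `samples.csv.gz`, `positional.csv` and `run.log`.
#'
#' @param cfg a [run_config()].
#' @return Invisibly, a list with the fitted models, MCMC samples,
#'   positional distributions and the event set.
#' @export
pipeline_fit <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  t0 <- as.numeric(Sys.time())
  df <- load_run_input(cfg)
  set.seed(cfg$seed)
  if (!is.null(cfg$control_col)) {
    controls <- df[[cfg$control_col]] == 1
    meta_cols <- c("subject_id", "label", cfg$control_col, cfg$patient_col,
                   cfg$covariates)
    bms <- setdiff(names(df), meta_cols)
    adj <- fit_control_adjustment(df, bms, controls, cfg$covariates)
    zdata <- to_zscores(df, adj,
                        subject_ids = if ("subject_id" %in% names(df))
                          as.character(df$subject_id) else NULL)
    write_control_adjustment(adj, file.path(cfg$output_dir, "adjustment.json"))
    patients <- if (!is.null(cfg$patient_col)) df[[cfg$patient_col]] == 1
                else !controls
  } else {
    zdata <- read_biomarker_csv(cfg$input)
    patients <- rep(TRUE, nrow(zdata$values))
  }
  log_lines <- run_log(log_lines, "preprocess", t0, cfg$seed)
  es <- select_events(zdata, patients, candidate_z = cfg$candidate_z,
                      min_count = cfg$min_count)
  kept <- attr(es, "kept_biomarkers")
  fit_data <- subset_dataset(zdata, seq_len(nrow(zdata$values)))
  fit_data$values <- fit_data$values[, kept, drop = FALSE]
  fit_data$biomarker_names <- fit_data$biomarker_names[kept]
  log_lines <- run_log(log_lines, "select_events", t0, cfg$seed)
  fits <- fit_hierarchical(fit_data, es, C_max = cfg$C_max,
                           n_restarts = cfg$n_restarts, seed = cfg$seed,
                           K = cfg$K, tol = cfg$em_tol,
                           max_iter = cfg$em_max_iter)
  log_lines <- run_log(log_lines, "fit_hierarchical", t0, cfg$seed)
  best <- fits[[length(fits)]]
  write_sustain_model(best$model, file.path(cfg$output_dir, "model.json"),
                      seed = cfg$seed)
  samples <- mcmc_sample(fit_data, best$model, n_samples = cfg$n_mcmc,
                         seed = cfg$seed, K = cfg$K)
  log_lines <- run_log(log_lines, "mcmc_sample", t0, cfg$seed)
  write_mcmc_samples(samples, file.path(cfg$output_dir, "samples.csv.gz"))
  pos <- positional_distribution(samples)
  write_positional_csv(pos, file.path(cfg$output_dir, "positional.csv"))
  log_lines <- c(log_lines, paste("config hash", cfg$hash))
  writeLines(log_lines, file.path(cfg$output_dir, "run.log"))
  invisible(list(fits = fits, samples = samples, positional = pos,
                 event_set = es, data = fit_data))
}

#' Write positional distributions as a long-format CSV
#'
#' One row per (subtype, event, position) probability.
#'
#' @param pos a [positional_distribution()].
#' @param path output file path.
#' @export
write_positional_csv <- function(pos, path) {
  stopifnot(inherits(pos, "positional_distribution"))
  rows <- list()
  for (c in seq_along(pos$matrices)) {
    m <- pos$matrices[[c]]
    N <- nrow(m)
    rows[[c]] <- data.frame(subtype = c,
                            event = rep(rownames(m) %||% seq_len(N),
                                        times = N),
                            position = rep(seq_len(N), each = N),
                            probability = as.vector(m))
  }
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run cross-validation from a config
#'
#' Fits per-fold hierarchical models, writes the CVIC table and, when
#' `n_mcmc_folds > 0`, short per-fold chains and the cross-validation
#' similarity table.
#'
#' @param cfg a [run_config()].
#' @param data optional pre-built [biomarker_dataset()] and `event_set`
#'   (skips preprocessing; both must be given together).
#' @param event_set see `data`.
#' @param full_samples optional [mcmc_sample()] result for the full-data
#'   model; enables the CVS table.
#' @param n_mcmc_folds chain length for per-fold uncertainty (default 0:
#'   CVS skipped).
#' @return Invisibly, the [cross_validate()] result (with `cvs` attached
#'   when computed).
#' @export
pipeline_crossval <- function(cfg, data = NULL, event_set = NULL,
                              full_samples = NULL, n_mcmc_folds = 0) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(data) || is.null(event_set)) {
    res <- pipeline_fit(cfg)
    data <- res$data
    event_set <- res$event_set
    full_samples <- res$samples
  }
  cv <- cross_validate(data, event_set, C_max = cfg$C_max,
                       n_folds = cfg$n_folds, seed = cfg$seed,
                       n_restarts = cfg$n_restarts, K = cfg$K,
                       tol = cfg$em_tol, max_iter = cfg$em_max_iter)
  write.csv(data.frame(C = seq_along(cv$cvic), cvic = cv$cvic,
                       oos_loglik = colSums(cv$oos_loglik)),
            file.path(cfg$output_dir, "cvic.csv"), row.names = FALSE)
  if (n_mcmc_folds > 0 && !is.null(full_samples)) {
    fold_pos <- lapply(cv$fold_fits, function(fits) {
      m <- fits[[min(cv$selected_C, length(fits))]]$model
      positional_distribution(
        mcmc_sample(data, m, n_samples = n_mcmc_folds, K = cfg$K))
    })
    cvs <- cross_validation_similarity(full_samples, fold_pos)
    write.csv(data.frame(subtype = seq_along(cvs), cvs = cvs),
              file.path(cfg$output_dir, "cvs.csv"), row.names = FALSE)
    attr(cv, "cvs") <- cvs
  }
  invisible(cv)
}
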