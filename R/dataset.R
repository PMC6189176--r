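#' Construct a biomarker dataset
#'
#' Wraps a subjects x biomarkers matrix of z-scores (unitless standard
#' deviations relative to a control population) together with biomarker
#' names, subject identifiers and optional per-subject labels. Labels
#' (diagnosis, genotype) are carried along for stratification and
#' classification but are never used in model fitting. Missing measurements
#' are `NA` and are marginalised out of the likelihood.
#'
#' @param values numeric matrix or data frame, subjects in rows, biomarkers
#'   in columns.
#' @param biomarker_names character vector; defaults to column names.
#' @param subject_ids character vector; defaults to row names or `s1, s2, ...`.
#' @param labels optional vector/factor of per-subject tags.
#' @return An object of class `biomarker_dataset`.
#' @export
biomarker_dataset <- function(values, biomarker_names = NULL,
                              subject_ids = NULL, labels = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(biomarker_names)) biomarker_names <- colnames(values)
  if (is.null(biomarker_names)) biomarker_names <- paste0("bm", seq_len(ncol(values)))
  if (length(biomarker_names) != ncol(values))
    stop("`biomarker_names` must match the number of columns")
  if (anyDuplicated(biomarker_names)) stop("biomarker names must be unique")
  if (is.null(subject_ids)) subject_ids <- rownames(values)
  if (is.null(subject_ids)) subject_ids <- paste0("s", seq_len(nrow(values)))
  if (length(subject_ids) != nrow(values))
    stop("`subject_ids` must match the number of rows")
  if (!is.null(labels) && length(labels) != nrow(values))
    stop("`labels` must have one entry per subject")
  if (any(is.infinite(values)))
    stop("non-finite measurements must be coded as NA")
  dimnames(values) <- list(subject_ids, biomarker_names)
  structure(list(values = values, biomarker_names = biomarker_names,
                 subject_ids = subject_ids, labels = labels),
            class = "biomarker_dataset")
}

#' @export
print.biomarker_dataset <- function(x, ...) {
  cat("biomarker dataset:", nrow(x$values), "subjects x", ncol(x$values),
      "biomarkers\n")
  nmiss <- sum(is.na(x$values))
  if (nmiss > 0) cat("  missing entries:", nmiss, "\n")
  if (!is.null(x$labels)) {
    tb <- table(x$labels)
    cat("  labels:", paste(names(tb), tb, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.biomarker_dataset <- function(x) dim(x$values)

# subset subjects, keeping ids/labels aligned
subset_dataset <- function(data, idx) {
  biomarker_dataset(data$values[idx, , drop = FALSE],
                    biomarker_names = data$biomarker_names,
                    subject_ids = data$subject_ids[idx],
                    labels = if (is.null(data$labels)) NULL else data$labels[idx])
}

as_dataset <- function(data) {
  if (inherits(data, "biomarker_dataset")) data else biomarker_dataset(data)
}

#' Read a biomarker table from CSV
#'
#' Expects a header row of biomarker names, one row per subject, and
#' optional leading `subject_id` and `label` columns. Empty cells and "NA"
#' are read as missing.
#'
#' @param path CSV file path.
#' @param id_col,label_col column names for subject identifiers and labels
#'   (used when present).
#' @return A [biomarker_dataset()].
#' @export
read_biomarker_csv <- function(path, id_col = "subject_id", label_col = "label") {
  df <- read.csv(path, check.names = FALSE, na.strings = c("", "NA"))
  ids <- NULL; labels <- NULL
  if (id_col %in% names(df)) { ids <- as.character(df[[id_col]]); df[[id_col]] <- NULL }
  if (label_col %in% names(df)) { labels <- df[[label_col]]; df[[label_col]] <- NULL }
  biomarker_dataset(df, subject_ids = ids, labels = labels)
}

#' Write a biomarker dataset to CSV
#'
#' @param data a [biomarker_dataset()].
#' @param path output file path.
#' @export
write_biomarker_csv <- function(data, path) {
  data <- as_dataset(data)
  df <- data.frame(subject_id = data$subject_ids, check.names = FALSE)
  if (!is.null(data$labels)) df$label <- data$labels
  df <- cbind(df, as.data.frame(data$values, check.names = FALSE))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
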