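#' Define a set of z-score events
#'
#' A z-score event is the point at which a biomarker's control-referenced
#' z-score reaches a threshold. The event set fixes, for each biomarker, its
#' strictly increasing positive thresholds and the terminal z-score
#' `z_max` that the trajectory reaches at the end of the progression. The
#' total number of events `N` across biomarkers determines the number of
#' model stages (`N + 1`, counting stage 0 in which no event has occurred).
#'
#' @param z_scores thresholds per biomarker: a list of numeric vectors (one
#'   per biomarker), or a single numeric vector recycled for all biomarkers
#'   (in which case `n_biomarkers` or `biomarker_names` must be given).
#' @param z_max numeric vector of terminal z-scores, one per biomarker (or a
#'   single value recycled). Must exceed each biomarker's largest threshold.
#' @param biomarker_names optional character vector of biomarker names.
#' @param n_biomarkers number of biomarkers when `z_scores` is a single
#'   vector and no names are given.
#'
#' @return An object of class `zscore_event_set` with components `events`
#'   (data frame with one row per event: `biomarker` index, `biomarker_name`,
#'   `z`), `z_max`, `biomarker_names`, `n_events` and `n_biomarkers`. Events
#'   are numbered in biomarker-major, increasing-z order; these indices are
#'   what sequences refer to.
#' @examples
#' es <- zscore_event_set(c(1, 2, 3), z_max = 5, n_biomarkers = 2)
#' es$n_events # 6
#' @export
zscore_event_set <- function(z_scores, z_max, biomarker_names = NULL,
                             n_biomarkers = NULL) {
  if (!is.list(z_scores)) {
    if (is.null(n_biomarkers)) n_biomarkers <- length(biomarker_names)
    if (is.null(n_biomarkers) || n_biomarkers < 1)
      stop("give `z_scores` as a list, or supply `n_biomarkers`/`biomarker_names`")
    z_scores <- rep(list(as.numeric(z_scores)), n_biomarkers)
  }
  I <- length(z_scores)
  if (length(z_max) == 1L) z_max <- rep(z_max, I)
  if (length(z_max) != I) stop("`z_max` must have one entry per biomarker")
  if (is.null(biomarker_names)) biomarker_names <- paste0("bm", seq_len(I))
  if (length(biomarker_names) != I) stop("`biomarker_names` length mismatch")
  if (anyDuplicated(biomarker_names)) stop("biomarker names must be unique")
  for (i in seq_len(I)) {
    zi <- z_scores[[i]]
    if (length(zi) < 1) stop("biomarker ", biomarker_names[i], " has no events")
    if (any(zi <= 0)) stop("z-score thresholds must be strictly positive")
    if (any(diff(zi) <= 0)) stop("z-score thresholds must be strictly increasing")
    if (z_max[i] <= max(zi))
      stop("z_max for ", biomarker_names[i], " must exceed its largest threshold")
  }
  events <- data.frame(
    biomarker = rep(seq_len(I), lengths(z_scores)),
    biomarker_name = rep(biomarker_names, lengths(z_scores)),
    z = unlist(z_scores, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  structure(list(events = events, z_max = as.numeric(z_max),
                 biomarker_names = biomarker_names,
                 n_events = nrow(events), n_biomarkers = I),
            class = "zscore_event_set")
}

#' @export
print.zscore_event_set <- function(x, ...) {
  cat("z-score event set:", x$n_events, "events over", x$n_biomarkers,
      "biomarkers\n")
  for (i in seq_len(x$n_biomarkers)) {
    zi <- x$events$z[x$events$biomarker == i]
    cat(sprintf("  %-16s z = {%s}, z_max = %g\n", x$biomarker_names[i],
                paste(zi, collapse = ", "), x$z_max[i]))
  }
  invisible(x)
}

#' Model times of events in a sequence
#'
#' The event in position `k` of a sequence completes at model time
#' `k / (N + 1)` (positions are 1-based; `N` is the number of events), so
#' stage `k` covers the interval from `k/(N+1)` to `(k+1)/(N+1)` and stage 0
#' precedes the first event. Model time is unitless on `[0, 1]`.
#'
#' @param sequence integer permutation of the event indices (position order).
#' @param n_events total number of events `N` (defaults to the sequence length).
#' @return Numeric vector of event completion times in position order,
#'   named by event index; strictly increasing.
#' @examples
#' event_times(c(2, 1)) # 1/3, 2/3
#' @export
event_times <- function(sequence, n_events = length(sequence)) {
  sequence <- as.integer(sequence)
  if (length(sequence) != n_events ||
      !identical(sort(sequence), seq_len(n_events)))
    stop("`sequence` must be a permutation of 1..", n_events)
  setNames(seq_len(n_events) / (n_events + 1), sequence)
}

#' Check that a sequence respects within-biomarker threshold order
#'
#' A sequence is admissible when it is a permutation of all events and, for
#' every biomarker, lower z-score events precede higher ones. Orderings that
#' reach z = 2 before z = 1 would require a decreasing trajectory and are
#' excluded from the model space.
#'
#' @param sequence integer vector of event indices in position order.
#' @param event_set a [zscore_event_set()].
#' @return `TRUE` or `FALSE`.
#' @export
is_admissible_sequence <- function(sequence, event_set) {
  N <- event_set$n_events
  sequence <- as.integer(sequence)
  if (length(sequence) != N || !identical(sort(sequence), seq_len(N)))
    return(FALSE)
  bio <- event_set$events$biomarker[sequence]
  z <- event_set$events$z[sequence]
  for (i in seq_len(event_set$n_biomarkers)) {
    zi <- z[bio == i]
    if (length(zi) > 1 && any(diff(zi) <= 0)) return(FALSE)
  }
  TRUE
}

#' Draw a uniformly random admissible sequence
#'
#' Each event gets an independent uniform key; events are ordered by key and
#' the events of each biomarker are then rearranged in place into increasing
#' z-score order. Every admissible ordering has equal probability because
#' the biomarker-position pattern is exchangeable under random keys.
#'
#' @inheritParams is_admissible_sequence
#' @return Integer vector of event indices in position order.
#' @export
random_admissible_sequence <- function(event_set) {
  N <- event_set$n_events
  ord <- order(runif(N))
  bio <- event_set$events$biomarker
  for (i in seq_len(event_set$n_biomarkers)) {
    ev_i <- which(bio == i) # already in increasing-z order
    pos <- which(bio[ord] == i)
    ord[pos] <- ev_i
  }
  ord
}

#' Enumerate all admissible sequences
#'
#' Exhaustive enumeration of orderings that respect within-biomarker
#' threshold order. Only feasible for small event sets; used for oracle
#' checks of the greedy optimiser and the MCMC sampler.
#'
#' @inheritParams is_admissible_sequence
#' @param max_n guard on the number of events (default 8).
#' @return A matrix with one admissible sequence per row.
#' @export
enumerate_admissible_sequences <- function(event_set, max_n = 8) {
  N <- event_set$n_events
  if (N > max_n) stop("refusing to enumerate ", N, " events (max_n = ", max_n, ")")
  bio <- event_set$events$biomarker
  z <- event_set$events$z
  res <- list()
  recurse <- function(prefix, remaining) {
    if (length(remaining) == 0) {
      res[[length(res) + 1L]] <<- prefix
      return(invisible())
    }
    for (e in remaining) {
      # e placeable only if no lower-z same-biomarker event remains
      others <- setdiff(remaining, e)
      if (!any(bio[others] == bio[e] & z[others] < z[e]))
        recurse(c(prefix, e), others)
    }
  }
  recurse(integer(0), seq_len(N))
  do.call(rbind, res)
}
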