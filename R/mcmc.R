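#' MCMC sampling of sequence (and fraction) uncertainty
#'
#' Metropolis-Hastings over the admissible orderings of each subtype, with
#' a flat prior. Each step relocates one randomly chosen event of one
#' randomly chosen subtype to a uniformly random admissible position (a
#' symmetric proposal: the admissible slot count depends only on the order
#' of the other events). With more than one subtype the mixture fractions
#' are, by default, jointly perturbed with a Gaussian step (SD `f_sd`),
#' clipped at zero and renormalised. Acceptance is by likelihood ratio.
#' The chain starts at the supplied (maximum-likelihood) model, so no
#' burn-in is discarded by default.
#'
#' @param data a [biomarker_dataset()] or matrix.
#' @param model fitted [sustain_model()] (the chain's starting point).
#' @param n_samples chain length (default 1e6; use fewer for quick checks).
#' @param seed optional integer seed for exact reproducibility.
#' @param thin keep every `thin`-th sample (default 1).
#' @param sample_fractions sample mixture fractions too (default `TRUE`);
#'   `FALSE` freezes them at the supplied values.
#' @param f_sd SD of the Gaussian fraction perturbation (default 0.01).
#' @param K quadrature points per stage (default 10).
#' @return An object of class `sustain_mcmc`: `sequences` (array
#'   `n_stored x C x N` of event indices), `fractions` (`n_stored x C`),
#'   `log_likelihoods`, `acceptance_rate`, `n_samples`, `thin`, `seed` and
#'   the `event_set`. A warning is raised when no proposal was accepted.
#' @export
mcmc_sample <- function(data, model, n_samples = 1e6, seed = NULL, thin = 1,
                        sample_fractions = TRUE, f_sd = 0.01, K = 10) {
  stopifnot(inherits(model, "sustain_model"), n_samples >= 1, thin >= 1)
  if (!is.null(seed)) set.seed(seed)
  data <- check_data_model(data, model$event_set)
  a <- model_args(model$event_set, model$sigma, K)
  C <- nrow(model$sequences)
  N <- model$event_set$n_events
  res <- cpp_mcmc(data$values, model$sequences, model$fractions, a$ev_bio,
                  a$ev_z, a$zmax, a$sigma, a$K, as.integer(n_samples),
                  as.integer(thin), isTRUE(sample_fractions) && C > 1,
                  f_sd)
  if (res$acceptance_rate == 0 && n_samples >= 100)
    warning("MCMC accepted no proposals over ", n_samples,
            " steps; the likelihood surface may be degenerate")
  n_store <- nrow(res$sequences)
  seqs <- array(res$sequences, dim = c(n_store, N, C))
  seqs <- aperm(seqs, c(1, 3, 2)) # stored sample x subtype x position
  structure(list(sequences = seqs, fractions = res$fractions,
                 log_likelihoods = res$log_likelihoods,
                 acceptance_rate = res$acceptance_rate,
                 n_samples = n_samples, thin = thin, seed = seed,
                 event_set = model$event_set, sigma = model$sigma),
            class = "sustain_mcmc")
}

#' @export
print.sustain_mcmc <- function(x, ...) {
  cat("MCMC samples:", dim(x$sequences)[1], "stored of", x$n_samples,
      "steps,", dim(x$sequences)[2], "subtype(s)\n")
  cat(sprintf("  acceptance rate %.3f, log likelihood range [%.4g, %.4g]\n",
              x$acceptance_rate, min(x$log_likelihoods),
              max(x$log_likelihoods)))
  invisible(x)
}

#' Positional probability of each event
#'
#' Summarises MCMC samples as, for each subtype, the `N x N` matrix of the
#' probability that each event occupies each sequence position (the
#' positional variance diagram). Rows (events) sum to 1 exactly; columns
#' sum to 1 in expectation.
#'
#' @param samples a [mcmc_sample()] result, or a single `sustain_model`
#'   (giving one-hot matrices).
#' @return An object of class `positional_distribution`: a list of `C`
#'   matrices (events x positions), with the event set attached.
#' @export
positional_distribution <- function(samples) {
  if (inherits(samples, "sustain_model")) {
    es <- samples$event_set
    N <- es$n_events
    mats <- lapply(seq_len(nrow(samples$sequences)), function(c) {
      m <- matrix(0, N, N)
      m[cbind(samples$sequences[c, ], seq_len(N))] <- 1
      m
    })
    return(structure(list(matrices = mats, event_set = es),
                     class = "positional_distribution"))
  }
  stopifnot(inherits(samples, "sustain_mcmc"))
  d <- dim(samples$sequences)
  if (d[1] < 1) stop("no stored samples")
  N <- d[3]
  mats <- lapply(seq_len(d[2]), function(c) {
    m <- matrix(0, N, N)
    for (p in seq_len(N)) {
      tb <- tabulate(samples$sequences[, c, p], nbins = N)
      m[, p] <- tb
    }
    m / d[1]
  })
  es <- samples$event_set
  mats <- lapply(mats, function(m) {
    rownames(m) <- paste0(es$events$biomarker_name, ":z", es$events$z)
    colnames(m) <- paste0("pos", seq_len(N))
    m
  })
  structure(list(matrices = mats, event_set = es),
            class = "positional_distribution")
}

#' @export
print.positional_distribution <- function(x, ...) {
  cat("positional distributions for", length(x$matrices), "subtype(s),",
      nrow(x$matrices[[1]]), "events\n")
  invisible(x)
}

#' Cumulative severity weights at a stage
#'
#' For each biomarker, the probability (over MCMC samples) that its z = 1,
#' z = 2 and z = 3 events have occurred by the given stage. These are the
#' stacked colour weights of the progression diagrams: the first channel
#' shades white to red as z = 1 is reached, the second red to magenta
#' (z = 2), the third magenta to blue (z = 3). Each weight is in `[0, 1]`
#' and non-decreasing in stage.
#'
#' @param pos a [positional_distribution()].
#' @param subtype subtype index.
#' @param stage stage in `0..N` (number of completed events).
#' @return Matrix of biomarkers x retained z thresholds of cumulative
#'   probabilities (thresholds a biomarker does not carry are `NA`).
#' @export
cumulative_severity_encoding <- function(pos, subtype = 1, stage) {
  stopifnot(inherits(pos, "positional_distribution"))
  es <- pos$event_set
  N <- es$n_events
  if (stage < 0 || stage > N) stop("`stage` must be in 0..", N)
  m <- pos$matrices[[subtype]]
  zs <- sort(unique(es$events$z))
  out <- matrix(NA_real_, es$n_biomarkers, length(zs),
                dimnames = list(es$biomarker_names, paste0("z", zs)))
  for (e in seq_len(N)) {
    p_by <- if (stage == 0) 0 else sum(m[e, seq_len(stage)])
    out[es$events$biomarker[e], match(es$events$z[e], zs)] <- p_by
  }
  out
}

#' Plot a positional variance diagram
#'
#' Heat map of event x position probabilities for one subtype, events on
#' the vertical axis in their maximum-likelihood order.
#'
#' @param x a [positional_distribution()].
#' @param subtype subtype index.
#' @param ... passed to [graphics::image()].
#' @export
plot.positional_distribution <- function(x, subtype = 1, ...) {
  m <- x$matrices[[subtype]]
  N <- nrow(m)
  ml_pos <- apply(m, 1, which.max)
  ord <- order(ml_pos)
  graphics::image(x = seq_len(N), y = seq_len(N), z = t(m[rev(ord), ]),
                  col = grDevices::hcl.colors(64, "Reds", rev = TRUE),
                  xlab = "sequence position", ylab = "", axes = FALSE, ...)
  graphics::axis(1)
  graphics::axis(2, at = seq_len(N), labels = rev(rownames(m)[ord]),
                 las = 2, cex.axis = 0.7)
  graphics::box()
  invisible(x)
}

#' Export MCMC samples to a compressed table
#'
#' One row per stored sample: the sequences of every subtype as
#' event-index lists, the fractions and the log likelihood. Written as a
#' gzip-compressed CSV.
#'
#' @param samples a [mcmc_sample()] result.
#' @param path output path (conventionally ending in `.csv.gz`).
#' @export
write_mcmc_samples <- function(samples, path) {
  stopifnot(inherits(samples, "sustain_mcmc"))
  d <- dim(samples$sequences)
  seq_flat <- matrix(aperm(samples$sequences, c(1, 3, 2)), nrow = d[1])
  cols <- as.vector(vapply(seq_len(d[2]), function(c)
    paste0("s", c, "_pos", seq_len(d[3])), character(d[3])))
  colnames(seq_flat) <- cols
  df <- data.frame(seq_flat, check.names = FALSE)
  for (c in seq_len(d[2])) df[[paste0("f", c)]] <- samples$fractions[, c]
  df$log_likelihood <- samples$log_likelihoods
  con <- gzfile(path, "w")
  on.exit(close(con))
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}
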