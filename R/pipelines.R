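#' End-to-end equilibrium population analysis
#'
#' Runs the full equilibrium workflow on a trace table: leakage-corrected
#' FRET, terminal-event classification (photobleach detection with the
#' dwell clock at frame 0), masking of post-event frames and donor-only
#' molecules, first-frames population samples, area-normalised histogram,
#' Gaussian-mixture state decomposition with BIC model selection,
#' state fractions, per-frame state assignment, interconversion
#' statistics, and donor-acceptor cross-correlation on a subset of
#' trajectories.
#'
#' @param traces Trace tibble ([simulate_traces()] or [extract_traces()]).
#' @param alpha Leakage correction factor.
#' @param n_init_frames Frames averaged per molecule for the population.
#' @param bins,range Histogram binning.
#' @param k Candidate mixture component counts.
#' @param frame_interval Seconds per frame.
#' @param max_lag Cross-correlation maximum lag (frames).
#' @param n_xcorr Number of molecules cross-correlated (first N).
#' @param seed Seed for the mixture restarts.
#' @return List of class `equilibrium_analysis`: `events`, `samples`,
#'   `histogram`, `fit`, `fractions`, `transitions`, `dynamic_percent`,
#'   `xcorr`.
#' @export
analyze_equilibrium <- function(traces, alpha = 0.88, n_init_frames = 10,
                                bins = 60, range = c(-0.1, 1.1), k = 1:3,
                                frame_interval = 0.1, max_lag = 50,
                                n_xcorr = 20, seed = 1L) {
  if (nrow(traces) == 0) abort("empty trace table")
  fr <- compute_fret(traces, alpha = alpha)
  events <- classify_events(traces, injection_frame = 0,
                            frame_interval = frame_interval)
  masked <- mask_after_events(fr, events)
  samples <- fret_samples(masked, n_init_frames = n_init_frames)
  if (nrow(samples) == 0) abort("no valid molecules after masking")
  hist <- fret_histogram(samples, bins = bins, range = range)
  fit <- fit_fret_states(samples, k = k, seed = seed)
  fractions <- population_fractions(fit)
  assigned <- assign_states(masked, fit)
  transitions <- detect_interconversion(assigned)
  dyn_pct <- 100 * mean(transitions$molecules$dynamic)

  ids <- head(unique(masked$molecule_id), n_xcorr)
  xcorr <- lapply(ids, function(id) {
    tr <- filter(traces, .data$molecule_id == id)
    ml <- min(max_lag, nrow(tr) - 1)
    mutate(cross_correlation(tr, ml, frame_interval), molecule_id = id)
  })
  out <- list(events = events, samples = samples, histogram = hist,
              fit = fit, fractions = fractions, transitions = transitions,
              dynamic_percent = dyn_pct, xcorr = bind_rows(xcorr))
  class(out) <- "equilibrium_analysis"
  out
}

#' @export
print.equilibrium_analysis <- function(x, ...) {
  cat("<equilibrium_analysis>", nrow(x$samples), "molecules;",
      x$fit$k, "FRET states\n")
  print(x$fractions)
  cat(sprintf("dynamic molecules: %.2f%%\n", x$dynamic_percent))
  invisible(x)
}

#' End-to-end real-time injection analysis
#'
#' Runs the single-turnover workflow on an injection experiment: FRET
#' computation, per-molecule event classification against the injection
#' frame, reacted fractions, dwell-time exponential fits for the transfer
#' and acceptor-photobleach populations, per-initial-state reaction
#' rates, the time-windowed population contour, and the cumulative
#' field-of-view intensity.
#'
#' @param traces Trace tibble.
#' @param injection_frame Injection frame (required).
#' @param frame_interval Seconds per frame (1 s for real-time imaging).
#' @param alpha Leakage correction factor.
#' @param k Candidate mixture component counts for initial-state labels.
#' @param window_s Contour window length (s).
#' @param bins,range Histogram binning.
#' @param dwell_model Dwell-fit model passed to [fit_dwell_times()].
#' @param seed Seed for mixture restarts.
#' @return List of class `realtime_analysis`: `events`, `fractions`,
#'   `fit`, `dwell_fit_transfer`, `dwell_fit_bleach`, `state_rates`,
#'   `contour`, `cumulative`.
#' @export
analyze_realtime <- function(traces, injection_frame, frame_interval = 1,
                             alpha = 0.88, k = 1:3, window_s = 15,
                             bins = 60, range = c(-0.1, 1.1),
                             dwell_model = "auto", seed = 1L) {
  if (missing(injection_frame) || is.na(injection_frame)) {
    abort("injection_frame is required for real-time analysis")
  }
  fr <- compute_fret(traces, alpha = alpha)
  # initial-state labels need a population fit from pre-injection frames
  pre <- filter(fr, .data$frame <= injection_frame)
  fit <- NULL
  pre_samples <- fret_samples(pre, n_init_frames = 10)
  if (nrow(pre_samples) >= 20) {
    fit <- fit_fret_states(pre_samples, k = k, seed = seed)
  }
  events <- classify_events(traces, injection_frame = injection_frame,
                            frame_interval = frame_interval, fit = fit,
                            alpha = alpha)
  fractions <- reacted_fractions(events)

  dwell_of <- function(classes) {
    d <- events$dwell_s[events$class %in% classes & !is.na(events$dwell_s)]
    if (length(d) >= 10) {
      fit_dwell_times(d, model = dwell_model, frame_interval = frame_interval)
    } else NULL
  }
  masked <- mask_after_events(fr, events)
  out <- list(
    events = events,
    fractions = fractions,
    fit = fit,
    dwell_fit_transfer = dwell_of(c("transfer_FRET", "transfer_donor_only")),
    dwell_fit_bleach = dwell_of("acceptor_photobleach"),
    state_rates = if (!is.null(fit)) per_state_reaction_rates(events) else NULL,
    contour = windowed_histograms(masked, window_s = window_s, bins = bins,
                                  range = range),
    cumulative = cumulative_intensity(traces, normalize = TRUE,
                                      injection_frame = injection_frame)
  )
  class(out) <- "realtime_analysis"
  out
}

#' @export
print.realtime_analysis <- function(x, ...) {
  cat("<realtime_analysis>", nrow(x$events), "molecules\n")
  print(x$fractions)
  if (!is.null(x$dwell_fit_transfer)) {
    cat("transfer dwell rate(s):",
        paste(signif(x$dwell_fit_transfer$rates, 3), collapse = ", "), "/s\n")
  }
  invisible(x)
}
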