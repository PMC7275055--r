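#' Leakage-corrected apparent FRET efficiency per frame
#'
#' Computes, for every frame of every molecule,
#' `E = I_A / (I_D + alpha * I_A)`, where `alpha` corrects for bleed-through
#' of donor emission into the acceptor detection channel (the default 0.88
#' corresponds to 12% leakage for the Cy3B / AlexaFluor 647 pair).
#' Frames where the corrected total `I_D + alpha * I_A` is not positive are
#' masked invalid rather than producing infinities. The ratio is
#' scale-invariant: multiplying both channels by any positive constant
#' leaves `E` unchanged.
#'
#' @param traces Tibble with columns `molecule_id`, `frame`, `I_D`, `I_A`
#'   (and optionally `time_s`), as produced by [simulate_traces()] or
#'   [extract_traces()].
#' @param alpha Leakage correction factor in (0, 1].
#' @param clamp If `TRUE`, clamp `E` into `[0, 1]`; by default the raw
#'   ratio is reported (values slightly outside `[0, 1]` are informative
#'   about background subtraction and noise).
#' @return The input tibble with columns `E_fret` and `valid` added.
#'   Molecules with no valid frame at all trigger a warning.
#' @examples
#' tr <- tibble::tibble(molecule_id = 1, frame = 1:2,
#'                      I_D = c(50, 100), I_A = c(50, 0))
#' compute_fret(tr)$E_fret
#' @export
compute_fret <- function(traces, alpha = 0.88, clamp = FALSE) {
  if (alpha <= 0 || alpha > 1) abort("alpha must lie in (0, 1]")
  stopifnot(all(c("molecule_id", "frame", "I_D", "I_A") %in% names(traces)))
  denom <- traces$I_D + alpha * traces$I_A
  valid <- is.finite(denom) & denom > 0 &
    is.finite(traces$I_D) & is.finite(traces$I_A)
  e <- ifelse(valid, traces$I_A / denom, NA_real_)
  if (clamp) e <- pmin(pmax(e, 0), 1)
  out <- mutate(traces, E_fret = e, valid = valid)
  bad <- tapply(valid, traces$molecule_id, function(v) !any(v))
  if (any(bad)) {
    warn(paste("molecules with no valid frames:",
               paste(names(bad)[bad], collapse = ", ")))
  }
  out
}

#' Convert dye separation to FRET efficiency (and back)
#'
#' The standard Forster relation `E = 1 / (1 + (r / R0)^6)`, with the
#' default Forster radius of 60 Angstrom for the Cy3B / AlexaFluor 647
#' pair. `efficiency_to_distance()` is the exact inverse for `E` in (0, 1).
#'
#' @param r Inter-dye distance(s) in Angstrom, non-negative.
#' @param efficiency FRET efficiency in (0, 1).
#' @param R0 Forster radius in Angstrom.
#' @return Numeric vector of efficiencies (or distances).
#' @examples
#' distance_to_efficiency(60)          # 0.5 at r = R0
#' efficiency_to_distance(0.5)         # back to 60
#' @export
distance_to_efficiency <- function(r, R0 = 60) {
  if (R0 <= 0) abort("R0 must be positive")
  if (any(r < 0)) abort("distance must be non-negative")
  1 / (1 + (r / R0)^6)
}

#' @rdname distance_to_efficiency
#' @export
efficiency_to_distance <- function(efficiency, R0 = 60) {
  if (R0 <= 0) abort("R0 must be positive")
  if (any(efficiency <= 0 | efficiency >= 1)) {
    abort("efficiency must lie strictly in (0, 1)")
  }
  R0 * ((1 - efficiency) / efficiency)^(1 / 6)
}

#' Per-molecule FRET samples from initial-frame averages
#'
#' Condenses each molecule's trajectory to a single population sample: the
#' mean apparent FRET over its first `n_init_frames` valid frames. This is
#' the standard way equilibrium populations are built — one number per
#' molecule so that long-lived molecules are not over-weighted. Molecules
#' with fewer valid frames than `n_init_frames` contribute the mean of all
#' their valid frames; molecules with fewer than `min_frames` valid frames
#' are dropped (their averages would be too noisy to place).
#'
#' @param fret Tibble from [compute_fret()] (columns `molecule_id`,
#'   `frame`, `E_fret`, `valid`).
#' @param n_init_frames Number of initial valid frames to average
#'   (default 10).
#' @param min_frames Minimum valid frames for a molecule to be kept.
#' @return Tibble with `molecule_id`, `E_mean`, `n_frames_used`.
#' @export
fret_samples <- function(fret, n_init_frames = 10, min_frames = 3) {
  stopifnot(all(c("molecule_id", "E_fret", "valid") %in% names(fret)))
  fret %>%
    filter(.data$valid) %>%
    arrange(.data$molecule_id, .data$frame) %>%
    group_by(.data$molecule_id) %>%
    summarise(
      E_mean = mean(head(.data$E_fret, n_init_frames)),
      n_frames_used = min(n(), n_init_frames),
      .groups = "drop"
    ) %>%
    filter(.data$n_frames_used >= min_frames)
}

#' Area-normalised FRET population histogram
#'
#' Bins per-molecule FRET samples into a probability-density histogram
#' normalised to unit area, so populations measured under different
#' conditions (different molecule counts) are directly comparable.
#'
#' @param samples Tibble from [fret_samples()] (or a bare numeric vector of
#'   per-molecule FRET values).
#' @param bins Number of equal-width bins.
#' @param range Histogram support; samples outside it are clipped into the
#'   edge bins so that the density always integrates to exactly 1.
#' @return A tibble of class `fret_histogram` with columns `bin_left`,
#'   `bin_right`, `bin_mid`, `count`, `density`; attributes `n_molecules`
#'   and `samples` carry the inputs.
#' @examples
#' h <- fret_histogram(stats::rnorm(500, 0.6, 0.05))
#' sum(h$density * (h$bin_right - h$bin_left))  # exactly 1
#' @export
fret_histogram <- function(samples, bins = 60, range = c(-0.1, 1.1)) {
  x <- if (is.data.frame(samples)) samples$E_mean else as.numeric(samples)
  x <- x[is.finite(x)]
  if (length(x) == 0) abort("no valid FRET samples to histogram")
  edges <- seq(range[1], range[2], length.out = bins + 1)
  bw <- diff(edges)[1]
  x <- pmin(pmax(x, range[1]), range[2] - bw * 1e-9)
  idx <- findInterval(x, edges, rightmost.closed = TRUE)
  counts <- tabulate(idx, nbins = bins)
  out <- tibble(
    bin_left = edges[-(bins + 1)],
    bin_right = edges[-1],
    bin_mid = (edges[-(bins + 1)] + edges[-1]) / 2,
    count = counts,
    density = counts / (length(x) * bw)
  )
  attr(out, "n_molecules") <- length(x)
  attr(out, "samples") <- x
  class(out) <- c("fret_histogram", class(out))
  out
}

#' Time-windowed FRET histograms (population contour)
#'
#' Splits each trajectory into consecutive time windows (15 s by default)
#' and histograms the surviving valid frames in each window. The result is
#' the contour-plot matrix used to follow a reacting population over time:
#' rows are windows, columns FRET bins. Only frames marked valid are used,
#' so masking frames after each molecule's terminal event (see
#' [mask_after_events()]) restricts each window to molecules still alive.
#'
#' @param fret Tibble from [compute_fret()], with a `time_s` column.
#' @param window_s Window length in seconds.
#' @param bins,range Histogram binning, as in [fret_histogram()].
#' @param normalize `"density"` area-normalises each window (empty windows
#'   are flagged, not errors); `"count"` keeps raw counts.
#' @return A tibble of class `fret_contour` with columns `window`,
#'   `t_start`, `t_end`, `bin_mid`, `count`, `density`, `n_frames`;
#'   attribute `matrix` holds the windows-by-bins matrix.
#' @export
windowed_histograms <- function(fret, window_s = 15, bins = 60,
                                range = c(-0.1, 1.1),
                                normalize = c("density", "count")) {
  normalize <- match.arg(normalize)
  stopifnot("time_s" %in% names(fret))
  dt <- min(diff(sort(unique(fret$time_s))))
  if (window_s < dt) abort("window_s is shorter than one frame")
  edges <- seq(range[1], range[2], length.out = bins + 1)
  bw <- diff(edges)[1]
  mids <- (edges[-(bins + 1)] + edges[-1]) / 2

  live <- filter(fret, .data$valid)
  win <- floor(live$time_s / window_s)
  n_win <- floor(max(fret$time_s) / window_s) + 1
  rows <- lapply(seq_len(n_win) - 1, function(w) {
    x <- live$E_fret[win == w]
    x <- x[is.finite(x)]
    if (length(x)) {
      x <- pmin(pmax(x, range[1]), range[2] - bw * 1e-9)
      counts <- tabulate(findInterval(x, edges, rightmost.closed = TRUE), nbins = bins)
    } else {
      counts <- rep(0L, bins)
    }
    tibble(
      window = w + 1L, t_start = w * window_s, t_end = (w + 1) * window_s,
      bin_mid = mids, count = counts,
      density = if (length(x)) counts / (length(x) * bw) else NA_real_,
      n_frames = length(x)
    )
  })
  out <- bind_rows(rows)
  m <- matrix(if (normalize == "density") out$density else out$count,
              nrow = n_win, ncol = bins, byrow = TRUE,
              dimnames = list(NULL, sprintf("%.3f", mids)))
  attr(out, "matrix") <- m
  class(out) <- c("fret_contour", class(out))
  out
}

#' Mask trajectory frames at and after each molecule's terminal event
#'
#' Sets `valid = FALSE` for all frames from the event frame onward (with an
#' optional guard band just before it), so that downstream population
#' statistics only see frames where the molecule still carried both dyes.
#' Donor-only molecules can be dropped entirely, since their apparent FRET
#' carries no conformational information.
#'
#' @param fret Tibble from [compute_fret()].
#' @param events Event table from [classify_events()] (needs
#'   `molecule_id`, `event_frame`, `donor_only`).
#' @param guard_frames Extra frames excluded immediately before the event.
#' @param drop_donor_only Remove donor-only molecules entirely.
#' @return The masked tibble.
#' @export
mask_after_events <- function(fret, events, guard_frames = 1,
                              drop_donor_only = TRUE) {
  ev <- select(events, "molecule_id", "event_frame", "donor_only")
  out <- left_join(fret, ev, by = "molecule_id")
  out$valid <- out$valid &
    (is.na(out$event_frame) | out$frame < out$event_frame - guard_frames)
  if (drop_donor_only) out <- filter(out, !.data$donor_only)
  select(out, -"event_frame", -"donor_only")
}
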