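#' Donor-acceptor cross-correlation of a single trajectory
#'
#' Computes, for lags `0..max_lag` frames,
#' `G(tau) = sum_t (I_D(t) - mean(I_D)) (I_A(t + tau) - mean(I_A)) /
#' (N * mean(I_D * I_A))`, with channel means taken over the entire
#' trajectory. Anticorrelated switching between FRET states produces a
#' negative `G` at short lags that decays with the switching correlation
#' time; a static single-state trajectory gives `G` fluctuating around
#' zero, the signature used to confirm the absence of fast hidden dynamics.
#'
#' The denominator is the mean of the per-frame intensity product by
#' default; `denominator = "product_of_means"` uses the product of the two
#' channel means instead (both normalisation conventions appear in the
#' literature; they differ only by a constant factor per trace).
#'
#' @param trace Tibble with columns `I_D`, `I_A` for one molecule (a
#'   single-molecule slice of a trace table), or a list/data.frame with
#'   those columns.
#' @param max_lag Maximum lag in frames (`< N`).
#' @param frame_interval Seconds per frame, for the `lag_s` column.
#' @param denominator Normalisation convention (see Details).
#' @return Tibble with `lag`, `lag_s`, `G`.
#' @examples
#' tr <- tibble::tibble(I_D = c(1, 2, 1, 2), I_A = c(2, 1, 2, 1))
#' cross_correlation(tr, max_lag = 1)
#' @export
cross_correlation <- function(trace, max_lag, frame_interval = 1,
                              denominator = c("mean_product",
                                              "product_of_means")) {
  denominator <- match.arg(denominator)
  i_d <- trace$I_D
  i_a <- trace$I_A
  n <- length(i_d)
  if (max_lag < 0 || max_lag >= n) abort("need 0 <= max_lag < trace length")
  m_d <- mean(i_d)
  m_a <- mean(i_a)
  den <- n * switch(denominator,
                    mean_product = mean(i_d * i_a),
                    product_of_means = m_d * m_a)
  if (!is.finite(den) || den == 0) abort("zero cross-correlation denominator")
  dd <- i_d - m_d
  da <- i_a - m_a
  g <- vapply(0:max_lag, function(tau) {
    idx <- seq_len(n - tau)
    sum(dd[idx] * da[idx + tau]) / den
  }, 0)
  tibble(lag = 0:max_lag, lag_s = (0:max_lag) * frame_interval, G = g)
}

#' Classify the terminal event of each trajectory
#'
#' Determines, per molecule, what ended its fluorescence: ubiquitin
#' transfer (rapid simultaneous loss of donor and acceptor with no
#' recovery), acceptor photobleaching (acceptor loss with concomitant
#' donor recovery, since de-quenched donor emission rises), donor
#' photobleaching (donor loss with the acceptor already dark), or nothing
#' (unreacted). Donor-only molecules — identified by an acceptor channel
#' at background over the first `donor_only_frames` frames — that lose
#' their donor are classed `transfer_donor_only`; without an acceptor
#' their donor loss cannot be distinguished from donor bleaching
#' per-molecule, only statistically through dwell-time rates.
#'
#' Steps are found per channel as the single change point maximising the
#' two-segment mean-shift likelihood; a drop must land below
#' `background + k_sigma * sigma` (noise estimated robustly from frame
#' differences) and persist at least `min_persist` frames; "simultaneous"
#' means within one frame. For transfer calls, both channels must remain
#' at background for `recovery_frames` frames (or to trace end) — there is
#' no recovery of FRET after transfer. Conflicting signatures are flagged
#' `ambiguous` and excluded from rate fits.
#'
#' @param traces Trace tibble (`molecule_id`, `frame`, `I_D`, `I_A`).
#' @param injection_frame Frame at the end of which reagents arrive; the
#'   dwell clock starts there. Use 0 for equilibrium traces.
#' @param frame_interval Seconds per frame.
#' @param background Background intensity level.
#' @param k_sigma Threshold in noise SDs above background.
#' @param recovery_frames Frames a transfer-lost signal must stay dark.
#' @param min_persist Minimum frames for a step's post-segment.
#' @param donor_only_frames Initial frames examined for the donor-only test.
#' @param fit Optional [fit_fret_states()] result; when supplied, each
#'   molecule gets an `initial_state` label (index into `fit$means`) from
#'   its mean pre-event FRET over the first 10 valid frames.
#' @param alpha Leakage factor used for the initial-state FRET average.
#' @return Tibble of class `event_calls`: `molecule_id`, `class`,
#'   `event_frame`, `dwell_s` (NA for unreacted or pre-injection events),
#'   `initial_state`, `donor_only`. Frame counts refer to the input frames.
#' @export
classify_events <- function(traces, injection_frame = 0, frame_interval = 1,
                            background = 0, k_sigma = 3, recovery_frames = 10,
                            min_persist = 3, donor_only_frames = 5,
                            fit = NULL, alpha = 0.88) {
  traces <- arrange(traces, .data$molecule_id, .data$frame)
  res <- lapply(split(seq_len(nrow(traces)), traces$molecule_id), function(rows) {
    classify_one(traces$I_D[rows], traces$I_A[rows],
                 traces$molecule_id[rows][1],
                 injection_frame, frame_interval, background, k_sigma,
                 recovery_frames, min_persist, donor_only_frames, fit, alpha)
  })
  out <- bind_rows(res)
  class(out) <- c("event_calls", class(out))
  out
}

classify_one <- function(i_d, i_a, id, injection_frame, dt, background,
                         k_sigma, recovery_frames, min_persist,
                         donor_only_frames, fit, alpha) {
  n <- length(i_d)
  sig_d <- robust_noise_sd(i_d)
  sig_a <- robust_noise_sd(i_a)
  thr_d <- background + k_sigma * sig_d
  thr_a <- background + k_sigma * sig_a

  donor_only <- mean(i_a[seq_len(min(donor_only_frames, n))]) < thr_a

  sd_step <- step_detect(i_d, k_sigma * sig_d, min_persist)
  sa_step <- step_detect(i_a, k_sigma * sig_a, min_persist)
  d_drop <- !is.null(sd_step) && sd_step$post < thr_d && sd_step$pre > thr_d
  d_rise <- !is.null(sd_step) && sd_step$post > sd_step$pre + k_sigma * sig_d
  a_drop <- !is.null(sa_step) && sa_step$post < thr_a && sa_step$pre > thr_a

  cls <- "unreacted"
  ev <- NA_integer_
  if (donor_only) {
    if (d_drop) {
      cls <- "transfer_donor_only"
      ev <- sd_step$cp
    }
  } else if (a_drop && d_rise && abs(sd_step$cp - sa_step$cp) <= 1) {
    cls <- "acceptor_photobleach"
    ev <- sa_step$cp
  } else if (a_drop && d_drop && abs(sd_step$cp - sa_step$cp) <= 1) {
    from <- max(sd_step$cp, sa_step$cp)
    dark_to <- min(n, from + recovery_frames)
    # recovery means a sustained (>= min_persist frames) return above
    # threshold, not a single noise excursion
    dark <- !sustained_above(i_d[from:dark_to], thr_d, min_persist) &&
      !sustained_above(i_a[from:dark_to], thr_a, min_persist)
    if (dark) {
      cls <- "transfer_FRET"
      ev <- max(sd_step$cp, sa_step$cp)
    } else {
      cls <- "ambiguous"
      ev <- sd_step$cp
    }
  } else if (d_drop && !a_drop &&
             mean(i_a[seq_len(max(sd_step$cp - 1, 1))]) < thr_a) {
    cls <- "donor_photobleach"
    ev <- sd_step$cp
  } else if (a_drop && !d_drop && !d_rise) {
    cls <- "acceptor_photobleach"
    ev <- sa_step$cp
  } else if (d_drop || a_drop) {
    cls <- "ambiguous"
    ev <- if (d_drop) sd_step$cp else sa_step$cp
  }

  # a dual loss at or before the injection frame cannot be transfer (no
  # reagents present yet); the only physical explanation is donor bleaching
  if (!is.na(ev) && ev <= injection_frame && injection_frame > 0 &&
      cls %in% c("transfer_FRET", "transfer_donor_only")) {
    cls <- "donor_photobleach"
  }
  dwell <- if (!is.na(ev) && ev > injection_frame) {
    (ev - injection_frame) * dt
  } else NA_real_

  init_state <- NA_integer_
  if (!is.null(fit) && !donor_only) {
    upto <- if (is.na(ev)) n else max(ev - 2L, 1L)
    e <- i_a[seq_len(upto)] / (i_d[seq_len(upto)] + alpha * i_a[seq_len(upto)])
    e <- e[is.finite(e)]
    if (length(e) >= 1) {
      init_state <- which.min(abs(mean(head(e, 10)) - fit$means))
    }
  }

  tibble(molecule_id = id, class = cls, event_frame = ev, dwell_s = dwell,
         initial_state = init_state, donor_only = donor_only)
}

# TRUE if x contains a run of at least len consecutive values above thr
sustained_above <- function(x, thr, len) {
  r <- rle(x > thr)
  any(r$values & r$lengths >= len)
}

# robust per-frame noise SD from first differences
robust_noise_sd <- function(x) {
  s <- mad(diff(x)) / sqrt(2)
  if (!is.finite(s) || s <= 0) s <- max(sd(x), .Machine$double.eps)
  s
}

# single change point maximising the two-segment mean-shift likelihood
# (equivalently, the between-segment sum-of-squares); returns NULL when the
# best split is not significant at `min_delta` or violates `min_persist`.
step_detect <- function(x, min_delta, min_persist) {
  n <- length(x)
  if (n < 2 * min_persist) return(NULL)
  cs <- cumsum(x)
  tot <- cs[n]
  k <- seq_len(n - 1)
  mean1 <- cs[k] / k
  mean2 <- (tot - cs[k]) / (n - k)
  between <- k * (n - k) / n * (mean1 - mean2)^2
  valid <- k >= min_persist & (n - k) >= min_persist
  between[!valid] <- -Inf
  cp <- which.max(between)
  pre <- mean1[cp]
  post <- mean2[cp]
  if (abs(pre - post) < min_delta) return(NULL)
  list(cp = cp + 1L, pre = pre, post = post)   # cp = first frame of new level
}

#' Per-class reaction percentages
#'
#' Summarises an event table into the percentage of molecules in each
#' class, and additionally reports the combined transfer percentage
#' (FRET-pair plus donor-only transfers) — the headline "reacted fraction"
#' of a single-turnover injection experiment.
#'
#' @param events Event table from [classify_events()].
#' @return Tibble with `class`, `n`, `percent`; the row
#'   `transfer_combined` (flagged by `combined = TRUE`) aggregates both
#'   transfer classes.
#' @export
reacted_fractions <- function(events) {
  if (nrow(events) == 0) abort("no event calls supplied")
  total <- nrow(events)
  base <- events %>%
    count(.data$class, name = "n") %>%
    mutate(percent = 100 * .data$n / total, combined = FALSE)
  n_tr <- sum(events$class %in% c("transfer_FRET", "transfer_donor_only"))
  bind_rows(base,
            tibble(class = "transfer_combined", n = n_tr,
                   percent = 100 * n_tr / total, combined = TRUE))
}

#' Exponential fit of dwell-time distributions
#'
#' Bins dwell times and fits `A exp(-k t)` (mono) or
#' `A1 exp(-k1 t) + A2 exp(-k2 t)` (bi) to the histogram by weighted
#' nonlinear least squares, each bin's residual scaled by its counting
#' error sqrt(count) (inverse-variance weights), with standard errors
#' from the fit covariance. `model = "auto"` fits both and selects by
#' AIC. An unbinned maximum-likelihood rate (`1 / mean(dwell)`) is
#' reported alongside as a cross-check. If all dwells are identical the
#' degenerate mono fit `k = 1 / mean` is returned with a warning.
#'
#' @param dwells Numeric vector of dwell times (s), positive; at least 10.
#' @param model `"auto"`, `"mono"` or `"bi"`.
#' @param frame_interval Seconds per frame; the histogram bin width is two
#'   frames.
#' @return An object of class `dwell_fit`: `model`, `rates` (per s),
#'   `rate_se`, `amplitudes`, `aic` (named, for the models tried),
#'   `mle_rate`, `n`, and the histogram used.
#' @examples
#' set.seed(1)
#' fit <- fit_dwell_times(rexp(400, 0.05), model = "mono")
#' round(fit$rates, 3)
#' @export
fit_dwell_times <- function(dwells, model = c("auto", "mono", "bi"),
                            frame_interval = 1) {
  model <- match.arg(model)
  dwells <- dwells[is.finite(dwells) & dwells > 0]
  if (length(dwells) < 10) abort("at least 10 dwell times are required")
  mle_rate <- 1 / mean(dwells)

  if (sd(dwells) == 0) {
    warn("all dwell times identical; returning degenerate mono fit k = 1/mean")
    out <- list(model = "mono", rates = mle_rate, rate_se = NA_real_,
                amplitudes = length(dwells), aic = c(mono = NA_real_),
                mle_rate = mle_rate, n = length(dwells), histogram = NULL)
    class(out) <- "dwell_fit"
    return(out)
  }

  bw <- 2 * frame_interval
  edges <- seq(0, max(dwells) + bw, by = bw)
  counts <- tabulate(findInterval(dwells, edges, rightmost.closed = TRUE),
                     nbins = length(edges) - 1)
  mid <- edges[-length(edges)] + bw / 2
  keep <- counts > 0
  df <- data.frame(t = mid[keep], y = counts[keep], w = 1 / counts[keep])

  fit_mono <- try(minpack.lm::nlsLM(
    y ~ A * exp(-k * t), data = df, weights = df$w,
    start = list(A = max(df$y), k = mle_rate),
    lower = c(0, 1e-8), control = minpack.lm::nls.lm.control(maxiter = 200)
  ), silent = TRUE)
  fit_bi <- if (model %in% c("auto", "bi")) {
    try(minpack.lm::nlsLM(
      y ~ A1 * exp(-k1 * t) + A2 * exp(-k2 * t), data = df, weights = df$w,
      start = list(A1 = max(df$y) * 0.7, k1 = mle_rate * 3,
                   A2 = max(df$y) * 0.3, k2 = mle_rate / 3),
      lower = c(0, 1e-8, 0, 1e-8),
      control = minpack.lm::nls.lm.control(maxiter = 400)
    ), silent = TRUE)
  } else NULL

  aic <- c(
    mono = if (!inherits(fit_mono, "try-error")) AIC(fit_mono) else NA_real_,
    bi = if (!is.null(fit_bi) && !inherits(fit_bi, "try-error")) AIC(fit_bi) else NA_real_
  )
  # a biexponential whose rates are indistinguishable, pinned at the
  # lower bound, or whose minor amplitude is negligible is not a genuine
  # second kinetic component
  bi_ok <- !is.null(fit_bi) && !inherits(fit_bi, "try-error")
  if (bi_ok) {
    cb <- coef(fit_bi)
    bi_ok <- max(cb["k1"], cb["k2"]) / max(min(cb["k1"], cb["k2"]), 1e-12) >= 3 &&
      min(cb["k1"], cb["k2"]) > 1e-6 &&
      min(cb["A1"], cb["A2"]) > 0.02 * (cb["A1"] + cb["A2"])
  }
  chosen <- switch(model,
    mono = "mono",
    bi = "bi",
    auto = if (bi_ok && !is.na(aic["bi"]) &&
               (is.na(aic["mono"]) || aic["bi"] < aic["mono"])) "bi" else "mono"
  )
  fit <- if (chosen == "bi") fit_bi else fit_mono
  if (inherits(fit, "try-error") || is.null(fit)) {
    abort("dwell-time fit failed to converge")
  }
  cf <- summary(fit)$coefficients
  if (chosen == "mono") {
    rates <- cf["k", "Estimate"]
    rate_se <- cf["k", "Std. Error"]
    amps <- cf["A", "Estimate"]
  } else {
    ord <- order(c(cf["k1", "Estimate"], cf["k2", "Estimate"]), decreasing = TRUE)
    rates <- c(cf["k1", "Estimate"], cf["k2", "Estimate"])[ord]
    rate_se <- c(cf["k1", "Std. Error"], cf["k2", "Std. Error"])[ord]
    amps <- c(cf["A1", "Estimate"], cf["A2", "Estimate"])[ord]
  }
  out <- list(model = chosen, rates = rates, rate_se = rate_se,
              amplitudes = amps, aic = aic, mle_rate = mle_rate,
              n = length(dwells),
              histogram = tibble(t = df$t, count = df$y), fit = fit)
  class(out) <- "dwell_fit"
  out
}

#' @export
print.dwell_fit <- function(x, ...) {
  cat("<dwell_fit>", x$model, "exponential,", x$n, "dwells\n")
  print(tidy(x))
  invisible(x)
}

#' Interconversion detection from assigned states
#'
#' Flags trajectories showing at least one accepted state-label change
#' before their terminal event, and lists the transitions. With the
#' long-lived states typical of stable conformations, only a small
#' percentage of molecules (about 1% in the published equilibrium data)
#' is expected to be dynamic on a one-minute observation window.
#'
#' @param assigned Tibble from [assign_states()] (columns `molecule_id`,
#'   `frame`, `state`; invalid frames have `NA` state).
#' @return A list of class `fret_transitions`: `molecules` (tibble with
#'   `molecule_id`, `n_transitions`, `dynamic`) and `transitions` (tibble
#'   with `molecule_id`, `frame`, `from_state`, `to_state`).
#' @export
detect_interconversion <- function(assigned) {
  stopifnot(all(c("molecule_id", "frame", "state") %in% names(assigned)))
  assigned <- arrange(assigned, .data$molecule_id, .data$frame)
  mols <- list()
  trans <- list()
  for (rows in split(seq_len(nrow(assigned)), assigned$molecule_id)) {
    id <- assigned$molecule_id[rows][1]
    s <- assigned$state[rows]
    f <- assigned$frame[rows]
    ok <- !is.na(s)
    s <- s[ok]
    f <- f[ok]
    ch <- which(diff(s) != 0)
    mols[[length(mols) + 1]] <- tibble(
      molecule_id = id, n_transitions = length(ch),
      dynamic = length(ch) > 0)
    if (length(ch)) {
      trans[[length(trans) + 1]] <- tibble(
        molecule_id = id, frame = f[ch + 1],
        from_state = s[ch], to_state = s[ch + 1])
    }
  }
  out <- list(
    molecules = bind_rows(mols),
    transitions = if (length(trans)) bind_rows(trans) else
      tibble(molecule_id = integer(), frame = integer(),
             from_state = integer(), to_state = integer())
  )
  class(out) <- "fret_transitions"
  out
}

#' @export
print.fret_transitions <- function(x, ...) {
  nd <- sum(x$molecules$dynamic)
  cat("<fret_transitions>", nd, "of", nrow(x$molecules),
      sprintf("molecules dynamic (%.2f%%)\n", 100 * nd / nrow(x$molecules)))
  invisible(x)
}

#' Per-initial-state reaction-rate summaries
#'
#' Groups transfer events by the molecule's initial FRET state and
#' summarises the per-molecule rates (`1 / dwell`): median, quartiles and
#' extremes — the box-plot comparison of reaction rates out of the low
#' versus high FRET states — plus each group's exponential rate
#' (`1 / mean dwell`). States with no events are reported empty.
#'
#' @param events Event table from [classify_events()] run with a mixture
#'   `fit` so that `initial_state` is populated.
#' @param n_states Number of states to report (defaults to the maximum
#'   label present).
#' @param state_labels Optional labels in ascending-FRET order.
#' @return Tibble with one row per state: `n`, `rate_median`, `rate_q1`,
#'   `rate_q3`, `rate_min`, `rate_max`, `rate_exp`; attribute `rates`
#'   holds the per-molecule table.
#' @export
per_state_reaction_rates <- function(events, n_states = NULL,
                                     state_labels = NULL) {
  tr <- filter(events,
               .data$class %in% c("transfer_FRET"),
               !is.na(.data$dwell_s), !is.na(.data$initial_state))
  if (is.null(n_states)) {
    n_states <- if (nrow(tr)) max(tr$initial_state) else 0L
  }
  if (is.null(state_labels)) {
    state_labels <- if (n_states == 3) c("low", "intermediate", "high") else
      paste0("state", seq_len(n_states))
  }
  rates <- mutate(tr, rate = 1 / .data$dwell_s)
  rows <- lapply(seq_len(n_states), function(s) {
    r <- rates$rate[rates$initial_state == s]
    if (length(r) == 0) {
      tibble(state = state_labels[s], n = 0L, rate_median = NA_real_,
             rate_q1 = NA_real_, rate_q3 = NA_real_, rate_min = NA_real_,
             rate_max = NA_real_, rate_exp = NA_real_)
    } else {
      q <- quantile(r, c(0.25, 0.5, 0.75), names = FALSE)
      tibble(state = state_labels[s], n = length(r), rate_median = q[2],
             rate_q1 = q[1], rate_q3 = q[3], rate_min = min(r),
             rate_max = max(r),
             rate_exp = 1 / mean(1 / r))
    }
  })
  out <- bind_rows(rows)
  attr(out, "rates") <- rates
  out
}

#' Cumulative intensity of all molecules over time
#'
#' Sums donor, acceptor and total intensity over all molecules at each
#' frame — the field-of-view intensity decay curve. In a reaction
#' injection the summed intensity falls as molecules transfer their
#' labelled ubiquitin away; in a control injection it stays flat apart
#' from slow photobleaching.
#'
#' @param traces Trace tibble.
#' @param normalize If `TRUE`, divide each curve by its mean over frames
#'   up to `injection_frame` (or the first 10 frames when no injection).
#' @param injection_frame Reference window end for normalisation.
#' @return Tibble with `frame`, `time_s` (if present), `donor`,
#'   `acceptor`, `total`.
#' @export
cumulative_intensity <- function(traces, normalize = FALSE,
                                 injection_frame = NULL) {
  out <- traces %>%
    group_by(.data$frame) %>%
    summarise(
      time_s = if ("time_s" %in% names(traces)) .data$time_s[1] else NA_real_,
      donor = sum(.data$I_D), acceptor = sum(.data$I_A),
      total = sum(.data$I_D) + sum(.data$I_A), .groups = "drop")
  if (normalize) {
    ref <- if (!is.null(injection_frame)) {
      out$frame <= injection_frame
    } else out$frame <= 10
    for (col in c("donor", "acceptor", "total")) {
      out[[col]] <- out[[col]] / mean(out[[col]][ref])
    }
  }
  out
}
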