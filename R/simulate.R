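#' Simulate a single smFRET trajectory
#'
#' Generates one donor/acceptor intensity trace under a [sim_config()],
#' together with its ground truth. The noise-free channel intensities are
#' set by inverting the leakage-corrected efficiency formula — given a
#' target apparent FRET `E` and total intensity `T`,
#' `I_D = T (1 - alpha E) / (1 - alpha E + E)` and
#' `I_A = E I_D / (1 - alpha E)` — so that [compute_fret()] recovers the
#' ground-truth state mean exactly in the noise-free limit.
#'
#' Each molecule experiences at most one terminal event, drawn from
#' competing exponentials: donor photobleaching (both channels fall to
#' background, since the acceptor is excited through FRET), acceptor
#' photobleaching (acceptor falls to background and the donor recovers to
#' the full summed intensity), or — after the injection frame, in real-time
#' configurations — ubiquitin transfer at the current state's configured
#' rate (simultaneous loss of both channels, with no subsequent recovery).
#' A configurable subpopulation interconverts between states as a
#' continuous-time Markov chain before its terminal event.
#'
#' @param config A [sim_config()].
#' @param molecule_seed Integer seed for this molecule's RNG stream.
#' @param molecule_id Identifier stored in the output.
#' @return A list with elements `trace` (tibble: `molecule_id`, `frame`,
#'   `time_s`, `I_D`, `I_A`) and `truth` (one-row tibble: initial state,
#'   donor-only and dynamic flags, event kind/frame/time, transition count,
#'   and the frame-wise `state_path` as a list column).
#' @seealso [simulate_traces()] for whole datasets.
#' @export
simulate_trace <- function(config, molecule_seed, molecule_id = 1L) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  set.seed(as.integer(molecule_seed) %% 2147483647L)

  n <- config$n_frames
  dt <- config$frame_interval
  total_t <- n * dt
  k_states <- length(config$state_means)

  donor_only <- runif(1) < config$donor_only_fraction
  init_state <- sample.int(k_states, 1L, prob = config$state_occupancies)
  dynamic <- k_states > 1 &&
    config$interconversion_rate > 0 &&
    runif(1) < config$dynamic_fraction

  # continuous-time state path: jump times + states
  jump_times <- numeric(0)
  jump_states <- integer(0)
  if (dynamic) {
    t_now <- 0
    s_now <- init_state
    repeat {
      t_now <- t_now + rexp(1, config$interconversion_rate)
      if (t_now >= total_t) break
      s_now <- sample(setdiff(seq_len(k_states), s_now), 1L)
      jump_times <- c(jump_times, t_now)
      jump_states <- c(jump_states, s_now)
    }
  }
  seg_start <- c(0, jump_times)
  seg_state <- c(init_state, jump_states)
  seg_end <- c(jump_times, total_t)

  # terminal event: competing exponentials (transfer hazard is piecewise
  # constant along the state path, active only after the injection frame)
  t_donor <- if (config$bleach_rate_donor > 0) rexp(1, config$bleach_rate_donor) else Inf
  t_acceptor <- if (!donor_only && config$bleach_rate_acceptor > 0) {
    rexp(1, config$bleach_rate_acceptor)
  } else Inf
  t_transfer <- Inf
  state_rates <- transfer_rates_by_state(config)
  if (!is.na(config$injection_frame) && any(state_rates > 0)) {
    t_inj <- config$injection_frame * dt
    u <- rexp(1)      # unit-exponential target for the integrated hazard
    acc <- 0
    for (i in seq_along(seg_state)) {
      a <- max(seg_start[i], t_inj)
      b <- seg_end[i]
      if (b <= a) next
      rate <- state_rates[seg_state[i]]
      seg_h <- rate * (b - a)
      if (acc + seg_h >= u && rate > 0) {
        t_transfer <- a + (u - acc) / rate
        break
      }
      acc <- acc + seg_h
    }
  }

  event_time <- min(t_donor, t_acceptor, t_transfer)
  if (is.finite(event_time) && event_time < total_t) {
    event_kind <- c("donor_bleach", "acceptor_bleach", "transfer")[
      which.min(c(t_donor, t_acceptor, t_transfer))]
    event_frame <- min(n, floor(event_time / dt) + 1L)
  } else {
    event_kind <- "none"
    event_frame <- NA_integer_
    event_time <- NA_real_
  }

  # frame-wise state path, truncated at the event
  frame_starts <- (seq_len(n) - 1L) * dt
  path <- seg_state[findInterval(frame_starts, seg_start)]
  last_live <- if (is.na(event_frame)) n else event_frame - 1L
  if (last_live < n) path[(last_live + 1L):n] <- path[max(last_live, 1L)]
  n_transitions <- if (last_live >= 2L) sum(diff(path[seq_len(last_live)]) != 0) else 0L

  # noise-free intensities from the inverted efficiency relation
  if (donor_only) {
    i_d <- rep(config$total_intensity, n)
    i_a <- rep(0, n)
  } else {
    e <- config$state_means[path]
    denom <- 1 - config$alpha * e
    i_d <- config$total_intensity * denom / (denom + e)
    i_a <- e * i_d / denom
  }
  if (!is.na(event_frame)) {
    post <- event_frame:n
    if (event_kind == "acceptor_bleach") {
      i_a[post] <- 0
      i_d[post] <- config$total_intensity
    } else {
      i_a[post] <- 0
      i_d[post] <- 0
    }
  }
  if (config$poisson_noise) {
    i_d <- stats::rpois(n, pmax(i_d, 0))
    i_a <- stats::rpois(n, pmax(i_a, 0))
  } else if (config$noise_sigma > 0) {
    i_d <- i_d + rnorm(n, 0, config$noise_sigma)
    i_a <- i_a + rnorm(n, 0, config$noise_sigma)
  }

  list(
    trace = tibble(
      molecule_id = molecule_id,
      frame = seq_len(n),
      time_s = frame_starts,
      I_D = i_d,
      I_A = i_a
    ),
    truth = tibble(
      molecule_id = molecule_id,
      initial_state = init_state,
      donor_only = donor_only,
      dynamic = dynamic,
      event_kind = event_kind,
      event_frame = event_frame,
      event_time = event_time,
      n_transitions = as.integer(n_transitions),
      state_path = list(as.integer(path))
    )
  )
}

transfer_rates_by_state <- function(config) {
  k <- length(config$state_means)
  if (k == 3) {
    c(config$reaction_rate_low, config$reaction_rate_mid, config$reaction_rate_high)
  } else if (k == 1) {
    config$reaction_rate_high
  } else {
    # lowest state uses the low rate, highest the high rate, rest the mid
    c(config$reaction_rate_low,
      rep(config$reaction_rate_mid, max(k - 2, 0)),
      config$reaction_rate_high)[seq_len(k)]
  }
}

#' Simulate a dataset of smFRET trajectories
#'
#' Runs [simulate_trace()] for `n_molecules` molecules, deriving one RNG
#' stream per molecule from the master seed by a fixed integer hash, so
#' identical `config` + `seed` give bit-identical output regardless of how
#' many molecules are drawn or in what order downstream code consumes them.
#'
#' @param config A [sim_config()] (or a preset name understood by
#'   [fret_presets()]).
#' @param n_molecules Number of molecules to simulate.
#' @param seed Master seed; defaults to `config$seed`.
#' @return An object of class `fret_sim`: a list with `traces` (long tibble
#'   of all frames), `truth` (one row per molecule) and `config`.
#' @examples
#' sim <- simulate_traces(sim_config(n_frames = 50), n_molecules = 5)
#' dplyr::count(sim$truth, event_kind)
#' @export
simulate_traces <- function(config, n_molecules, seed = NULL) {
  if (is.character(config)) config <- fret_presets(config)
  stopifnot(inherits(config, "sim_config"))
  if (n_molecules < 1) abort("n_molecules must be >= 1")
  if (is.null(seed)) seed <- config$seed
  out <- vector("list", n_molecules)
  for (i in seq_len(n_molecules)) {
    out[[i]] <- simulate_trace(config, molecule_seed(seed, i), molecule_id = i)
  }
  res <- list(
    traces = bind_rows(lapply(out, `[[`, "trace")),
    truth = bind_rows(lapply(out, `[[`, "truth")),
    config = config
  )
  class(res) <- "fret_sim"
  res
}

# fixed multiplicative hash of (seed, molecule index) -> stream seed < 2^31
molecule_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 69621) %% 2147483629)
}

#' @export
print.fret_sim <- function(x, ...) {
  cat("<fret_sim> ", nrow(x$truth), " molecules x ", x$config$n_frames,
      " frames (", x$config$frame_interval, " s/frame)\n", sep = "")
  print(count(x$truth, .data$event_kind))
  invisible(x)
}
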