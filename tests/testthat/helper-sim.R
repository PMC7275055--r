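# deterministic, noise-free configs used across tests

quiet_config <- function(...) {
  args <- list(noise_sigma = 0, donor_only_fraction = 0,
               bleach_rate_donor = 0, bleach_rate_acceptor = 0,
               dynamic_fraction = 0)
  user <- list(...)
  args[names(user)] <- user
  do.call(sim_config, args)
}

# single-state noise-free config at a given apparent FRET
single_state_config <- function(mean = 0.71, n_frames = 50, ...) {
  quiet_config(state_means = mean, state_occupancies = 1,
               n_frames = n_frames, ...)
}

# brute-force double-loop evaluation of the cross-correlation definition
xcorr_bruteforce <- function(i_d, i_a, max_lag,
                             denominator = "mean_product") {
  n <- length(i_d)
  m_d <- mean(i_d)
  m_a <- mean(i_a)
  den <- n * if (denominator == "mean_product") mean(i_d * i_a) else m_d * m_a
  vapply(0:max_lag, function(tau) {
    s <- 0
    for (t in seq_len(n - tau)) {
      s <- s + (i_d[t] - m_d) * (i_a[t + tau] - m_a)
    }
    s / den
  }, 0)
}

# expected event class implied by the ground truth labels
expected_class <- function(truth) {
  ifelse(truth$event_kind == "transfer" & !truth$donor_only, "transfer_FRET",
  ifelse(truth$event_kind == "transfer" & truth$donor_only, "transfer_donor_only",
  ifelse(truth$event_kind == "donor_bleach", "donor_photobleach",
  ifelse(truth$event_kind == "acceptor_bleach", "acceptor_photobleach",
         "unreacted"))))
}
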