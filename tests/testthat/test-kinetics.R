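test_that("cross-correlation matches the hand-computed and brute-force oracle", {
  # 4-point anticorrelated trace: numerator at lag 0 is 4 * (-0.25) = -1,
  # denominator 4 * mean(I_D * I_A) = 8, so G(0) = -1/8
  tr <- tibble::tibble(I_D = c(1, 2, 1, 2), I_A = c(2, 1, 2, 1))
  g <- cross_correlation(tr, max_lag = 2)
  expect_equal(g$G[1], -0.125)
  expect_equal(g$G, xcorr_bruteforce(tr$I_D, tr$I_A, 2), tolerance = 1e-12)

  # brute-force equivalence on random traces, both normalisations
  set.seed(20)
  for (rep in 1:5) {
    i_d <- runif(200, 100, 900)
    i_a <- runif(200, 100, 900)
    tr <- tibble::tibble(I_D = i_d, I_A = i_a)
    for (den in c("mean_product", "product_of_means")) {
      expect_equal(cross_correlation(tr, 20, denominator = den)$G,
                   xcorr_bruteforce(i_d, i_a, 20, den), tolerance = 1e-9)
    }
  }
  expect_equal(cross_correlation(tibble::tibble(I_D = rep(5, 10),
                                                I_A = rep(3, 10)), 3)$G,
               rep(0, 4))
  expect_error(cross_correlation(tibble::tibble(I_D = rep(0, 10),
                                                I_A = rep(0, 10)), 3),
               "denominator")
  expect_error(cross_correlation(tr, max_lag = 500), "max_lag")
})

test_that("anticorrelated switching gives negative short-lag correlation", {
  # two-state switcher: donor and acceptor move in opposite directions
  set.seed(30)
  state <- numeric(2000)
  s <- 1
  for (t in 1:2000) {
    if (runif(1) < 0.02) s <- 3 - s
    state[t] <- s
  }
  i_a <- ifelse(state == 1, 300, 700) + rnorm(2000, 0, 30)
  i_d <- 1000 - i_a + rnorm(2000, 0, 30)
  g <- cross_correlation(tibble::tibble(I_D = i_d, I_A = i_a), 400)
  expect_lt(g$G[1], 0)
  # decays towards zero well beyond the ~50-frame correlation time
  expect_lt(mean(abs(g$G[301:401])), 0.25 * abs(g$G[1]))
})

test_that("event classes are recovered from their channel signatures", {
  n <- 120
  base_d <- rep(466, n)
  base_a <- rep(534, n)
  mk <- function(i_d, i_a, id = 1) {
    tibble::tibble(molecule_id = id, frame = 1:n, I_D = i_d, I_A = i_a)
  }
  set.seed(40)
  noise <- function(x) x + rnorm(n, 0, 30)

  # transfer: simultaneous dual loss at frame 40, no recovery
  tr <- mk(noise(c(base_d[1:39], rep(0, n - 39))),
           noise(c(base_a[1:39], rep(0, n - 39))))
  ev <- classify_events(tr, injection_frame = 10, frame_interval = 1)
  expect_equal(ev$class, "transfer_FRET")
  expect_lte(abs(ev$event_frame - 40), 1)
  expect_equal(ev$dwell_s, (ev$event_frame - 10) * 1)

  # acceptor bleach: acceptor falls, donor recovers in the same frame
  ab <- mk(noise(c(base_d[1:59], rep(1000, n - 59))),
           noise(c(base_a[1:59], rep(0, n - 59))))
  expect_equal(classify_events(ab, 10, 1)$class, "acceptor_photobleach")

  # flat to the end: unreacted
  fl <- mk(noise(base_d), noise(base_a))
  expect_equal(classify_events(fl, 10, 1)$class, "unreacted")

  # donor-only molecule losing its donor
  do <- mk(noise(c(rep(1000, 69), rep(0, n - 69))), rnorm(n, 0, 30))
  evd <- classify_events(do, 10, 1)
  expect_equal(evd$class, "transfer_donor_only")
  expect_true(evd$donor_only)

  # a dual loss before the injection cannot be transfer
  pre <- mk(noise(c(base_d[1:5], rep(0, n - 5))),
            noise(c(base_a[1:5], rep(0, n - 5))))
  expect_equal(classify_events(pre, 10, 1)$class, "donor_photobleach")
})

test_that("classification accuracy on labelled traces exceeds 95 percent", {
  sim <- simulate_traces(fret_presets("thioester_reaction"), 800, seed = 17)
  ev <- classify_events(sim$traces, injection_frame = 20, frame_interval = 1)
  expected <- expected_class(sim$truth)
  expect_gt(mean(ev$class == expected), 0.95)
  expect_lt(mean(ev$class == "ambiguous"), 0.02)
})

test_that("transfer calls never show post-event FRET recovery", {
  sim <- simulate_traces(fret_presets("thioester_reaction"), 200, seed = 23)
  ev <- classify_events(sim$traces, injection_frame = 20, frame_interval = 1)
  calls <- ev[ev$class == "transfer_FRET", ]
  for (i in seq_len(nrow(calls))) {
    tr <- sim$traces[sim$traces$molecule_id == calls$molecule_id[i], ]
    post <- tr$frame >= calls$event_frame[i] + 1
    tot <- tr$I_D[post] + 0.88 * tr$I_A[post]
    # no sustained return of signal after the transfer frame
    r <- rle(tot > 200)
    expect_false(any(r$values & r$lengths >= 3))
  }
})

test_that("reacted fractions are reported split and combined", {
  ev <- tibble::tibble(
    molecule_id = 1:100,
    class = c(rep("transfer_FRET", 50), rep("transfer_donor_only", 10),
              rep("unreacted", 40)),
    event_frame = NA, dwell_s = NA, initial_state = NA, donor_only = FALSE)
  rf <- reacted_fractions(ev)
  expect_equal(rf$percent[rf$class == "transfer_FRET"], 50)
  expect_equal(rf$percent[rf$class == "transfer_combined"], 60)
  all_un <- dplyr::mutate(ev, class = "unreacted")
  rfu <- reacted_fractions(all_un)
  expect_equal(rfu$percent[rfu$class == "unreacted"], 100)
  expect_equal(rfu$percent[rfu$class == "transfer_combined"], 0)
})

test_that("dwell-time fits recover exponential rates", {
  set.seed(50)
  d <- rexp(1000, 0.05)
  fit <- fit_dwell_times(d, model = "mono")
  expect_lt(abs(fit$rates - 0.05), 2 * fit$rate_se)
  # the unbinned MLE cross-check agrees with the binned fit
  expect_equal(fit$mle_rate, 1 / mean(d))
  expect_lt(abs(fit$rates - fit$mle_rate) / fit$mle_rate, 0.15)

  # AIC selects the biexponential on a genuine two-rate mixture
  d2 <- c(rexp(1000, 0.2), rexp(1000, 0.01))
  fit2 <- fit_dwell_times(d2, model = "auto")
  expect_equal(fit2$model, "bi")
  expect_equal(sort(fit2$rates), c(0.01, 0.2), tolerance = 0.5)

  # degenerate identical dwells: k = 1 / mean with a warning
  expect_warning(fit3 <- fit_dwell_times(rep(10, 50)), "identical")
  expect_equal(fit3$rates, 0.1)
  expect_error(fit_dwell_times(rexp(5, 1)), "at least 10")
})

test_that("per-state rates separate fast and slow reacting states", {
  cfg <- sim_config(noise_sigma = 40, donor_only_fraction = 0,
                    dynamic_fraction = 0, frame_interval = 1, n_frames = 600,
                    injection_frame = 10, bleach_rate_donor = 1e-4,
                    bleach_rate_acceptor = 1e-4,
                    state_occupancies = c(0.5, 0, 0.5),
                    reaction_rate_high = 0.1, reaction_rate_low = 0.01)
  sim <- simulate_traces(cfg, 400, seed = 31)
  fr <- compute_fret(sim$traces)
  fit <- fit_fret_states(fret_samples(dplyr::filter(fr, frame <= 10)),
                         k = 1:3)
  expect_equal(fit$k, 2)   # only the open and closed states are populated
  ev <- classify_events(sim$traces, injection_frame = 10, frame_interval = 1,
                        fit = fit)
  rates <- per_state_reaction_rates(ev, n_states = 2)
  hi <- rates$rate_median[2]
  lo <- rates$rate_median[1]
  expect_gt(hi, lo)
  expect_gt(hi / lo, 5)
  expect_lt(hi / lo, 20)

  # degenerate groups: a single event gives collapsed quartiles, an empty
  # state is reported with n = 0 rather than dropped
  ev1 <- tibble::tibble(molecule_id = 1:3, class = "transfer_FRET",
                        event_frame = c(20, 30, 40), dwell_s = c(10, 20, 30),
                        initial_state = c(3, 3, 1), donor_only = FALSE)
  r1 <- per_state_reaction_rates(ev1, n_states = 3)
  expect_equal(r1$n, c(1L, 0L, 2L))
  expect_equal(r1$rate_median[1], 1 / 30)
  expect_equal(r1$rate_q1[1], r1$rate_q3[1])
  expect_equal(r1$rate_median[3], mean(c(1 / 10, 1 / 20)))
  expect_true(is.na(r1$rate_median[2]))
})

test_that("interconversion flags only genuinely dynamic molecules", {
  cfg <- quiet_config(n_frames = 200, dynamic_fraction = 0.5,
                      interconversion_rate = 0.05)
  sim <- simulate_traces(cfg, 60, seed = 19)
  fr <- compute_fret(sim$traces)
  fit <- structure(list(k = 3, means = c(0.36, 0.57, 0.71),
                        sds = rep(0.03, 3), weights = rep(1 / 3, 3)),
                   class = "fret_mixture")
  tw <- detect_interconversion(assign_states(fr, fit))
  # the minimum-dwell rule intentionally ignores sub-threshold excursions,
  # so compare only molecules whose true dwells all last >= 5 frames
  resolvable <- vapply(sim$truth$state_path, function(p) {
    all(rle(p)$lengths >= 5)
  }, TRUE)
  truth_dyn <- sim$truth$n_transitions > 0
  expect_equal(tw$molecules$dynamic[resolvable], truth_dyn[resolvable])
  expect_equal(tw$molecules$n_transitions[resolvable],
               sim$truth$n_transitions[resolvable])
  expect_gt(sum(resolvable), 40)
})

test_that("cumulative intensity reflects the reaction time course", {
  # one constant molecule: the curve is that trace
  tr <- tibble::tibble(molecule_id = 1, frame = 1:20, time_s = 0:19,
                       I_D = 400, I_A = 600)
  ci <- cumulative_intensity(tr)
  expect_equal(ci$total, rep(1000, 20))

  sim <- simulate_traces(fret_presets("thioester_reaction"), 150, seed = 13)
  ci2 <- cumulative_intensity(sim$traces, normalize = TRUE,
                              injection_frame = 20)
  # total intensity decays substantially after the injection
  expect_lt(mean(ci2$total[250:320]), 0.5)
  # and the pre-injection baseline sits at 1 by construction
  expect_equal(mean(ci2$total[1:20]), 1, tolerance = 1e-9)

  simU <- simulate_traces(fret_presets("thioester_UEV_only"), 150, seed = 13)
  ciU <- cumulative_intensity(simU$traces, normalize = TRUE,
                              injection_frame = 20)
  expect_gt(mean(ciU$total[250:320]), mean(ci2$total[250:320]) + 0.2)
})
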