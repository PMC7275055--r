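test_that("efficiency formula matches hand arithmetic", {
  tr <- tibble::tibble(molecule_id = 1, frame = 1:3,
                       I_D = c(100, 0, 50), I_A = c(0, 100, 50))
  e <- compute_fret(tr, alpha = 0.88)$E_fret
  expect_equal(e[1], 0)                      # no acceptor signal
  expect_equal(e[2], 1 / 0.88)               # donor fully quenched, raw ratio
  expect_equal(e[3], 50 / 94)                # 50 / (50 + 0.88 * 50)
  ec <- compute_fret(tr, alpha = 0.88, clamp = TRUE)$E_fret
  expect_equal(ec[2], 1)
})

test_that("efficiency is scale-invariant and masks non-positive totals", {
  set.seed(1)
  tr <- tibble::tibble(molecule_id = 1, frame = 1:50,
                       I_D = runif(50, 100, 800), I_A = runif(50, 100, 800))
  e1 <- compute_fret(tr)$E_fret
  tr2 <- dplyr::mutate(tr, I_D = I_D * 7.3, I_A = I_A * 7.3)
  expect_equal(compute_fret(tr2)$E_fret, e1, tolerance = 1e-12)

  bad <- tibble::tibble(molecule_id = 1, frame = 1:2,
                        I_D = c(-50, 100), I_A = c(10, 100))
  fr <- compute_fret(bad)
  expect_false(fr$valid[1])
  expect_true(is.na(fr$E_fret[1]))
  allbad <- tibble::tibble(molecule_id = 5, frame = 1:2,
                           I_D = c(-10, -10), I_A = c(0, 0))
  expect_warning(compute_fret(allbad), "no valid frames")
})

test_that("Forster relation and its inverse behave correctly", {
  expect_equal(distance_to_efficiency(60, R0 = 60), 0.5)
  expect_equal(distance_to_efficiency(0), 1)
  expect_equal(distance_to_efficiency(120, R0 = 60), 1 / 65)
  expect_error(distance_to_efficiency(-5), "non-negative")
  # monotone decreasing in r
  r <- seq(10, 120, by = 5)
  expect_true(all(diff(distance_to_efficiency(r)) < 0))
  # inverse composes to identity
  e <- seq(0.01, 0.99, by = 0.01)
  expect_equal(distance_to_efficiency(efficiency_to_distance(e)), e,
               tolerance = 1e-9)
})

test_that("population samples average the first ten valid frames", {
  sim <- simulate_traces(single_state_config(0.57, n_frames = 30), 4)
  fr <- compute_fret(sim$traces)
  s <- fret_samples(fr, n_init_frames = 10)
  expect_equal(nrow(s), 4)
  expect_equal(s$E_mean, rep(0.57, 4), tolerance = 1e-12)
  expect_true(all(s$n_frames_used == 10))
  # short traces fall back to all available valid frames
  short <- compute_fret(dplyr::filter(sim$traces, frame <= 4))
  s4 <- fret_samples(short, n_init_frames = 10)
  expect_true(all(s4$n_frames_used == 4))
  # below the minimum the molecule is dropped
  tiny <- compute_fret(dplyr::filter(sim$traces, frame <= 2))
  expect_equal(nrow(fret_samples(tiny)), 0)
})

test_that("population histograms integrate to exactly one", {
  set.seed(4)
  for (x in list(rnorm(500, 0.5, 0.1), runif(37), c(rep(0.2, 50), rep(0.8, 50)))) {
    h <- fret_histogram(x)
    expect_equal(sum(h$density * (h$bin_right - h$bin_left)), 1,
                 tolerance = 1e-9)
  }
  # noise-free single state: all mass in the bin containing the state mean
  h1 <- fret_histogram(rep(0.5, 100))
  expect_equal(sum(h1$count > 0), 1)
  expect_lt(abs(h1$bin_mid[h1$count > 0] - 0.5), 0.011)
  # two equal states split the mass in half
  h2 <- fret_histogram(c(rep(0.2, 50), rep(0.8, 50)))
  bw <- h2$bin_right[1] - h2$bin_left[1]
  expect_equal(sort(h2$density[h2$count > 0] * bw), c(0.5, 0.5))
  expect_error(fret_histogram(numeric(0)), "no valid")
})

test_that("windowed histograms track population changes over time", {
  # static population: every window identical (noise-free)
  sim <- simulate_traces(quiet_config(n_frames = 600), 30)
  fr <- compute_fret(sim$traces)
  wh <- windowed_histograms(fr, window_s = 15)
  m <- attr(wh, "matrix")
  expect_equal(nrow(m), 4)
  for (w in 2:4) expect_equal(m[w, ], m[1, ], tolerance = 1e-9)
  expect_error(windowed_histograms(fr, window_s = 0.01), "shorter than one frame")

  # reacting high state: high-FRET column mass decays, low/mid stay level
  cfg <- sim_config(noise_sigma = 0, donor_only_fraction = 0,
                    dynamic_fraction = 0, bleach_rate_donor = 0,
                    bleach_rate_acceptor = 0, frame_interval = 1,
                    n_frames = 90, injection_frame = 5,
                    reaction_rate_high = 0.05)
  simr <- simulate_traces(cfg, 400, seed = 6)
  frr <- compute_fret(simr$traces)
  ev <- classify_events(simr$traces, injection_frame = 5, frame_interval = 1)
  whr <- windowed_histograms(mask_after_events(frr, ev), window_s = 15,
                             normalize = "count")
  mr <- attr(whr, "matrix")
  bins <- as.numeric(colnames(mr))
  high_mass <- rowSums(mr[, abs(bins - 0.71) < 0.05])
  low_mass <- rowSums(mr[, abs(bins - 0.36) < 0.05])
  expect_lt(high_mass[6], 0.2 * high_mass[1])
  expect_gt(min(low_mass) / max(low_mass), 0.9)
})

test_that("empty windows are flagged rather than erroring", {
  tr <- tibble::tibble(molecule_id = 1, frame = 1:40, time_s = 0:39,
                       I_D = 500, I_A = 500)
  fr <- compute_fret(tr)
  fr$valid[31:40] <- FALSE     # everyone reacted in the last window
  wh <- windowed_histograms(fr, window_s = 10)
  last <- dplyr::filter(wh, window == 4)
  expect_true(all(last$n_frames == 0))
  expect_true(all(is.na(last$density)))
})
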