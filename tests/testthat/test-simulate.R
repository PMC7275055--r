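test_that("noise-free traces round-trip exactly through the efficiency formula", {
  sim <- simulate_traces(single_state_config(0.71), 5)
  fr <- compute_fret(sim$traces, alpha = 0.88)
  expect_equal(fr$E_fret, rep(0.71, nrow(fr)), tolerance = 1e-12)
  # and for a three-state config every frame matches its ground-truth state
  cfg <- quiet_config(n_frames = 40)
  sim3 <- simulate_traces(cfg, 20)
  fr3 <- compute_fret(sim3$traces)
  truth_e <- unlist(lapply(sim3$truth$state_path, function(p) cfg$state_means[p]))
  expect_equal(fr3$E_fret, truth_e, tolerance = 1e-12)
})

test_that("static molecules never change state", {
  sim <- simulate_traces(quiet_config(dynamic_fraction = 0, n_frames = 100), 50)
  expect_true(all(sim$truth$n_transitions == 0))
  expect_true(all(vapply(sim$truth$state_path,
                         function(p) length(unique(p)) == 1, TRUE)))
})

test_that("photobleach times follow the configured exponential", {
  cfg <- sim_config(noise_sigma = 0, donor_only_fraction = 0,
                    bleach_rate_donor = 0, bleach_rate_acceptor = 0.02,
                    dynamic_fraction = 0, frame_interval = 1,
                    n_frames = 600)
  sim <- simulate_traces(cfg, 2000, seed = 42)
  tb <- sim$truth$event_time[sim$truth$event_kind == "acceptor_bleach"]
  # mean of a rate-0.02 exponential is 50 s; censoring at 600 s is negligible
  se <- 50 / sqrt(length(tb))
  expect_lt(abs(mean(tb) - 50), 2 * se)
  # and the empirical distribution matches the exponential itself
  ks <- suppressWarnings(stats::ks.test(tb, "pexp", 0.02))
  expect_gt(ks$p.value, 0.01)
})

test_that("reaction traces honour the injection frame and transfer semantics", {
  cfg <- sim_config(noise_sigma = 0, donor_only_fraction = 0,
                    dynamic_fraction = 0, frame_interval = 1, n_frames = 200,
                    injection_frame = 5, bleach_rate_donor = 1e-3,
                    bleach_rate_acceptor = 1e-3,
                    reaction_rate_high = 0.5, reaction_rate_mid = 0.5,
                    reaction_rate_low = 0.5)
  sim <- simulate_traces(cfg, 300, seed = 2)
  tr <- sim$truth[sim$truth$event_kind == "transfer", ]
  # no transfer before the injection completes at 5 s
  expect_true(all(tr$event_time > 5))
  # transfer is near-certain when it outpaces bleaching: surviving the
  # 5 s pre-injection window times the competing-rate ratio k_r/(k_r + k_b)
  p_expected <- exp(-2e-3 * 5) * 0.5 / (0.5 + 2e-3)
  expect_gte(mean(sim$truth$event_kind == "transfer"),
             p_expected - 3 * sqrt(p_expected * (1 - p_expected) / 300))
  expect_gte(p_expected, 0.95)
  # both channels drop to background in the transfer frame, with no recovery
  for (id in head(tr$molecule_id, 10)) {
    t1 <- sim$traces[sim$traces$molecule_id == id, ]
    ef <- tr$event_frame[tr$molecule_id == id]
    expect_true(all(t1$I_D[ef:200] == 0))
    expect_true(all(t1$I_A[ef:200] == 0))
  }
})

test_that("zero reaction rates produce no transfer events", {
  cfg <- sim_config(frame_interval = 1, n_frames = 100, injection_frame = 10)
  sim <- simulate_traces(cfg, 100, seed = 9)
  expect_false(any(sim$truth$event_kind == "transfer"))
})

test_that("donor-only molecules appear at the configured fraction", {
  cfg <- sim_config(donor_only_fraction = 0.2, n_frames = 20)
  sim <- simulate_traces(cfg, 1000, seed = 7)
  expect_lt(abs(mean(sim$truth$donor_only) - 0.2), 0.03)
  # their acceptor channel is background throughout
  ids <- sim$truth$molecule_id[sim$truth$donor_only]
  acc <- sim$traces$I_A[sim$traces$molecule_id %in% ids]
  expect_lt(max(abs(acc)), 5 * sim$config$noise_sigma)
})

test_that("acceptor bleaching produces donor recovery", {
  cfg <- sim_config(noise_sigma = 0, donor_only_fraction = 0,
                    bleach_rate_donor = 0, bleach_rate_acceptor = 0.05,
                    dynamic_fraction = 0, frame_interval = 1, n_frames = 100)
  sim <- simulate_traces(cfg, 50, seed = 3)
  ab <- sim$truth[sim$truth$event_kind == "acceptor_bleach", ]
  expect_gt(nrow(ab), 0)
  for (i in seq_len(min(5, nrow(ab)))) {
    t1 <- sim$traces[sim$traces$molecule_id == ab$molecule_id[i], ]
    ef <- ab$event_frame[i]
    expect_true(all(t1$I_A[ef:100] == 0))
    expect_true(all(t1$I_D[ef:100] == cfg$total_intensity))
  }
})

test_that("simulation is deterministic and seed-derived per molecule", {
  cfg <- sim_config(n_frames = 30)
  a <- simulate_traces(cfg, 20, seed = 11)
  b <- simulate_traces(cfg, 20, seed = 11)
  expect_identical(a$traces, b$traces)
  expect_identical(a$truth, b$truth)
  c <- simulate_traces(cfg, 20, seed = 12)
  expect_false(identical(a$traces, c$traces))
  # single-molecule dataset is valid
  expect_equal(nrow(simulate_traces(cfg, 1)$truth), 1)
  expect_error(simulate_traces(cfg, 0), "n_molecules")
})

test_that("initial states follow the configured occupancies", {
  cfg <- sim_config(state_occupancies = c(0.3, 0.3, 0.4), n_frames = 5)
  sim <- simulate_traces(cfg, 3000, seed = 21)
  counts <- tabulate(sim$truth$initial_state, 3)
  expected <- 3000 * c(0.3, 0.3, 0.4)
  sds <- sqrt(3000 * c(0.3, 0.3, 0.4) * c(0.7, 0.7, 0.6))
  expect_true(all(abs(counts - expected) < 3 * sds))
})
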