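# Generative session simulator: determinism, closed-form means,
# holography routing, spike trains and pupil traces.

test_that("identical seed and config give bit-identical sessions", {
  nt <- make_neurons(n = 30, seed = 5,
                     n_ic_encoders = c(IC1 = 2, IC2 = 2),
                     n_segment = c(BR = 2, BL = 2, TL = 2, TR = 2))
  tt <- make_trial_table(c(I_C1 = 10, L_C1 = 10, blank_circles = 5),
                         seed = 5)
  a <- simulate_population(nt, fx_set, tt, seed = 9)
  b <- simulate_population(nt, fx_set, tt, seed = 9)
  expect_identical(a$responses, b$responses)
  expect_identical(a$drives, b$drives)
  c <- simulate_population(nt, fx_set, tt, seed = 10)
  expect_false(identical(a$responses, c$responses))
})

test_that("planted emergent means are recovered at the closed-form rate", {
  # noiseless planted IC1 neuron with a gap-confined RF: the emergent
  # amplitude appears exactly as the I_C1 - L_C1 and I_C1 - I_C2 drive
  # difference
  nt <- make_neurons(n = 12, seed = 3, n_ic_encoders = c(IC1 = 3, IC2 = 0),
                     n_segment = c(BR = 0, BL = 0, TL = 0, TR = 0),
                     emergent_amp = 3)
  tt <- make_trial_table(c(I_C1 = 60, L_C1 = 60, I_C2 = 60,
                           blank_circles = 30), seed = 3)
  ses <- simulate_population(nt, fx_set, tt, seed = 3)
  ic <- which(nt$emergent_class == "IC1")
  dr <- ses$drives
  expect_equal(unname(dr["I_C1", ic] - dr["L_C1", ic]), rep(3, 3),
               tolerance = 0.05)
  expect_equal(unname(dr["I_C1", ic] - dr["I_C2", ic]), rep(3, 3),
               tolerance = 0.05)
  # empirical trial means recover the planted difference within 3 sigma/sqrt(n)
  y <- ses$trials$stimulus
  m1 <- colMeans(ses$responses[y == "I_C1", ic, drop = FALSE])
  m2 <- colMeans(ses$responses[y == "L_C1", ic, drop = FALSE])
  expect_true(all(abs((m1 - m2) - 3) < 3 * sqrt(2 / 60) * 3))
  # blank trials fluctuate around baseline
  mb <- colMeans(ses$responses[y == "blank_circles", , drop = FALSE])
  expect_true(all(abs(mb - nt$baseline) < 4 / sqrt(30) + 0.2))
})

test_that("a neuron seeing only the shared inducer ignores the recombination", {
  # sigma = 0, c = 0: responses to I_C1 and L_C1 are identical for a
  # neuron whose RF covers only the BR inducer (shared by both images)
  nt <- make_neurons(n = 4, seed = 7,
                     n_ic_encoders = c(IC1 = 0, IC2 = 0),
                     n_segment = c(BR = 2, BL = 0, TL = 0, TR = 0),
                     noise_sd = 0)
  tt <- make_trial_table(c(I_C1 = 5, L_C1 = 5), seed = 7)
  ses <- simulate_population(nt, fx_set, tt, seed = 7, gain_noise_sd = 0)
  br <- which(nt$segment_class == "BR")
  y <- ses$trials$stimulus
  # without noise every trial response equals the deterministic drive,
  # and the drive is image-independent across the recombination
  for (i in br) {
    expect_equal(unique(ses$responses[y == "I_C1", i]),
                 unique(ses$responses[y == "L_C1", i]), tolerance = 1e-3)
  }
  expect_equal(unname(ses$drives["I_C1", br]),
               unname(ses$drives["L_C1", br]), tolerance = 1e-3)
})

test_that("out-of-canvas receptive fields warn and contribute no drive", {
  nt <- make_neurons(n = 2, seed = 1,
                     n_ic_encoders = c(IC1 = 0, IC2 = 0),
                     n_segment = c(BR = 0, BL = 0, TL = 0, TR = 0))
  nt$rf_x_deg[1] <- 500
  tt <- make_trial_table(c(I_C1 = 3), seed = 1)
  expect_warning(ses <- simulate_population(nt, fx_set, tt, seed = 1),
                 "outside canvas")
  expect_equal(unname(ses$drives["I_C1", 1]), nt$baseline[1])
})

test_that("holography routing matches its closed-form expectations", {
  ses <- fx$planted_session
  nt <- ses$neurons
  ens <- list(IC1_encoders = nt$id[nt$emergent_class == "IC1"])
  plan <- holography_plan(ens, n_reps = 40, direct_drive = 5)
  # W = 0, FF = 0, s > 0: mean non-target response is -s
  conn0 <- make_connectivity(ses, like_to_like = FALSE, suppression = 0.5)
  h0 <- simulate_holography(ses, conn0, plan, seed = 2, noise_sd = 0)
  tgt <- match(ens[[1]], nt$id)
  expect_equal(unname(colMeans(h0$responses[, -tgt])),
               rep(-0.5, ncol(h0$responses) - length(tgt)),
               tolerance = 1e-12)
  expect_equal(unname(colMeans(h0$responses[, tgt])),
               rep(5 - 0.5, length(tgt)), tolerance = 1e-12)
  # like-to-like recurrence: responsive non-targets gain the aggregate
  # drive recurrent_gain * d over the suppressed baseline
  conn1 <- make_connectivity(ses, like_to_like = TRUE,
                             recurrent_gain = 0.4, suppression = 0.5)
  h1 <- simulate_holography(ses, conn1, plan, seed = 2, noise_sd = 0)
  resp <- icdecode:::responsive_to(ses, "I_C1") & nt$emergent_class != "IC1"
  gain_v <- colMeans(h1$responses) - colMeans(h0$responses)
  expect_equal(unname(gain_v[resp]), rep(0.4 * 5, sum(resp)),
               tolerance = 1e-9)
  nonresp_nontgt <- !resp & !(seq_len(nrow(nt)) %in% tgt)
  expect_equal(unname(gain_v[nonresp_nontgt]),
               rep(0, sum(nonresp_nontgt)), tolerance = 1e-9)
  expect_error(simulate_holography(ses, conn0,
                                   holography_plan(list(bad = 9999)),
                                   seed = 1),
               "unknown neuron ids")
})

test_that("feedforward weights drive only higher-area responsive neurons", {
  nt <- make_neurons(n = 80, seed = 13, gain = 2,
                     n_ic_encoders = c(IC1 = 5, IC2 = 5),
                     n_segment = c(BR = 5, BL = 5, TL = 5, TR = 5),
                     area_counts = c(V1 = 60, LM = 20))
  tt <- make_trial_table(c(I_C1 = 30, L_C1 = 30, L_C2 = 30, I_C2 = 30,
                           blank_circles = 20), seed = 13)
  ses <- simulate_population(nt, fx_set, tt, seed = 13)
  ens <- list(seg_BR_TL = nt$id[nt$segment_class %in% c("BR", "TL")])
  conn <- make_connectivity(ses, like_to_like = FALSE, feedforward = TRUE,
                            ff_gain = 0.4, suppression = 0.5)
  h <- simulate_holography(ses, conn, holography_plan(ens, n_reps = 20),
                           seed = 13, noise_sd = 0)
  hva_resp <- nt$area != "V1" & icdecode:::responsive_to(ses, "I_C1")
  v1_nontgt <- nt$area == "V1" & !(nt$id %in% ens[[1]])
  expect_true(all(colMeans(h$responses[, hva_resp, drop = FALSE]) > 0))
  expect_equal(unname(colMeans(h$responses[, v1_nontgt, drop = FALSE])),
               rep(-0.5, sum(v1_nontgt)), tolerance = 1e-12)
})

test_that("spike trains honor rates, synapses and comodulation", {
  st <- simulate_spike_trains(c(10, 0.5), NULL, duration_s = 200, seed = 4)
  expect_equal(length(st$times[[1]]) / 200, 10, tolerance = 0.1)
  expect_equal(length(st$times[[2]]) / 200, 0.5, tolerance = 0.4)
  expect_true(all(diff(st$times[[1]]) >= 0))
  expect_true(all(st$times[[1]] >= 0 & st$times[[1]] < 200))
  # planted synapse inserts ~transfer_p extra spikes at the right lag
  st2 <- simulate_spike_trains(
    c(10, 10), data.frame(pre = 1, post = 2, lag_ms = 4, transfer_p = 0.5),
    duration_s = 400, seed = 5)
  n_extra <- length(st2$times[[2]]) - 10 * 400
  expect_equal(n_extra / (10 * 400), 0.5, tolerance = 0.15)
  # out-of-window lag warns
  expect_warning(simulate_spike_trains(
    c(5, 5), data.frame(pre = 1, post = 2, lag_ms = 15, transfer_p = 0.2),
    duration_s = 60, seed = 6), "undetectable")
  # sinusoidal comodulation preserves the mean rate
  st3 <- simulate_spike_trains(c(20), NULL, duration_s = 300,
                               comodulation = list(freq_hz = 2, depth = 0.8),
                               seed = 7)
  expect_equal(length(st3$times[[1]]) / 300, 20, tolerance = 0.1)
})

test_that("pupil traces are stationary except for planted excursions", {
  tt <- make_trial_table(c(I_C1 = 20), seed = 8, stim_s = 1, iti_s = 0)
  pup <- simulate_pupil(tt, seed = 8)
  expect_true(all(fixed_gaze_filter(pup, tt, 8)))
  pup2 <- simulate_pupil(tt, excursion = list(trials = 7, amp_deg = 10),
                         seed = 8)
  keep <- fixed_gaze_filter(pup2, tt, 8)
  expect_false(keep[7])
  expect_true(all(keep[-7]))
  # rejected fraction tracks the excursion fraction
  exc <- c(2, 5, 11, 17)
  pup3 <- simulate_pupil(tt, excursion = list(trials = exc, amp_deg = 12),
                         seed = 9)
  expect_equal(mean(!fixed_gaze_filter(pup3, tt, 8)), length(exc) / 20)
})
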