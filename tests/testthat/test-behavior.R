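test_that("pitch-error classification follows the added/deleted-tone rule", {
  t0 <- perfect_trial()
  expect_equal(classify_pitch_errors(t0, melody)$status, "clean")
  expect_equal(classify_pitch_errors(t0, melody)$matched_event_index, 1:32)

  # one deleted tone: length 31 forces an indel -> excluded
  expect_equal(classify_pitch_errors(t0[-5, ], melody)$status, "excluded")

  # one added tone -> excluded
  ins <- rbind(t0[1:7, ], t0[7, ], t0[8:32, ])
  expect_equal(classify_pitch_errors(ins, melody)$status, "excluded")

  # substituted pitch, same length -> retained, pairing undisturbed
  sub <- t0
  sub$played_pitch[5] <- sub$played_pitch[5] + 2
  cls <- classify_pitch_errors(sub, melody)
  expect_equal(cls$status, "substitution_only")
  expect_equal(cls$matched_event_index, 1:32)

  empty <- classify_pitch_errors(t0[0, ], melody)
  expect_equal(empty$status, "excluded")
  expect_equal(empty$reason, "empty")
})

test_that("filter decisions match injected ground-truth labels exactly", {
  tc <- timing_sim_config(n_trials = 6, n_repetitions = 4, seed = 11)
  solo <- simulate_solo_timing(melody, tc)
  bad <- inject_pitch_errors(solo, 0.3, seed = 11)
  filt <- filter_pitch_errors(bad, melody)
  s <- filt$summary
  expect_equal(s$status == "excluded", s$injected_error != "none")
  expect_true(all(filt$trials$injected_error == "none"))
})

test_that("quarter-level IOIs interpolate half notes and drop off-beat eighths", {
  tr <- with_match(perfect_trial(period_ms = 500))
  io <- quarter_level_iois(tr, melody)
  expect_equal(io$values, rep(500, 30))   # 31 beat onsets incl. midpoints
  expect_equal(io$rate_hz, 2.0)

  tr2 <- with_match(perfect_trial(period_ms = 480))
  io2 <- quarter_level_iois(tr2, melody)
  expect_equal(io2$mean_ioi_ms, 480)
  expect_equal(io2$n, 30L)

  one <- perfect_trial()[1, ]
  one$matched_event_index <- 1L
  expect_error(quarter_level_iois(one, melody), "too short")
})

test_that("a hand-built half-note/eighth-pair sequence splits as computed by hand", {
  # 8 quarters @480, half @960 split at midpoint, eighth pair @240+240,
  # final quarter: eleven 480 ms beat intervals
  onsets <- c(seq(0, 7 * 480, by = 480),            # 8 quarters
              8 * 480,                              # half (spans 2 beats)
              10 * 480, 10 * 480 + 240,             # eighth pair
              11 * 480)                             # final quarter
  toy <- tibble::tibble(
    onset_ms = onsets,
    matched_event_index = 1:12
  )
  toy_melody <- tibble::tibble(
    event = 1:12,
    pitch = rep(60, 12),
    beat_value = c(rep(1, 8), 2, 0.5, 0.5, 1),
    is_on_beat = c(rep(TRUE, 10), FALSE, TRUE),
    beat = cumsum(c(0, c(rep(1, 8), 2, 0.5, 0.5)))
  )
  io <- quarter_level_iois(toy, toy_melody)
  expect_equal(io$values, rep(480, 11))
  expect_equal(io$mean_ioi_ms, 480)
})

test_that("asynchronies are normalized signed/absolute proportions of the duet IOI", {
  L <- with_match(perfect_trial(period_ms = 500, performer = "L"))
  L$role <- "Leader"
  F_ <- with_match(perfect_trial(period_ms = 500, performer = "F"))
  F_$role <- "Follower"

  same <- duet_asynchronies(L, F_, melody)
  expect_equal(same$signed_mean, 0)
  expect_equal(same$absolute_mean, 0)

  late <- F_
  late$onset_ms <- late$onset_ms + 10   # follower 10 ms late on every tone
  res <- duet_asynchronies(L, late, melody)
  expect_equal(res$signed_mean, -0.02, tolerance = 1e-9)
  expect_equal(res$absolute_mean, 0.02, tolerance = 1e-9)
})

test_that("swapping roles negates signed and preserves absolute asynchrony", {
  tc <- timing_sim_config(T_leader = 520, T_follower = 480, alpha = 0.5,
                          sigma_timekeeper = 6, sigma_motor = 2,
                          n_trials = 1, n_repetitions = 3, seed = 31)
  d <- simulate_duet_timing(melody, tc)
  filt <- filter_pitch_errors(rbind(d$leader, d$follower), melody)
  kl <- filt$trials[filt$trials$role == "Leader", ]
  kf <- filt$trials[filt$trials$role == "Follower", ]
  ab <- duet_asynchronies(kl, kf, melody)
  ba <- duet_asynchronies(kf, kl, melody)
  expect_equal(ba$signed_mean, -ab$signed_mean, tolerance = 1e-12)
  expect_equal(ba$absolute_mean, ab$absolute_mean, tolerance = 1e-12)
  expect_gte(ab$absolute_mean, abs(ab$signed_mean))
})

test_that("normalized asynchronies are invariant to uniform time scaling", {
  tc <- timing_sim_config(T_leader = 510, T_follower = 490, alpha = 0.6,
                          sigma_timekeeper = 5, sigma_motor = 2,
                          n_trials = 1, n_repetitions = 2, seed = 13)
  d <- simulate_duet_timing(melody, tc)
  filt <- filter_pitch_errors(rbind(d$leader, d$follower), melody)
  kl <- filt$trials[filt$trials$role == "Leader", ]
  kf <- filt$trials[filt$trials$role == "Follower", ]
  base <- duet_asynchronies(kl, kf, melody)
  for (c_scale in c(0.5, 2)) {
    kl2 <- kl; kf2 <- kf
    kl2$onset_ms <- kl2$onset_ms * c_scale
    kf2$onset_ms <- kf2$onset_ms * c_scale
    scaled <- duet_asynchronies(kl2, kf2, melody)
    expect_equal(scaled$signed_mean, base$signed_mean, tolerance = 1e-12)
    expect_equal(scaled$absolute_mean, base$absolute_mean, tolerance = 1e-12)
    io <- quarter_level_iois(kl2[kl2$repetition == 1, ], melody)
    io0 <- quarter_level_iois(kl[kl$repetition == 1, ], melody)
    expect_equal(io$rate_hz, io0$rate_hz / c_scale, tolerance = 1e-12)
  }
})

test_that("Hz conversion round-trips the mean IOI", {
  for (ioi in c(302, 470, 597)) {
    tr <- with_match(perfect_trial(period_ms = ioi))
    io <- quarter_level_iois(tr, melody)
    expect_equal(1000 / io$rate_hz, io$mean_ioi_ms, tolerance = 1e-9)
  }
})

test_that("detuning-asynchrony rank correlation handles monotone and degenerate input", {
  mono <- tibble::tibble(detuning_ms = c(-30, -10, 5, 22, 40),
                         signed_asynchrony = c(-0.06, -0.02, 0.01, 0.04, 0.09))
  expect_equal(detuning_vs_asynchrony(mono)$rho, 1)
  flip <- mono; flip$signed_asynchrony <- -flip$signed_asynchrony
  expect_equal(detuning_vs_asynchrony(flip)$rho, -1)
  const <- mono; const$detuning_ms <- 0
  expect_error(detuning_vs_asynchrony(const), "constant")
})

test_that("duet-rate regression attributes the tempo to the right partner", {
  set.seed(99)
  leader <- rnorm(12, 2, 0.3); follower <- rnorm(12, 2, 0.3)
  d1 <- tibble::tibble(duet_rate = leader, leader_solo_rate = leader,
                       follower_solo_rate = follower)
  r1 <- suppressWarnings(duet_rate_regression(d1))  # exact fit by construction
  expect_equal(r1$beta_leader, 1, tolerance = 1e-8)
  expect_equal(r1$beta_follower, 0, tolerance = 1e-8)
  expect_equal(r1$r_squared, 1, tolerance = 1e-8)

  d2 <- tibble::tibble(duet_rate = (leader + follower) / 2,
                       leader_solo_rate = leader,
                       follower_solo_rate = follower)
  r2 <- suppressWarnings(duet_rate_regression(d2))
  # y = (L + F)/2 exactly: standardized betas scale with each predictor's SD
  expect_equal(r2$beta_leader * sd(follower), r2$beta_follower * sd(leader),
               tolerance = 1e-6)

  d3 <- tibble::tibble(duet_rate = leader, leader_solo_rate = leader,
                       follower_solo_rate = leader)
  expect_error(duet_rate_regression(d3), "collinear")
})
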