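test_that("Hilbert envelope recovers amplitude of pure and AM tones", {
  fs <- 100; tt <- (0:(60 * fs - 1)) / fs
  x <- cos(2 * pi * 2 * tt)
  env <- hilbert_envelope(x)
  mid <- (5 * fs):(55 * fs)
  expect_lt(max(abs(env[mid] - 1)), 0.02)

  A <- 1 + 0.4 * sin(2 * pi * 0.1 * tt)
  env_am <- hilbert_envelope(A * cos(2 * pi * 2 * tt))
  rmse <- sqrt(mean((env_am[mid] - A[mid])^2)) / mean(A)
  expect_lt(rmse, 0.05)

  expect_equal(hilbert_envelope(rep(0, 1000)), rep(0, 1000))
})

test_that("envelope extraction returns a flat envelope for a pure tone at the duet rate", {
  fs <- 500; f0 <- 2.0
  dur <- 40; n <- dur * fs
  tt <- (0:(n - 1)) / fs
  rec <- eeg_recording(matrix(cos(2 * pi * f0 * tt), 1), fs, "FCz")
  bounds <- tibble::tibble(trial = 1L, repetition = 1L,
                           start_ms = 5000, end_ms = 20000)
  env <- extract_envelope(rec, 1, f0, bounds)
  expect_length(env, 1L)
  s <- env[[1]]$samples
  expect_equal(length(s), 15 * 100)
  expect_lt(max(abs(s - 1)), 0.02)
  expect_error(extract_envelope(rec, 1, 0.5, bounds), "\\[1, 4\\]")
})

test_that("repetitions whose padded window leaves the recording are dropped with a warning", {
  fs <- 500
  rec <- eeg_recording(matrix(rnorm(10 * fs), 1), fs, "Cz")
  bounds <- tibble::tibble(trial = 1L, repetition = 1:2,
                           start_ms = c(3000, 8000), end_ms = c(6000, 9500))
  expect_warning(env <- extract_envelope(rec, 1, 2, bounds), "dropped")
  expect_length(env, 1L)
})

test_that("event resampling maps every repetition onto a 64 m grid", {
  m <- 10L
  anchors <- c(melody$beat * 2 * m, 64 * m)   # already grid-conformal
  n_samp <- 64 * m + 1
  const <- rep(2.5, n_samp)
  out <- event_resample(const, anchors, melody, m)
  expect_length(out, 64 * m)
  expect_equal(out, rep(2.5, 64 * m))

  lin <- seq(0, 1, length.out = n_samp)
  out_lin <- event_resample(lin, anchors, melody, m)
  expect_equal(out_lin, lin[-n_samp], tolerance = 1e-9)   # idempotence on the grid
})

test_that("resampling aligns the same event-locked shape across tempi", {
  shape <- function(beat) 1 + sin(2 * pi * beat / 8)   # function of position
  fs <- 100
  envs <- lapply(c(400, 520), function(period) {
    dur <- 32 * period / 1000
    tt <- seq(0, dur, by = 1 / fs)
    beat <- tt * 1000 / period
    list(samples = shape(beat),
         anchors = c(melody$beat, 32) * period / 1000 * fs)
  })
  m <- grid_density(lapply(envs, `[[`, "anchors"), melody)
  r1 <- event_resample(envs[[1]]$samples, envs[[1]]$anchors, melody, m)
  r2 <- event_resample(envs[[2]]$samples, envs[[2]]$anchors, melody, m)
  expect_gt(cor(r1, r2), 0.99)
})

test_that("grid density is the minimum eighth-equivalent inter-onset count", {
  a1 <- c(melody$beat * 20, 640)        # 10 samples per eighth unit
  a2 <- c(melody$beat * 16, 512)        # 8 per eighth unit
  expect_equal(grid_density(list(a1, a2), melody), 8L)
  a_bad <- c(melody$beat * 6, 192)
  expect_error(grid_density(list(a_bad), melody), "coarse")
})

test_that("AEC machinery: correlations, count-in skipping, Fisher averaging", {
  m <- 8L
  set.seed(7)
  e1 <- lapply(1:4, function(i) rnorm(64 * m))
  trials <- c(1L, 1L, 2L, 2L); reps <- c(1L, 2L, 1L, 2L)
  same <- aec(e1, e1, trials, reps, m)
  expect_equal(same$per_repetition_r, rep(1, 4))
  expect_true(is.finite(same$fisher_z_mean))
  expect_gt(same$r, 0.999)

  # scaling either envelope leaves r unchanged
  e2 <- lapply(e1, function(x) 3.7 * x + 0)
  expect_equal(aec(e1, e2, trials, reps, m)$per_repetition_r, rep(1, 4))

  # first repetition of each trial starts at the 9th event (grid index 16m)
  spiked <- lapply(e1, function(x) x)
  spiked[[1]][1:(16 * m)] <- -e1[[1]][1:(16 * m)]   # corrupt only the count-in
  expect_equal(aec(spiked, e1, trials, reps, m)$per_repetition_r, rep(1, 4))

  # closed-form Fisher average
  half <- lapply(1:4, function(i) rnorm(64 * m))
  res <- aec(half, half, trials, reps, m)
  expect_equal(mean(fisher_z(res$per_repetition_r)), res$fisher_z_mean)
  expect_equal(as.numeric(fisher_z(0.5)), atanh(0.5))
  expect_equal(atanh(0.5), 0.5493, tolerance = 1e-4)
})

test_that("independent envelopes give near-zero mean AEC", {
  m <- 8L
  rs <- sapply(1:20, function(s) {
    set.seed(s)
    eL <- lapply(1:24, function(i) rnorm(64 * m))
    eF <- lapply(1:24, function(i) rnorm(64 * m))
    aec(eL, eF, rep(1:6, each = 4), rep(1:4, 6), m)$r
  })
  expect_gte(mean(abs(rs) < 0.08), 0.95)
  expect_lt(abs(mean(rs)), 0.03)
})

test_that("Fisher transform round-trips and clips perfect correlations", {
  r <- c(-0.999, -0.5, 0, 0.31, 0.999)
  expect_equal(fisher_r(fisher_z(r)), r, tolerance = 1e-12)
  z <- fisher_z(1)
  expect_true(attr(z, "clipped"))
  expect_equal(fisher_r(as.numeric(z)), 0.999999, tolerance = 1e-9)
})

test_that("surrogate re-pairing: exchangeable envelopes give surrogate = observed", {
  m0 <- 12L
  set.seed(41)
  reps <- 3L
  shared_raw <- lapply(seq_len(reps), function(i) abs(rnorm(64 * m0 + 1)) + 1)
  anchors <- c(melody$beat * 2 * m0, 64 * m0)
  payload <- lapply(1:4, function(p) {
    side <- list(raw = shared_raw,
                 anchors = lapply(seq_len(reps), function(i) anchors),
                 trials = rep(1L, reps), repetitions = seq_len(reps))
    list(leader = side, follower = side)
  })
  sur <- surrogate_aecs(payload, melody)
  expect_equal(nrow(sur), 4L)
  expect_equal(sur$n_surrogates, rep(3L, 4))        # n - 1 pairings
  obs <- aec(shared_raw, shared_raw, rep(1L, reps), seq_len(reps), m0)
  expect_equal(sur$surrogate_z_mean, rep(obs$fisher_z_mean, 4), tolerance = 1e-9)
})

test_that("binomial comparison reproduces exact tail probabilities", {
  # 15 of 20 successes
  res <- binomial_comparison(c(rep(1, 15), rep(-1, 5)), rep(0, 20))
  expect_equal(res$k, 15L)
  expect_equal(res$p, 21700 / 1048576, tolerance = 1e-12)
  expect_equal(round(res$p, 2), 0.02)

  # brute-force oracle for k = 10 of 20
  p_brute <- sum(choose(20, 10:20)) / 2^20
  res10 <- binomial_comparison(c(rep(1, 10), rep(-1, 10)), rep(0, 20))
  expect_equal(res10$p, p_brute, tolerance = 1e-12)
  expect_equal(round(res10$p, 3), 0.588)

  expect_equal(binomial_comparison(rep(1, 12), rep(0, 12))$p, 2^-12)
  # ties count as failures
  expect_equal(binomial_comparison(rep(0, 5), rep(0, 5))$k, 0L)
  expect_error(binomial_comparison(numeric(0), numeric(0)), "no pairs")
})
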