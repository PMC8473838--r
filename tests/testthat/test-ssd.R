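# small helper: a recording with a known source mixed into white noise
toy_source_recording <- function(n_ch = 6, dur_s = 90, fs = 250, f0 = 2.5,
                                 noise_sd = 0.05, seed = 1) {
  set.seed(seed)
  n <- dur_s * fs
  tt <- (0:(n - 1)) / fs
  A <- 1 + 0.3 * sin(2 * pi * 0.07 * tt)
  src <- A * cos(2 * pi * f0 * tt)
  topo <- rnorm(n_ch); topo <- topo / sqrt(sum(topo^2))
  X <- outer(topo, src) + matrix(rnorm(n_ch * n, 0, noise_sd), n_ch)
  list(rec = eeg_recording(X, fs, paste0("ch", seq_len(n_ch))),
       src = src, topo = topo)
}

test_that("generalized eigenpairs match an independent solve-based route", {
  set.seed(12)
  for (rep_i in 1:5) {
    A <- matrix(rnorm(9), 3); S <- crossprod(A) + diag(0.1, 3)
    B <- matrix(rnorm(9), 3); N <- crossprod(B) + diag(0.1, 3)
    ge <- duetsync:::gen_eigen(S, N)
    # independent oracle: non-symmetric eigendecomposition of N^{-1} S
    ev_oracle <- sort(Re(eigen(solve(N) %*% S)$values), decreasing = TRUE)
    expect_equal(ge$values, ev_oracle, tolerance = 1e-10)
    # defining property S w = lambda N w
    for (k in 1:3) {
      expect_equal(S %*% ge$vectors[, k],
                   ge$values[k] * N %*% ge$vectors[, k], tolerance = 1e-8)
    }
    # N-orthogonality of distinct components
    G <- t(ge$vectors) %*% N %*% ge$vectors
    expect_equal(G, diag(3), tolerance = 1e-8)
  }
})

test_that("equal band and flank covariances give unit eigenvalues", {
  set.seed(3)
  # broadband white noise: band and flank power differ only by bandwidth;
  # use the analytic S = N case directly on the eigensolver
  S <- N <- crossprod(matrix(rnorm(16), 4)) + diag(0.2, 4)
  ge <- duetsync:::gen_eigen(S, N)
  expect_equal(ge$values, rep(1, 4), tolerance = 1e-10)
})

test_that("SSD recovers a single narrowband source and its topography", {
  toy <- toy_source_recording(seed = 21)
  fit <- fit_ssd(toy$rec, band = c(1.5, 3.5), decimate_to = 50)
  expect_true(all(diff(fit$eigenvalues) <= 1e-9))   # sorted descending
  course <- apply_spatial_filter(toy$rec, fit$filters[, 1])
  expect_gt(abs(cor(course, toy$src)), 0.95)
  cosine <- abs(sum(fit$patterns[, 1] * toy$topo)) /
    sqrt(sum(fit$patterns[, 1]^2) * sum(toy$topo^2))
  expect_gt(cosine, 0.9)
})

test_that("leading eigenvalue approximates the component's band/flank power ratio", {
  # built at the SSD working rate so the ratio uses the same filters
  toy <- toy_source_recording(dur_s = 120, fs = 50, seed = 22)
  fit <- fit_ssd(toy$rec)
  course <- apply_spatial_filter(toy$rec, fit$filters[, 1])
  ratio <- duetsync:::band_flank_ratio(course, toy$rec$fs, fit$band, fit$flanks)
  expect_equal(fit$eigenvalues[1], ratio, tolerance = 0.05)
})

test_that("component time courses are invariant to invertible channel mixing", {
  toy <- toy_source_recording(n_ch = 4, dur_s = 60, seed = 23)
  set.seed(24)
  M <- matrix(rnorm(16), 4) + diag(2, 4)   # well-conditioned mixing
  mixed <- eeg_recording(M %*% toy$rec$data, toy$rec$fs,
                         toy$rec$channel_names)
  c1 <- apply_spatial_filter(toy$rec, fit_ssd(toy$rec)$filters[, 1])
  c2 <- apply_spatial_filter(mixed, fit_ssd(mixed)$filters[, 1])
  expect_gt(abs(cor(c1, c2)), 0.999)
})

test_that("component selection prefers the fronto-central duet-rate source over an alpha distractor", {
  tc <- timing_sim_config(T_leader = 480, T_follower = 480, alpha = 0.5,
                          n_trials = 2, n_repetitions = 2, seed = 61)
  solo <- simulate_solo_timing(melody, tc, period_ms = 480)
  ec <- eeg_sim_config(snr_db = 10, distractor_alpha = TRUE, seed = 62)
  se <- simulate_solo_eeg(solo, ec, melody)
  fit <- fit_ssd(se$recording)
  sel <- select_component(fit, se$recording)
  course <- apply_spatial_filter(se$recording, sel$filter)
  ps <- welch_psd(course[1:4500], spectral_config())
  f_peak <- ps$freq[which.max(ps$power[1, ])]
  expect_lt(abs(f_peak - se$f_source), 0.3)        # duet-rate, not 10 Hz
  # and its pattern is fronto-central
  ridx <- match(c("FC1", "FC2", "Cz", "Fz"), rownames(fit$patterns))
  expect_gt(sum(abs(sel$pattern[ridx])) / sum(abs(sel$pattern)), 0.3)
})

test_that("a global sign flip of the data leaves the selection and its envelope unchanged", {
  # covariance-based filters cannot sense data polarity; the convention
  # (positive mean ROI pattern loading) pins the filter itself, and the
  # component's amplitude envelope - the quantity used downstream - is
  # flip-invariant
  toy <- toy_source_recording(n_ch = 6, dur_s = 60, seed = 25)
  names(toy$topo) <- toy$rec$channel_names
  roi <- toy$rec$channel_names[order(-abs(toy$topo))][1:2]
  flipped <- eeg_recording(-toy$rec$data, toy$rec$fs, toy$rec$channel_names)
  s1 <- select_component(fit_ssd(toy$rec), toy$rec, roi = roi)
  s2 <- select_component(fit_ssd(flipped), flipped, roi = roi)
  expect_equal(s2$index, s1$index)
  expect_equal(s2$filter, s1$filter, tolerance = 1e-6)
  c1 <- apply_spatial_filter(toy$rec, s1$filter)
  c2 <- apply_spatial_filter(flipped, s2$filter)
  expect_equal(hilbert_envelope(c2), hilbert_envelope(c1), tolerance = 1e-6)
})
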