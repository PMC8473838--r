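#' Multichannel EEG recording container
#'
#' @param data channels x samples numeric matrix; rownames are channel names
#' @param fs sampling rate, Hz
#' @param channel_names character vector (defaults to rownames of `data`)
#' @param anchors tibble of event-sample anchors: `trial, repetition,
#'   event_index, sample` (0-based sample indices)
#' @return an object of class `eeg_recording`
#' @export
eeg_recording <- function(data, fs, channel_names = rownames(data),
                          anchors = NULL) {
  stopifnot(is.matrix(data), fs > 0,
            length(channel_names) == nrow(data))
  rownames(data) <- channel_names
  structure(list(data = data, fs = fs, channel_names = channel_names,
                 anchors = anchors),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s), %s anchors\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs,
              if (is.null(x$anchors)) "no" else nrow(x$anchors)))
  invisible(x)
}

#' Default 24-channel 10-20 montage
#'
#' A fixed montage guaranteeing that the fronto-central region of interest
#' (FC1, FC2, Fz, Cz) is always addressable.
#' @return character vector of 24 channel names
#' @export
default_montage <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
    "FC5", "FC1", "FC2", "FC6",
    "T7", "C3", "Cz", "C4", "T8",
    "CP1", "CP2", "P7", "P3", "Pz", "P4", "O1", "O2")
}

#' Fronto-central forward topography for the duet-rate source
#'
#' Weights peak at FC1/FC2 with Fz/Cz close behind, fall off toward
#' neighboring fronto-central sites, and are small elsewhere; normalized to
#' unit norm.
#' @param channel_names montage (default [default_montage()])
#' @return named unit-norm numeric vector
#' @export
frontocentral_topography <- function(channel_names = default_montage()) {
  w <- stats::setNames(rep(0.08, length(channel_names)), channel_names)
  strong <- c(FC1 = 1, FC2 = 1, Fz = 0.85, Cz = 0.85,
              F3 = 0.45, F4 = 0.45, C3 = 0.45, C4 = 0.45,
              FC5 = 0.3, FC6 = 0.3)
  w[names(strong)] <- strong
  w / sqrt(sum(w^2))
}

# occipito-parietal topography for the optional 10 Hz distractor
occipital_topography <- function(channel_names = default_montage()) {
  w <- stats::setNames(rep(0.05, length(channel_names)), channel_names)
  strong <- c(O1 = 1, O2 = 1, Pz = 0.7, P3 = 0.5, P4 = 0.5, P7 = 0.3)
  w[names(strong)] <- strong
  w / sqrt(sum(w^2))
}

#' Configuration for the dual-brain EEG simulator
#'
#' @param fs sampling rate, Hz
#' @param channel_names montage
#' @param topography unit-norm forward weights of the duet-rate source
#' @param rho_envelope target correlation between the partners' source
#'   amplitude envelopes, in `[0, 1]`
#' @param snr_db source-to-background power ratio (dB) within the duet-rate
#'   analysis band at the maximum-topography channel; `-Inf` turns the
#'   source off (noise-only recordings)
#' @param distractor_alpha add a 10 Hz source with an occipito-parietal
#'   topography
#' @param env_cutoff_hz bandwidth of the envelope fluctuation process
#' @param bg_pink_sd,bg_white_sd background 1/f and white sensor noise SDs
#' @param seed integer seed
#' @return a list of class `eeg_sim_config`
#' @export
eeg_sim_config <- function(fs = 500, channel_names = default_montage(),
                           topography = frontocentral_topography(channel_names),
                           rho_envelope = 0.6, snr_db = 5,
                           distractor_alpha = FALSE,
                           env_cutoff_hz = 0.4,
                           bg_pink_sd = 1, bg_white_sd = 0.3,
                           seed = 1L) {
  stopifnot(rho_envelope >= 0, rho_envelope <= 1,
            abs(sum(topography^2) - 1) < 1e-8,
            length(topography) == length(channel_names))
  structure(list(fs = fs, n_channels = length(channel_names),
                 channel_names = channel_names, topography = topography,
                 rho_envelope = rho_envelope, snr_db = snr_db,
                 distractor_alpha = distractor_alpha,
                 env_cutoff_hz = env_cutoff_hz,
                 bg_pink_sd = bg_pink_sd, bg_white_sd = bg_white_sd,
                 seed = seed),
            class = "eeg_sim_config")
}

#' 1/f (pink) noise
#'
#' Spectral-synthesis pink noise: white Gaussian Fourier coefficients scaled
#' by 1/sqrt(f) above a 0.5 Hz corner (flat below), unit variance.
#'
#' @param n number of samples
#' @param fs sampling rate, Hz
#' @return numeric vector of length `n`
#' @export
pink_noise <- function(n, fs) {
  pink_noise_matrix(n, fs, 1)[1, ]
}

# channels x samples pink noise in one multichannel FFT
pink_noise_matrix <- function(n, fs, n_ch) {
  nfft <- stats::nextn(n, factors = 2)   # even, and keeps the FFT O(n log n)
  nh <- nfft / 2 + 1
  f <- seq(0, fs / 2, length.out = nh)
  shape <- 1 / sqrt(pmax(f, 0.5))
  half <- matrix(complex(real = rnorm(nh * n_ch), imaginary = rnorm(nh * n_ch)),
                 nh, n_ch) * shape
  half[1, ] <- 0
  spec <- rbind(half, Conj(half[(nfft / 2):2, , drop = FALSE]))
  x <- Re(stats::mvfft(spec, inverse = TRUE))[seq_len(n), , drop = FALSE]
  t(x) / apply(x, 2, stats::sd)
}

softplus <- function(x) log1p(exp(-abs(x))) + pmax(x, 0)

# standardized slow Gaussian process: lowpass-filtered white noise
slow_process <- function(n, fs, cutoff_hz) {
  bt <- signal::butter(2, cutoff_hz / (fs / 2), type = "low")
  x <- signal::filtfilt(bt, rnorm(n))
  (x - mean(x)) / stats::sd(x)
}

#' Generate a pair of correlated amplitude-envelope processes
#'
#' Two smoothed Gaussian processes are mixed from a shared and a private
#' component as `sqrt(rho) * shared + sqrt(1 - rho) * private`, then mapped
#' to strictly positive amplitudes by a softplus centered well inside its
#' near-linear region (`softplus(2 + z/2)`), which keeps the envelopes
#' smooth and leaves their correlation essentially equal to `rho`.
#'
#' @param n samples
#' @param fs sampling rate, Hz
#' @param rho target correlation in `[0, 1]`
#' @param cutoff_hz fluctuation bandwidth
#' @return a list with positive vectors `a1`, `a2`
#' @export
make_envelope_pair <- function(n, fs, rho, cutoff_hz = 0.4) {
  stopifnot(rho >= 0, rho <= 1)
  shared <- slow_process(n, fs, cutoff_hz)
  z1 <- sqrt(rho) * shared + sqrt(1 - rho) * slow_process(n, fs, cutoff_hz)
  z2 <- sqrt(rho) * shared + sqrt(1 - rho) * slow_process(n, fs, cutoff_hz)
  list(a1 = softplus(2 + z1 / 2), a2 = softplus(2 + z2 / 2))
}

#' Simulate dual-brain EEG for one duet condition
#'
#' Each partner's recording is `topography %o% (A(t) * cos(2*pi*f_duet*t +
#' phi))` plus 1/f background and white sensor noise (plus an optional
#' 10 Hz occipito-parietal distractor). The two amplitude envelopes share a
#' common component to the degree `rho_envelope`. The duet rate `f_duet` is
#' estimated from the realized beat-level tempo of the input trials
#' (`1000 / mean duet IOI`); the source amplitude is scaled so that its
#' power within the duet-rate analysis band (±0.183 Hz) at the
#' maximum-topography channel sits `snr_db` decibels above the background's.
#' Event-sample anchors are recorded for every tone onset.
#'
#' @param leader_trials,follower_trials event tibbles from
#'   [simulate_duet_timing()] (one condition)
#' @param cfg an [eeg_sim_config()]
#' @param melody a [make_melody_spec()] template
#' @param tail_ms silence appended after the last onset
#' @return a list with `leader` and `follower` ([eeg_recording()]s),
#'   `f_duet`, and `truth` (generated source envelopes, down-sampled by 5,
#'   plus the topography) for parameter-recovery tests
#' @export
simulate_duet_eeg <- function(leader_trials, follower_trials, cfg,
                              melody = make_melody_spec(),
                              tail_ms = 4000) {
  stopifnot(inherits(cfg, "eeg_sim_config"))
  f_duet <- estimate_beat_rate(list(leader_trials, follower_trials), melody)
  if (f_duet >= cfg$fs / 2) stop("duet rate at or above Nyquist")
  n <- ceiling((max(leader_trials$onset_ms, follower_trials$onset_ms) + tail_ms) /
                 1000 * cfg$fs)
  with_seed(cfg$seed, {
    env <- make_envelope_pair(n, cfg$fs, cfg$rho_envelope, cfg$env_cutoff_hz)
    recs <- list()
    truth_env <- list()
    for (i in 1:2) {
      trials <- list(leader_trials, follower_trials)[[i]]
      A <- env[[i]]
      tt <- (seq_len(n) - 1) / cfg$fs
      src <- A * cos(2 * pi * f_duet * tt + stats::runif(1, 0, 2 * pi))
      bg <- cfg$bg_pink_sd * pink_noise_matrix(n, cfg$fs, cfg$n_channels) +
        matrix(rnorm(cfg$n_channels * n, 0, cfg$bg_white_sd), cfg$n_channels)
      g <- source_gain(src, bg, cfg, f_duet)
      X <- outer(cfg$topography, g * src) + bg
      if (cfg$distractor_alpha) {
        Ad <- softplus(2 + slow_process(n, cfg$fs, cfg$env_cutoff_hz) / 2)
        dsrc <- Ad * cos(2 * pi * 10 * tt + stats::runif(1, 0, 2 * pi))
        gd <- source_gain(dsrc, bg, cfg, 10)
        X <- X + outer(occipital_topography(cfg$channel_names), gd * dsrc)
      }
      recs[[i]] <- eeg_recording(
        X, cfg$fs, cfg$channel_names,
        anchors = tibble::tibble(
          trial = trials$trial, repetition = trials$repetition,
          event_index = trials$event_index,
          sample = as.integer(round(trials$onset_ms / 1000 * cfg$fs))
        )
      )
      truth_env[[i]] <- g * A[seq(1, n, by = 5)]
    }
    list(leader = recs[[1]], follower = recs[[2]], f_duet = f_duet,
         truth = list(envelope_leader = truth_env[[1]],
                      envelope_follower = truth_env[[2]],
                      topography = cfg$topography,
                      rho_envelope = cfg$rho_envelope))
  })
}

# scale factor putting the source snr_db above the background within the
# f0 +/- 0.183 Hz analysis band at the maximum-topography channel
source_gain <- function(src, bg, cfg, f0) {
  if (identical(cfg$snr_db, -Inf)) return(0)
  ch_max <- which.max(abs(cfg$topography))
  bt <- signal::butter(2, c(f0 - 0.183, f0 + 0.183) / (cfg$fs / 2), type = "pass")
  v_bg <- stats::var(signal::filtfilt(bt, bg[ch_max, ]))
  if (v_bg == 0) return(1)   # noise-free recording: emit the source as-is
  v_src <- cfg$topography[ch_max]^2 * stats::var(src)
  sqrt(10^(cfg$snr_db / 10) * v_bg / v_src)
}

#' Estimate the beat-level performance rate of a set of trials
#'
#' Tempo estimate used to place the simulated neural source: for each
#' repetition, (last on-beat onset - first on-beat onset) divided by the
#' spanned beats, averaged across repetitions and performers; returned in
#' Hz as `1000 / mean IOI`.
#'
#' @param trial_list list of event tibbles
#' @param melody a [make_melody_spec()] template
#' @return rate in Hz
#' @export
estimate_beat_rate <- function(trial_list, melody) {
  iois <- unlist(lapply(trial_list, function(tab) {
    key <- interaction(tab$trial, tab$repetition, drop = TRUE)
    vapply(split(tab, key), function(p) {
      on <- p[!is.na(p$event_index) & melody$is_on_beat[p$event_index], ]
      span <- melody$beat[on$event_index[nrow(on)]] - melody$beat[on$event_index[1]]
      (on$onset_ms[nrow(on)] - on$onset_ms[1]) / span
    }, numeric(1))
  }))
  1000 / mean(iois)
}
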