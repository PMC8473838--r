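#' Analytic-signal amplitude envelope
#'
#' Magnitude of the Hilbert analytic signal, computed by zeroing the
#' negative-frequency half of the FFT and doubling the positive half.
#'
#' @param x real numeric vector
#' @return non-negative envelope, same length
#' @export
hilbert_envelope <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(X * h, inverse = TRUE) / n)
}

#' Extract per-repetition amplitude envelopes at the duet rate
#'
#' The recording is projected through the selected spatial filter to a
#' single time course, band-passed around the duet rate (±0.183 Hz,
#' 2nd-order Butterworth, zero-phase), cut into one segment per melody
#' repetition padded by 2.5 s on each side, down-sampled to 100 Hz with an
#' antialiasing FIR filter, Hilbert-transformed, and the 2.5-s tails are
#' trimmed off the envelope. Projection and filtering commute (both are
#' linear), so projecting first is a pure speed optimization.
#'
#' @param recording an [eeg_recording()]
#' @param filter spatial filter from [select_component()]
#' @param f_duet the pair's duet performance rate, Hz, in `[1, 4]`
#' @param boundaries repetition windows (`trial, repetition, start_ms,
#'   end_ms`), e.g. from [repetition_boundaries()]
#' @param halfwidth_hz narrowband half-width (default 0.183)
#' @param pad_s edge padding trimmed after the Hilbert transform
#' @param fs_out output envelope rate (default 100 Hz)
#' @return a list of class `envelope_set`: per repetition a list with
#'   `trial, repetition, samples` (envelope at `fs_out`), `start_ms`;
#'   repetitions whose padded window exceeds the recording are dropped
#'   with a warning
#' @export
extract_envelope <- function(recording, filter, f_duet, boundaries,
                             halfwidth_hz = 0.183, pad_s = 2.5,
                             fs_out = 100) {
  if (f_duet < 1 || f_duet > 4) stop("duet rate outside [1, 4] Hz")
  fs <- recording$fs
  q <- fs / fs_out
  stopifnot(q == round(q))
  course <- apply_spatial_filter(recording, filter)
  bt <- signal::butter(2, c(f_duet - halfwidth_hz, f_duet + halfwidth_hz) / (fs / 2),
                       type = "pass")
  narrow <- signal::filtfilt(bt, course)
  pad <- round(pad_s * fs)
  out <- list(); dropped <- 0L
  for (i in seq_len(nrow(boundaries))) {
    s0 <- round(boundaries$start_ms[i] / 1000 * fs) - pad
    s1 <- round(boundaries$end_ms[i] / 1000 * fs) + pad
    if (s0 < 0 || s1 > length(narrow)) { dropped <- dropped + 1L; next }
    seg <- narrow[(s0 + 1):s1]
    dec <- signal::decimate(seg, q, ftype = "fir")
    env <- hilbert_envelope(dec)
    trim <- round(pad_s * fs_out)
    env <- env[(trim + 1):(length(env) - trim)]
    out[[length(out) + 1L]] <- list(
      trial = boundaries$trial[i], repetition = boundaries$repetition[i],
      samples = env, start_ms = boundaries$start_ms[i], fs = fs_out
    )
  }
  if (dropped > 0) warning(sprintf("%d repetition(s) dropped: padded window outside recording", dropped))
  structure(out, class = "envelope_set")
}

# map event onsets (ms) of one repetition to fractional sample positions
# within its trimmed envelope
onset_anchor_samples <- function(onset_ms, start_ms, fs_out = 100) {
  (onset_ms - start_ms) / 1000 * fs_out
}

#' Eighth-note grid density for event-structure resampling
#'
#' The minimum inter-onset sample count per eighth-note unit across all
#' repetitions (and, for pair-level grids, across both partners): each
#' interval between consecutive melody events spans `2 * beat_value`
#' eighth units, and its envelope sample count divided by that unit count
#' is its eighth-equivalent density. The minimum over everything is `m`.
#'
#' @param anchor_list list of per-repetition anchor vectors (fractional
#'   sample positions of events 1..32 plus the repetition end)
#' @param melody a [make_melody_spec()] template
#' @return integer `m`
#' @export
grid_density <- function(anchor_list, melody) {
  units <- 2 * melody$beat_value
  dens <- unlist(lapply(anchor_list, function(a) {
    stopifnot(length(a) == 33)
    diff(a) / units
  }))
  m <- floor(min(dens))
  if (m < 4) stop("grid too coarse: fewer than 4 samples per eighth note")
  as.integer(m)
}

#' Resample an envelope onto the melodic event grid
#'
#' Warps envelope time so that a fixed number of samples separates
#' corresponding melody events across performances at different tempi:
#' every eighth-note unit maps to `m` samples (quarter notes 2m, half notes
#' 4m; 64 m samples per 32-beat repetition), using shape-preserving
#' piecewise-cubic (pchip) interpolation so no overshoot is introduced and
#' segment endpoints are hit exactly.
#'
#' @param samples one repetition's envelope
#' @param anchors fractional sample positions (0-based) of the 32 events
#'   plus the repetition end within `samples`
#' @param melody a [make_melody_spec()] template
#' @param m samples per eighth note (from [grid_density()])
#' @return a numeric vector of length `64 * m`
#' @export
event_resample <- function(samples, anchors, melody, m) {
  stopifnot(length(anchors) == 33, m >= 4)
  units <- 2 * melody$beat_value
  x <- seq_along(samples) - 1
  qx <- unlist(lapply(seq_len(32), function(i) {
    k <- m * units[i]
    anchors[i] + (anchors[i + 1] - anchors[i]) * (seq_len(k) - 1) / k
  }))
  qx <- pmin(pmax(qx, 0), length(samples) - 1)
  signal::pchip(x, samples, qx)
}

#' Fisher z transform and inverse
#'
#' `fisher_z()` is `atanh` with |r| clipped at 0.999999 (flagged via
#' attribute when clipping occurs); `fisher_r()` is `tanh`.
#' @param r correlation(s)
#' @param z Fisher z value(s)
#' @return transformed values
#' @export
fisher_z <- function(r) {
  clipped <- abs(r) > 0.999999
  r <- pmin(pmax(r, -0.999999), 0.999999)
  z <- atanh(r)
  if (any(clipped)) attr(z, "clipped") <- TRUE
  z
}

#' @rdname fisher_z
#' @export
fisher_r <- function(z) tanh(z)

#' Inter-brain amplitude envelope correlation for one pair and condition
#'
#' Pearson correlations of the two partners' event-resampled envelopes,
#' one per melody repetition; for the first repetition of each trial only
#' samples at or after the 9th event's grid anchor enter (both partners
#' are playing from there). Per-repetition r values are Fisher-z
#' transformed and averaged.
#'
#' @param env_leader,env_follower lists of resampled envelopes (length
#'   `64 * m` each), aligned by repetition; names or order must correspond
#' @param trials integer vector of trial numbers per repetition
#' @param repetitions integer vector of within-trial repetition numbers
#' @param m grid density the envelopes were resampled at
#' @return a list with `per_repetition_r`, `fisher_z_mean`, `r`
#'   (back-transformed mean), `n`
#' @export
aec <- function(env_leader, env_follower, trials, repetitions, m) {
  stopifnot(length(env_leader) == length(env_follower),
            length(env_leader) == length(trials))
  skip_from <- 16L * m + 1L   # events 1-8 are quarters: 16 eighth units
  rs <- numeric(0)
  for (i in seq_along(env_leader)) {
    a <- env_leader[[i]]; b <- env_follower[[i]]
    stopifnot(length(a) == length(b))
    if (repetitions[i] == 1L) {
      a <- a[skip_from:length(a)]
      b <- b[skip_from:length(b)]
    }
    if (stats::sd(a) == 0 || stats::sd(b) == 0) next
    rs <- c(rs, stats::cor(a, b))
  }
  if (length(rs) == 0) stop("no repetitions with non-degenerate envelopes")
  zbar <- mean(fisher_z(rs))
  list(per_repetition_r = rs, fisher_z_mean = zbar,
       r = fisher_r(zbar), n = length(rs))
}

#' Surrogate re-pairing null for inter-brain envelope correlations
#'
#' Pairs each leader with every follower except their true partner (n - 1
#' surrogate pairings per leader and condition; 19 when n = 20). Because
#' surrogate partners performed at different tempi, both members' raw
#' envelopes are re-resampled to the surrogate pairing's common event grid
#' (the minimum density across the two) before repetition-k is correlated
#' with repetition-k. Fisher-z averaging is as in [aec()]; the surrogate
#' mean per leader is the z-mean across that leader's surrogate pairings.
#'
#' @param pair_envelopes a list, one element per pair, each with `leader`
#'   and `follower` components holding `raw` (list of per-repetition
#'   envelope samples), `anchors` (list of 33-anchor vectors), `trials`,
#'   `repetitions`
#' @param melody a [make_melody_spec()] template
#' @return a tibble with `pair`, `surrogate_z_mean`, `surrogate_r`,
#'   `n_surrogates`
#' @export
surrogate_aecs <- function(pair_envelopes, melody) {
  n <- length(pair_envelopes)
  stopifnot(n >= 3)
  out <- list()
  for (i in seq_len(n)) {
    zs <- numeric(0)
    for (j in setdiff(seq_len(n), i)) {
      L <- pair_envelopes[[i]]$leader
      F_ <- pair_envelopes[[j]]$follower
      nrep <- min(length(L$raw), length(F_$raw))
      if (nrep < length(L$raw) || nrep < length(F_$raw)) {
        warning(sprintf("pair %d vs %d: mismatched repetition counts; using common prefix", i, j))
      }
      idx <- seq_len(nrep)
      m <- grid_density(c(L$anchors[idx], F_$anchors[idx]), melody)
      eL <- lapply(idx, function(k) event_resample(L$raw[[k]], L$anchors[[k]], melody, m))
      eF <- lapply(idx, function(k) event_resample(F_$raw[[k]], F_$anchors[[k]], melody, m))
      res <- aec(eL, eF, L$trials[idx], L$repetitions[idx], m)
      zs <- c(zs, res$fisher_z_mean)
    }
    out[[i]] <- tibble::tibble(pair = i, surrogate_z_mean = mean(zs),
                               surrogate_r = fisher_r(mean(zs)),
                               n_surrogates = length(zs))
  }
  do.call(rbind, out)
}

#' Exact binomial comparison of observed versus surrogate correlations
#'
#' One observed and one surrogate-mean correlation per pair; a success is
#' an observed value strictly greater than the surrogate mean (ties count
#' as failures). The one-sided exact tail probability under the chance
#' null p = 0.5 is `sum_{i=k..n} choose(n, i) / 2^n`.
#'
#' @param observed,surrogate numeric vectors, one value per pair
#' @return a list with `k`, `n`, `p`
#' @export
binomial_comparison <- function(observed, surrogate) {
  stopifnot(length(observed) == length(surrogate))
  n <- length(observed)
  if (n == 0) stop("no pairs")
  k <- sum(observed > surrogate)
  p <- stats::pbinom(k - 1, n, 0.5, lower.tail = FALSE)
  list(k = k, n = n, p = p)
}
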