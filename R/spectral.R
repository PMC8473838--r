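#' Spectral analysis configuration
#'
#' Fixes the frequency-tagging geometry used throughout: 9-s epochs at
#' 500 Hz are multiplied with a 4500-point Hanning window and zero-padded to
#' `nfft = 8192`, the power of two giving a bin spacing of
#' 500/8192 = 0.061 Hz. Noise normalization subtracts the mean log power at
#' the ±3 neighboring bins (±0.183 Hz); the peak test compares the center
#' bin with the surrounding ±8 bins; rate-aligned spectra keep ±24 bins
#' (49 bins, spanning 2.99 Hz) around the duet-rate bin.
#'
#' @param fs sampling rate, Hz
#' @param epoch_s epoch duration, s
#' @param noise_halfwidth_bins half-width of the noise-normalization
#'   neighborhood (offsets 1..halfwidth on each side)
#' @param peak_halfwidth_bins half-width of the peak-test neighborhood
#' @param align_halfwidth_bins half-width of the rate-aligned window
#' @param roi fronto-central region-of-interest channel names
#' @param highpass_hz,lowpass_hz pre-filter band edges for
#'   [bandlimit_recording()]
#' @return a list of class `spectral_config` with the derived fields
#'   `window` (Hanning, `epoch_s * fs` points), `nfft`, and `bin_hz`
#' @export
spectral_config <- function(fs = 500, epoch_s = 9,
                            noise_halfwidth_bins = 3L,
                            peak_halfwidth_bins = 8L,
                            align_halfwidth_bins = 24L,
                            roi = c("FC1", "FC2", "Cz", "Fz"),
                            highpass_hz = 0.1, lowpass_hz = 20) {
  n_win <- as.integer(round(epoch_s * fs))
  nfft <- 2^ceiling(log2(n_win))
  cfg <- list(
    fs = fs, epoch_s = epoch_s, n_win = n_win,
    window = signal::hanning(n_win), nfft = nfft, bin_hz = fs / nfft,
    noise_halfwidth_bins = as.integer(noise_halfwidth_bins),
    peak_halfwidth_bins = as.integer(peak_halfwidth_bins),
    align_halfwidth_bins = as.integer(align_halfwidth_bins),
    roi = roi, highpass_hz = highpass_hz, lowpass_hz = lowpass_hz
  )
  stopifnot(length(cfg$window) == cfg$n_win)
  class(cfg) <- "spectral_config"
  cfg
}

#' Cut fixed 9-s epochs, one per melody repetition
#'
#' Each epoch starts at the repetition's first sample and runs for
#' `epoch_s * fs` samples (half-open, 0-based); repetitions shorter than the
#' epoch borrow samples from the beginning of the subsequent repetition. A
#' final repetition with fewer than `epoch_s * fs` samples of data remaining
#' is dropped with a warning.
#'
#' @param recording an [eeg_recording()]
#' @param start_samples 0-based sample index of each repetition's start
#' @param cfg a [spectral_config()]
#' @return a list of channels-by-samples epoch matrices
#' @export
epoch_fixed_window <- function(recording, start_samples, cfg = spectral_config()) {
  n <- ncol(recording$data)
  len <- cfg$n_win
  epochs <- list()
  dropped <- 0L
  for (s in start_samples) {
    if (s + len > n) { dropped <- dropped + 1L; next }
    epochs[[length(epochs) + 1L]] <- recording$data[, (s + 1):(s + len), drop = FALSE]
  }
  if (dropped > 0) {
    warning(sprintf("%d epoch(s) dropped: repetition extends past end of recording", dropped))
  }
  epochs
}

#' Welch power spectral density of one epoch
#'
#' The whole epoch is one Welch segment: the data are multiplied with the
#' Hanning window, zero-padded to `nfft`, and converted to a one-sided
#' power spectral density (per Hz). With a single segment this is the
#' modified periodogram; overlap never enters.
#'
#' @param epoch a channels-by-samples matrix (or a vector for one channel),
#'   exactly `cfg$n_win` samples long
#' @param cfg a [spectral_config()]
#' @return a list with `freq` (Hz, `nfft/2 + 1` bins at spacing
#'   `fs / nfft`) and `power` (channels x bins, strictly positive up to
#'   numerical zero)
#' @export
welch_psd <- function(epoch, cfg = spectral_config()) {
  if (is.vector(epoch)) epoch <- matrix(epoch, nrow = 1)
  if (ncol(epoch) != cfg$n_win) {
    stop(sprintf("epoch must be %d samples, got %d", cfg$n_win, ncol(epoch)))
  }
  w <- cfg$window
  xw <- sweep(epoch, 2, w, `*`)
  pad <- matrix(0, nrow(epoch), cfg$nfft - cfg$n_win)
  X <- t(stats::mvfft(t(cbind(xw, pad))))
  nb <- cfg$nfft / 2 + 1
  P <- Mod(X[, 1:nb, drop = FALSE])^2 / (cfg$fs * sum(w^2))
  P[, 2:(nb - 1)] <- 2 * P[, 2:(nb - 1)]
  list(freq = (0:(nb - 1)) * cfg$bin_hz, power = P)
}

#' Mean log power spectrum over epochs
#'
#' Computes the Welch PSD of every epoch, log-transforms (natural log, to
#' compensate the 1/f power distribution of EEG), and averages across
#' epochs per channel.
#'
#' @param epochs list of epoch matrices from [epoch_fixed_window()]
#' @param cfg a [spectral_config()]
#' @return a list with `freq` and `log_power` (channels x bins)
#' @export
epoch_log_psd_mean <- function(epochs, cfg = spectral_config()) {
  stopifnot(length(epochs) >= 1)
  acc <- NULL; freq <- NULL
  for (ep in epochs) {
    ps <- welch_psd(ep, cfg)
    freq <- ps$freq
    lp <- log(pmax(ps$power, .Machine$double.xmin))
    acc <- if (is.null(acc)) lp else acc + lp
  }
  list(freq = freq, log_power = acc / length(epochs))
}

#' Local noise normalization of a (log) spectrum
#'
#' Subtracts from each frequency bin the mean value at the ±`halfwidth`
#' neighboring bins (offsets ±1..±halfwidth, center excluded). Broadband
#' background, locally smooth in frequency, cancels; narrowband peaks
#' survive. Edge bins use the neighbors that exist and are flagged.
#'
#' @param values numeric matrix (channels x bins) or vector of log power
#' @param halfwidth neighborhood half-width in bins
#' @return a list with `values` (same shape) and `edge` (logical per bin)
#' @export
noise_normalize <- function(values, halfwidth = 3L) {
  if (is.vector(values)) values <- matrix(values, nrow = 1)
  nb <- ncol(values)
  hw <- as.integer(halfwidth)
  stopifnot(nb >= 2 * hw + 1)
  # windowed neighbor sums via a centered moving sum (O(n) per channel);
  # interior bins have exactly 2*hw neighbors
  kernel <- rep(1, 2 * hw + 1)
  win_sum <- t(apply(values, 1, function(x) {
    as.numeric(stats::filter(x, kernel, sides = 2))
  }))
  out <- values - (win_sum - values) / (2 * hw)
  edge <- c(rep(TRUE, hw), rep(FALSE, nb - 2 * hw), rep(TRUE, hw))
  for (j in which(edge)) {   # edges: use the neighbors that exist
    nbrs <- j + c(-(hw:1), 1:hw)
    nbrs <- nbrs[nbrs >= 1 & nbrs <= nb]
    out[, j] <- values[, j] - rowMeans(values[, nbrs, drop = FALSE])
  }
  rownames(out) <- rownames(values)
  list(values = out, edge = edge)
}

#' Log-transform and noise-normalize a power spectrum
#'
#' @param spectrum a list with `freq` and `power` (strictly positive), as
#'   returned by [welch_psd()]
#' @param cfg a [spectral_config()]
#' @return a list of class `normalized_spectrum` with `freqs_hz`, `values`
#'   (channels x bins), `edge`
#' @export
lognormalize <- function(spectrum, cfg = spectral_config()) {
  if (any(spectrum$power <= 0)) stop("non-positive power: cannot log-transform")
  nn <- noise_normalize(log(spectrum$power), cfg$noise_halfwidth_bins)
  structure(list(freqs_hz = spectrum$freq, values = nn$values,
                 edge = nn$edge),
            class = "normalized_spectrum")
}

# nearest bin to f on an equally spaced grid starting at 0; exact midpoint
# ties resolve toward the lower bin
nearest_bin <- function(f, bin_hz) {
  k <- floor(f / bin_hz)
  frac <- f / bin_hz - k
  as.integer(k + (frac > 0.5)) + 1L   # 1-based index
}

#' Extract the rate-aligned spectral window around the duet rate
#'
#' Returns the 49 values at the bin nearest the pair's duet performance
#' rate ±24 bins, allowing spectra of pairs with different tempi to be
#' aligned bin-by-bin at their own performance frequency.
#'
#' @param nspec a `normalized_spectrum` (or list with `freqs_hz`, `values`)
#' @param f_duet the pair's duet performance rate, Hz
#' @param cfg a [spectral_config()]
#' @return a list with `values` (channels x 49), `rel_bins` (-24..24),
#'   `center_bin` (1-based index into the full spectrum)
#' @export
align_to_duet_rate <- function(nspec, f_duet, cfg = spectral_config()) {
  hw <- cfg$align_halfwidth_bins
  nb <- length(nspec$freqs_hz)
  center <- nearest_bin(f_duet, cfg$bin_hz)
  if (center - hw < 1 || center + hw > nb) {
    stop(sprintf("duet rate %.3f Hz is within %d bins of the spectrum edge", f_duet, hw))
  }
  vals <- nspec$values[, (center - hw):(center + hw), drop = FALSE]
  list(values = vals, rel_bins = -hw:hw, center_bin = center)
}

#' Average a spectrum over the fronto-central region of interest
#'
#' @param values channels x bins matrix with channel rownames
#' @param roi ROI channel names (case-insensitive); `NULL` averages all
#'   channels (the channel-mean variant)
#' @return a numeric vector, one value per bin
#' @export
roi_mean <- function(values, roi = c("FC1", "FC2", "Cz", "Fz")) {
  if (is.null(roi)) return(colMeans(values))
  have <- tolower(rownames(values))
  idx <- match(tolower(roi), have)
  if (anyNA(idx)) {
    stop("missing ROI channel(s): ", paste(roi[is.na(idx)], collapse = ", "))
  }
  colMeans(values[idx, , drop = FALSE])
}

#' Wilcoxon signed-rank test for a spectral peak
#'
#' Paired test of the noise-normalized power at the bin closest to the duet
#' performance rate against the mean power at the surrounding ±8 bins, one
#' pair of values per participant. The normal-approximation z statistic is
#' reported (matching common practice for n = 20-40 cohorts), with an
#' exact-distribution option for small samples.
#'
#' @param center numeric vector of center-bin values
#' @param neighbor numeric vector of neighborhood-mean values (same length)
#' @param method `"normal"` (z with tie correction) or `"exact"` (null
#'   distribution of the signed-rank statistic; requires no ties or zeros)
#' @param alternative `"greater"` (default; peak above neighborhood),
#'   `"two.sided"`, or `"less"`
#' @return a list with `statistic` (W, sum of positive ranks), `z`, `p`,
#'   `n` (non-zero differences), `degenerate` (all differences zero)
#' @export
peak_test <- function(center, neighbor, method = c("normal", "exact"),
                      alternative = c("greater", "two.sided", "less")) {
  method <- match.arg(method)
  alternative <- match.arg(alternative)
  stopifnot(length(center) == length(neighbor), length(center) >= 6)
  d <- center - neighbor
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(list(statistic = NA_real_, z = 0, p = 1, n = 0L, degenerate = TRUE))
  }
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  z <- (W - mu) / sqrt(sigma2)
  if (method == "exact") {
    if (any(duplicated(abs(d)))) {
      warning("ties present; exact distribution assumes none")
    }
    p <- switch(alternative,
      greater = stats::psignrank(W - 1, n, lower.tail = FALSE),
      less = stats::psignrank(W, n),
      two.sided = min(1, 2 * min(stats::psignrank(W - 1, n, lower.tail = FALSE),
                                 stats::psignrank(W, n)))
    )
  } else {
    p <- switch(alternative,
      greater = stats::pnorm(z, lower.tail = FALSE),
      less = stats::pnorm(z),
      two.sided = 2 * stats::pnorm(-abs(z))
    )
  }
  list(statistic = W, z = z, p = p, n = n, degenerate = FALSE)
}

#' Peak-vs-neighborhood values from a rate-aligned spectrum
#'
#' Convenience extractor: the center-bin value and the mean of the values
#' at offsets ±1..±`halfwidth` from a 49-bin aligned window (one spectrum,
#' already ROI- or channel-averaged).
#'
#' @param aligned_values numeric vector over relative bins -24..24
#' @param halfwidth neighborhood half-width (default 8)
#' @return a list with `center` and `neighbor_mean`
#' @export
peak_values <- function(aligned_values, halfwidth = 8L) {
  c0 <- (length(aligned_values) + 1L) / 2L
  nbrs <- c0 + c(-(halfwidth:1), 1:halfwidth)
  list(center = aligned_values[c0],
       neighbor_mean = mean(aligned_values[nbrs]))
}

#' Correlate spectral power at the duet rate with synchronization accuracy
#'
#' Pearson correlation of participants' noise-normalized PSD at the duet
#' performance rate with the pair's mean absolute asynchrony, plus an
#' optional standardized two-predictor regression (leader and follower PSD
#' predicting asynchrony).
#'
#' @param psd numeric vector of PSD-at-rate values
#' @param asynchrony numeric vector of mean absolute asynchronies
#' @param psd_follower optional second predictor; when given, the
#'   regression component is fitted
#' @return a list with `r`, `p`, `n`, and (when `psd_follower` is given)
#'   `regression` as in [duet_rate_regression()]
#' @export
psd_synchrony_correlation <- function(psd, asynchrony, psd_follower = NULL) {
  stopifnot(length(psd) == length(asynchrony), length(psd) >= 4)
  if (stats::sd(psd) == 0 || stats::sd(asynchrony) == 0) {
    stop("constant input: correlation undefined")
  }
  ct <- stats::cor.test(psd, asynchrony)
  out <- list(r = unname(ct$estimate), p = ct$p.value, n = length(psd))
  if (!is.null(psd_follower)) {
    out$regression <- duet_rate_regression(tibble::tibble(
      duet_rate = asynchrony,
      leader_solo_rate = psd,
      follower_solo_rate = psd_follower
    ))
  }
  out
}

#' Zero-phase band-limiting pre-filter
#'
#' High-pass plus low-pass FIR filtering (windowed-sinc design, applied
#' forward and backward) matching the conventional pre-processing before
#' PSD estimation. Synthetic recordings contain no drift and may skip it.
#'
#' @param recording an [eeg_recording()]
#' @param cfg a [spectral_config()]
#' @param order FIR order (default 1000)
#' @return the filtered recording
#' @export
bandlimit_recording <- function(recording, cfg = spectral_config(), order = 1000L) {
  nyq <- recording$fs / 2
  lo <- signal::fir1(order, cfg$lowpass_hz / nyq, type = "low")
  hi <- signal::fir1(order, cfg$highpass_hz / nyq, type = "high")
  dat <- recording$data
  for (ch in seq_len(nrow(dat))) {
    x <- signal::filtfilt(lo, 1, dat[ch, ])
    dat[ch, ] <- signal::filtfilt(hi, 1, x)
  }
  recording$data <- dat
  recording
}
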