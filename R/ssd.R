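#' Spatio-spectral decomposition (SSD)
#'
#' Finds spatial filters maximizing oscillatory power in a target band
#' relative to two flanking bands, via the generalized eigenvalue problem
#' `S w = lambda N w`, where `S` is the channel covariance of the
#' band-passed data and `N` the summed covariance of the two flank-passed
#' versions. Filters are returned by descending eigenvalue together with
#' their forward patterns (`S %*% filters`, column-normalized), which are
#' what should be interpreted topographically.
#'
#' Band-passes are zero-phase (forward-backward) 2nd-order Butterworth
#' filters. A rank-deficient flank covariance is ridge-regularized
#' (`1e-6 * trace/dim`) with a warning.
#'
#' @param recording an [eeg_recording()] (>= 4 channels; 60 s or more of
#'   data recommended)
#' @param band target band in Hz (default `c(1.5, 3.5)`, the range of
#'   observed solo performance rates)
#' @param flank_width width of each flanking band, Hz
#' @param gap gap between the target band edge and its flank, Hz
#' @param decimate_to working sampling rate, Hz: the recording is
#'   antialias-decimated before covariance estimation, since every band of
#'   interest lies far below this Nyquist; set `NULL` to disable
#' @return a list of class `ssd_result`: `filters` (channels x components),
#'   `patterns`, `eigenvalues` (descending), `band`, `flanks`
#' @export
fit_ssd <- function(recording, band = c(1.5, 3.5), flank_width = 1, gap = 0.5,
                    decimate_to = 50) {
  dat <- recording$data
  if (!all(is.finite(dat))) stop("non-finite data")
  stopifnot(nrow(dat) >= 4, band[1] > 0, band[2] > band[1])
  fs <- recording$fs
  if (!is.null(decimate_to) && fs > decimate_to) {
    q <- fs / decimate_to
    if (q == round(q)) {
      dat <- t(apply(dat, 1, signal::decimate, q = q, ftype = "fir"))
      fs <- decimate_to
    }
  }
  flanks <- list(c(max(band[1] - gap - flank_width, 0.1), band[1] - gap),
                 c(band[2] + gap, band[2] + gap + flank_width))
  S <- band_cov(dat, fs, band)
  N <- band_cov(dat, fs, flanks[[1]]) + band_cov(dat, fs, flanks[[2]])
  d <- nrow(N)
  ev_N <- eigen(N, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev_N) < 1e-12 * max(ev_N)) {
    warning("rank-deficient flank covariance; applying ridge regularization")
    N <- N + diag(1e-6 * sum(diag(N)) / d, d)
  }
  ge <- gen_eigen(S, N)
  patterns <- S %*% ge$vectors
  patterns <- sweep(patterns, 2, sqrt(colSums(patterns^2)), `/`)
  rownames(patterns) <- rownames(ge$vectors) <- recording$channel_names
  structure(list(filters = ge$vectors, patterns = patterns,
                 eigenvalues = ge$values, band = band, flanks = flanks),
            class = "ssd_result")
}

# Zero-phase 2nd-order Butterworth band-pass applied in the frequency
# domain: multiplying the spectrum by |H(f)|^2 is the steady-state
# equivalent of forward-backward (filtfilt) filtering and is much faster
# over long multichannel recordings. Used for covariance and band-power
# estimation, where edge transients are negligible.
zerophase_bandpass <- function(x, fs, band) {
  bt <- signal::butter(2, band / (fs / 2), type = "pass")
  n <- length(x)
  nfft <- stats::nextn(n)
  f <- seq(0, fs, length.out = nfft + 1)[1:nfft]
  z <- exp(-2i * pi * f / fs)
  H2 <- Mod(polyval_rev(bt$b, z) / polyval_rev(bt$a, z))^2
  X <- stats::fft(c(x, numeric(nfft - n)))
  Re(stats::fft(X * H2, inverse = TRUE) / nfft)[seq_len(n)]
}

polyval_rev <- function(p, z) {
  acc <- 0
  for (c in p) acc <- acc * z + c
  acc
}

band_cov <- function(dat, fs, band) {
  filt <- t(apply(dat, 1, function(x) zerophase_bandpass(x, fs, band)))
  stats::cov(t(filt))
}

# generalized symmetric eigenproblem S w = lambda N w via whitening:
# N = V D V', W_white = V D^{-1/2}, then ordinary symmetric eigen of
# W' S W. Eigenvalues descending; eigenvectors N-orthonormal.
gen_eigen <- function(S, N) {
  eN <- eigen(N, symmetric = TRUE)
  keep <- eN$values > max(eN$values) * 1e-12
  W <- eN$vectors[, keep, drop = FALSE] %*%
    diag(1 / sqrt(eN$values[keep]), sum(keep))
  eM <- eigen(t(W) %*% S %*% W, symmetric = TRUE)
  list(values = eM$values, vectors = W %*% eM$vectors)
}

#' @export
print.ssd_result <- function(x, ...) {
  cat(sprintf("<ssd_result> %d components, band %.2f-%.2f Hz, lambda_1 = %.2f\n",
              length(x$eigenvalues), x$band[1], x$band[2], x$eigenvalues[1]))
  invisible(x)
}

#' Project a recording through a spatial filter
#'
#' @param recording an [eeg_recording()]
#' @param filter channel weight vector
#' @return numeric time course (length = samples)
#' @export
apply_spatial_filter <- function(recording, filter) {
  stopifnot(length(filter) == nrow(recording$data))
  as.numeric(crossprod(filter, recording$data))
}

#' Select the duet-rate SSD component
#'
#' Automated stand-in for visual selection of the component with a
#' stereotypical fronto-central delta topography: each component is scored
#' by (band/flank power ratio of its time course) x (fraction of its
#' forward-pattern mass on the fronto-central ROI), and the best is
#' returned as a unit-norm filter, sign-fixed so the mean ROI pattern
#' loading is positive. If no component loads positively on the ROI, the
#' maximum-eigenvalue component is returned with a warning.
#'
#' @param ssd an [fit_ssd()] result
#' @param recording the recording the scores are evaluated on (typically
#'   the same solo recording the SSD was fitted on)
#' @param roi ROI channel names
#' @param n_candidates number of leading components scored (default 6)
#' @return a list with `filter` (unit-norm), `pattern`, `index`, `score`
#' @export
select_component <- function(ssd, recording,
                             roi = c("FC1", "FC2", "Cz", "Fz"),
                             n_candidates = 6L) {
  k <- min(n_candidates, length(ssd$eigenvalues))
  ridx <- match(tolower(roi), tolower(rownames(ssd$patterns)))
  if (anyNA(ridx)) stop("missing ROI channel(s): ", paste(roi[is.na(ridx)], collapse = ", "))
  fs <- recording$fs
  dat <- recording$data
  q <- fs / 50
  if (fs > 50 && q == round(q)) {   # scores only involve bands below 6 Hz
    dat <- t(apply(dat, 1, signal::decimate, q = q, ftype = "fir"))
    fs <- 50
  }
  scores <- roi_load <- numeric(k)
  for (i in seq_len(k)) {
    course <- as.numeric(crossprod(ssd$filters[, i], dat))
    snr <- band_flank_ratio(course, fs, ssd$band, ssd$flanks)
    pat <- ssd$patterns[, i]
    roi_frac <- sum(abs(pat[ridx])) / sum(abs(pat))
    roi_load[i] <- mean(pat[ridx])
    scores[i] <- snr * roi_frac
  }
  pos <- which(abs(roi_load) > 0)
  best <- if (length(pos)) pos[which.max(scores[pos])] else {
    warning("no component with ROI loading; falling back to maximum eigenvalue")
    1L
  }
  filt <- ssd$filters[, best]
  pat <- ssd$patterns[, best]
  if (mean(pat[ridx]) < 0) { filt <- -filt; pat <- -pat }
  filt <- filt / sqrt(sum(filt^2))
  list(filter = filt, pattern = pat, index = best, score = scores[best])
}

band_flank_ratio <- function(x, fs, band, flanks) {
  bp <- function(b) stats::var(zerophase_bandpass(x, fs, b))
  bp(band) / (bp(flanks[[1]]) + bp(flanks[[2]]))
}
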