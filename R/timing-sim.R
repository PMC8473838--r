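#' Configuration for the duet timing simulator
#'
#' The simulator is a linear phase-correction timekeeper model operating on
#' the beat grid: each performer's internal beat advances by their natural
#' period plus timekeeper noise, minus a correction proportional to the
#' current leader-minus-follower asynchrony. The follower corrects with gain
#' `alpha`; the leader with gain `beta` (0 by default: the leader sets the
#' pace and ignores the partner). Emitted tone onsets add motor noise that
#' does not propagate.
#'
#' With zero noise the asynchrony recursion
#' `A(n+1) = (1 - alpha - beta) * A(n) + (T_leader - T_follower)`
#' contracts to the fixed point `(T_leader - T_follower) / (alpha + beta)`,
#' the closed-form detuning-to-asynchrony law used throughout the test suite.
#'
#' @param T_leader,T_follower natural beat periods in ms (200..1200)
#' @param alpha follower phase-correction gain, in `[0, 2]`
#' @param beta leader phase-correction gain, in `[0, 2]` (default 0)
#' @param sigma_timekeeper timekeeper (period) noise SD, ms
#' @param sigma_motor motor (onset) noise SD, ms
#' @param n_trials trials per condition (default 6)
#' @param n_repetitions melody repetitions per trial (default 4, so 24 per
#'   condition)
#' @param p_pitch_error probability that a repetition carries one inserted or
#'   deleted tone
#' @param lead_in_ms silence before the first trial (and between trials),
#'   needed downstream as filter padding
#' @param seed integer seed
#' @return a list of class `timing_sim_config`
#' @export
timing_sim_config <- function(T_leader = 500, T_follower = 500,
                              alpha = 0.5, beta = 0,
                              sigma_timekeeper = 10, sigma_motor = 4,
                              n_trials = 6, n_repetitions = 4,
                              p_pitch_error = 0.04,
                              lead_in_ms = 4000, seed = 1L) {
  stopifnot(
    T_leader >= 200, T_leader <= 1200,
    T_follower >= 200, T_follower <= 1200,
    alpha >= 0, alpha <= 2, beta >= 0, beta <= 2,
    sigma_timekeeper >= 0, sigma_motor >= 0,
    n_trials >= 1, n_repetitions >= 1,
    p_pitch_error >= 0, p_pitch_error <= 1,
    lead_in_ms >= 0
  )
  structure(as.list(environment()), class = "timing_sim_config")
}

# Beat-grid recursion for one trial. Returns central (pre-motor-noise) beat
# times, beats 0..n_beats, for both performers.
simulate_beat_grid <- function(cfg, n_beats) {
  eL <- rnorm(n_beats, 0, cfg$sigma_timekeeper)
  eF <- rnorm(n_beats, 0, cfg$sigma_timekeeper)
  tL <- tF <- numeric(n_beats + 1)
  for (n in seq_len(n_beats)) {
    A <- tL[n] - tF[n]
    tL[n + 1] <- tL[n] + cfg$T_leader + eL[n] - cfg$beta * A
    tF[n + 1] <- tF[n] + cfg$T_follower + eF[n] + cfg$alpha * A
  }
  list(leader = tL, follower = tF)
}

# Map melody events of one repetition onto beat times. Off-beat eighths are
# emitted at the temporal midpoint of the surrounding beats (isochronous
# subdivision). `beat_times` covers beats 0..32*n_repetitions of the trial.
event_onsets_from_beats <- function(beat_times, melody, repetition) {
  b <- melody$beat + 32 * (repetition - 1)
  onset <- numeric(nrow(melody))
  on <- melody$is_on_beat
  onset[on] <- beat_times[b[on] + 1]
  k <- floor(b[!on])
  onset[!on] <- (beat_times[k + 1] + beat_times[k + 2]) / 2
  onset
}

#' Simulate coupled duet performances of the melody
#'
#' Generates leader and follower tone-onset streams for one duet condition
#' under the phase-correction timekeeper model (see
#' [timing_sim_config()]). Trials are placed sequentially on a global
#' timeline separated by `lead_in_ms` of silence. The follower emits no
#' onsets for melody events 1-8 of the first repetition of each trial (the
#' leader's count-in); all later repetitions are fully in unison.
#'
#' @param melody a [make_melody_spec()] template
#' @param cfg a [timing_sim_config()]
#' @param condition condition label stored in the output (default
#'   `"First-Leader"`)
#' @param pair_id,leader_id,follower_id identifiers stored in the output
#' @return a list with tibbles `leader` and `follower`, one row per emitted
#'   tone: columns `pair_id, performer, role, condition, trial, repetition,
#'   event_index, nominal_pitch, played_pitch, onset_ms, beat_value,
#'   is_on_beat, injected_error`. Onsets are strictly increasing per
#'   performer; identical config and seed give identical output.
#' @export
simulate_duet_timing <- function(melody, cfg, condition = "First-Leader",
                                 pair_id = 1L, leader_id = "L",
                                 follower_id = "F") {
  stopifnot(inherits(cfg, "timing_sim_config"))
  if (cfg$alpha == 0 && cfg$beta == 0 && cfg$T_leader != cfg$T_follower &&
      cfg$n_repetitions * cfg$n_trials > 1) {
    warning("uncoupled performers with nonzero detuning: asynchrony drifts without bound")
  }
  with_seed(cfg$seed, {
    n_beats <- 32L * cfg$n_repetitions
    out_L <- out_F <- list()
    t0 <- cfg$lead_in_ms
    for (tr in seq_len(cfg$n_trials)) {
      grid <- simulate_beat_grid(cfg, n_beats)
      for (rep_i in seq_len(cfg$n_repetitions)) {
        onL <- t0 + event_onsets_from_beats(grid$leader, melody, rep_i) +
          rnorm(32, 0, cfg$sigma_motor)
        onF <- t0 + event_onsets_from_beats(grid$follower, melody, rep_i) +
          rnorm(32, 0, cfg$sigma_motor)
        keep_F <- if (rep_i == 1L) melody$event > 8L else rep(TRUE, 32)
        out_L[[length(out_L) + 1L]] <- event_rows(
          melody, onL, rep(TRUE, 32), pair_id, leader_id, "Leader",
          condition, tr, rep_i)
        out_F[[length(out_F) + 1L]] <- event_rows(
          melody, onF, keep_F, pair_id, follower_id, "Follower",
          condition, tr, rep_i)
      }
      t0 <- t0 + grid$leader[n_beats + 1] + cfg$lead_in_ms
    }
    res <- list(
      leader = tibble::as_tibble(do.call(rbind, out_L[!vapply(out_L, is.null, TRUE)])),
      follower = tibble::as_tibble(do.call(rbind, out_F[!vapply(out_F, is.null, TRUE)]))
    )
    validate_onsets(res$leader)
    validate_onsets(res$follower)
    res
  })
}

event_rows <- function(melody, onset, keep, pair_id, performer, role,
                       condition, trial, repetition) {
  if (!any(keep)) return(NULL)
  data.frame(
    pair_id = pair_id,
    performer = performer,
    role = role,
    condition = condition,
    trial = as.integer(trial),
    repetition = as.integer(repetition),
    event_index = melody$event[keep],
    nominal_pitch = melody$pitch[keep],
    played_pitch = melody$pitch[keep],
    onset_ms = onset[keep],
    beat_value = melody$beat_value[keep],
    is_on_beat = melody$is_on_beat[keep],
    injected_error = "none"
  )
}

validate_onsets <- function(tab) {
  d <- diff(tab$onset_ms)
  if (any(d <= 0)) stop("onsets are not strictly increasing; reduce motor noise")
  invisible(tab)
}

#' Simulate solo performances
#'
#' One performer plays the melody alone at their natural period; the
#' phase-correction recursion degenerates to an isochronous timekeeper with
#' period and motor noise.
#'
#' @inheritParams simulate_duet_timing
#' @param period_ms the performer's natural beat period
#' @param performer_id identifier stored in the output
#' @return a tibble in the same schema as [simulate_duet_timing()]
#' @export
simulate_solo_timing <- function(melody, cfg, period_ms = cfg$T_leader,
                                 pair_id = 1L, performer_id = "L") {
  cfg2 <- cfg
  cfg2$T_leader <- cfg2$T_follower <- period_ms
  cfg2$alpha <- cfg2$beta <- 0
  res <- simulate_duet_timing(melody, cfg2, condition = "Solo",
                              pair_id = pair_id, leader_id = performer_id)
  tab <- res$leader
  tab$role <- "Solo"
  tab
}

#' Inject pitch errors (added or deleted tones) into performances
#'
#' With probability `p` per repetition, one tone is inserted (a doubled
#' pitch placed midway between two onsets) or deleted, with the choice and
#' position drawn from the given seed. The affected repetition is tagged in
#' the `injected_error` column (`"insertion"` or `"deletion"`) so that the
#' downstream error filter can be validated against ground truth.
#'
#' @param trials a trial tibble from [simulate_duet_timing()]
#' @param p probability per repetition, in `[0, 1]`
#' @param seed integer seed
#' @return the modified tibble
#' @export
inject_pitch_errors <- function(trials, p, seed = 1L) {
  stopifnot(p >= 0, p <= 1)
  if (p == 0) return(trials)
  with_seed(seed, {
    key <- interaction(trials$performer, trials$condition, trials$trial,
                       trials$repetition, drop = TRUE)
    pieces <- split(trials, key)
    hit <- runif(length(pieces)) < p
    for (i in which(hit)) {
      piece <- pieces[[i]]
      n <- nrow(piece)
      if (runif(1) < 0.5 && n >= 2) {         # deletion
        piece <- piece[-sample.int(n, 1), ]
        piece$injected_error <- "deletion"
      } else {                                 # insertion
        at <- sample.int(n - 1, 1)
        extra <- piece[at, ]
        extra$onset_ms <- (piece$onset_ms[at] + piece$onset_ms[at + 1]) / 2
        extra$event_index <- NA_integer_
        extra$nominal_pitch <- NA_real_
        piece <- rbind(piece[seq_len(at), ], extra,
                       piece[seq(at + 1, n), ])
        piece$injected_error <- "insertion"
      }
      pieces[[i]] <- piece
    }
    out <- do.call(rbind, pieces)
    out <- out[order(out$performer, out$condition, out$trial,
                     out$repetition, out$onset_ms), ]
    rownames(out) <- NULL
    out
  })
}

#' Derive repetition time windows from a performance stream
#'
#' Each repetition's window starts at its first onset and ends at the start
#' of the following repetition in the same trial; the last repetition of a
#' trial ends two beats (the final half note) after its last onset, using
#' the trial's median beat interval as the local tempo estimate.
#'
#' @param trials a trial tibble (typically the leader's stream)
#' @return a tibble with `trial, repetition, start_ms, end_ms`
#' @export
repetition_boundaries <- function(trials) {
  key <- interaction(trials$trial, trials$repetition, drop = TRUE)
  starts <- tapply(trials$onset_ms, key, min)
  lasts <- tapply(trials$onset_ms, key, max)
  ids <- do.call(rbind, strsplit(names(starts), "\\."))
  out <- tibble::tibble(
    trial = as.integer(ids[, 1]),
    repetition = as.integer(ids[, 2]),
    start_ms = as.numeric(starts),
    end_ms = NA_real_
  )
  out <- out[order(out$trial, out$repetition), ]
  for (tr in unique(out$trial)) {
    idx <- which(out$trial == tr)
    on_tr <- sort(trials$onset_ms[trials$trial == tr])
    beat_est <- stats::median(diff(on_tr))
    ends <- c(out$start_ms[idx][-1],
              max(on_tr) + 2 * beat_est)
    out$end_ms[idx] <- ends
  }
  out
}
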