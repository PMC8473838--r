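#' Classify a performance against the melody template by pitch alignment
#'
#' Repetitions containing pitch errors defined as added or deleted tones are
#' excluded from all downstream analyses; substituted pitches (wrong note,
#' same position) are retained because they do not disrupt the timing of the
#' pitch sequence. Classification is by global (Needleman-Wunsch) alignment
#' of the played pitch sequence against the template, scored match +1,
#' mismatch -0.25, indel -1. The scoring deliberately prefers a substitution
#' over an insertion/deletion pair, and traceback ties resolve toward the
#' diagonal (substitution).
#'
#' @param trial a tibble of one repetition's events, with `played_pitch`
#' @param melody a [make_melody_spec()] template
#' @return a list with
#'   \describe{
#'     \item{status}{`"clean"`, `"substitution_only"`, or `"excluded"`}
#'     \item{matched_event_index}{for retained trials, the template event
#'       matched to each played tone (integer vector, same length as the
#'       trial); `NULL` for excluded trials}
#'     \item{reason}{for excluded trials, `"empty"` or `"indel"`}
#'   }
#' @export
classify_pitch_errors <- function(trial, melody) {
  played <- trial$played_pitch
  if (length(played) == 0) {
    return(list(status = "excluded", matched_event_index = NULL,
                reason = "empty"))
  }
  template <- melody$pitch
  aln <- align_global(played, template,
                      match = 1, mismatch = -0.25, indel = -1)
  if (aln$n_indel > 0) {
    return(list(status = "excluded", matched_event_index = NULL,
                reason = "indel"))
  }
  status <- if (aln$n_mismatch == 0) "clean" else "substitution_only"
  list(status = status, matched_event_index = aln$match_index,
       reason = NULL)
}

# Needleman-Wunsch with affine-free linear gap penalty. Returns the number
# of indels/mismatches on the optimal path and, when gapless, the template
# index matched to each query position. Ties prefer diagonal moves.
align_global <- function(query, ref, match, mismatch, indel) {
  n <- length(query); m <- length(ref)
  S <- matrix(0, n + 1, m + 1)
  S[, 1] <- (0:n) * indel
  S[1, ] <- (0:m) * indel
  for (i in seq_len(n)) {
    sub <- ifelse(query[i] == ref, match, mismatch)
    for (j in seq_len(m)) {
      S[i + 1, j + 1] <- max(S[i, j] + sub[j],
                             S[i, j + 1] + indel,
                             S[i + 1, j] + indel)
    }
  }
  i <- n; j <- m
  n_indel <- 0L; n_mismatch <- 0L
  match_index <- integer(n)
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 &&
        S[i + 1, j + 1] == S[i, j] +
          (if (query[i] == ref[j]) match else mismatch)) {
      if (query[i] != ref[j]) n_mismatch <- n_mismatch + 1L
      match_index[i] <- j
      i <- i - 1; j <- j - 1
    } else if (i > 0 && S[i + 1, j + 1] == S[i, j + 1] + indel) {
      n_indel <- n_indel + 1L
      match_index[i] <- NA_integer_
      i <- i - 1
    } else {
      n_indel <- n_indel + 1L
      j <- j - 1
    }
  }
  list(n_indel = n_indel, n_mismatch = n_mismatch,
       match_index = match_index)
}

#' Filter a performance stream, excluding repetitions with added/deleted tones
#'
#' Applies [classify_pitch_errors()] to every repetition in a stream and
#' drops excluded ones, writing `matched_event_index` on the retained rows.
#'
#' @param trials a trial tibble
#' @param melody a [make_melody_spec()] template
#' @return a list with `trials` (retained rows, with a
#'   `matched_event_index` column) and `summary` (a tibble with one row per
#'   repetition: keys, `status`, `n_events`)
#' @export
filter_pitch_errors <- function(trials, melody) {
  key <- interaction(trials$performer, trials$condition, trials$trial,
                     trials$repetition, drop = TRUE)
  pieces <- split(trials, key)
  kept <- list(); summ <- list()
  for (piece in pieces) {
    # the follower joins on the 9th tone of each trial's first repetition:
    # those repetitions are scored against the post-count-in template
    offset <- 0L
    template <- melody
    if (identical(piece$role[1], "Follower") && piece$repetition[1] == 1L) {
      template <- melody[9:32, ]
      offset <- 8L
    }
    cls <- classify_pitch_errors(piece, template)
    if (!is.null(cls$matched_event_index)) {
      cls$matched_event_index <- cls$matched_event_index + offset
    }
    summ[[length(summ) + 1L]] <- tibble::tibble(
      pair_id = piece$pair_id[1], performer = piece$performer[1],
      condition = piece$condition[1], trial = piece$trial[1],
      repetition = piece$repetition[1], status = cls$status,
      n_events = nrow(piece),
      injected_error = piece$injected_error[1]
    )
    if (cls$status != "excluded") {
      piece$matched_event_index <- cls$matched_event_index
      kept[[length(kept) + 1L]] <- piece
    }
  }
  out <- if (length(kept)) do.call(rbind, kept) else NULL
  list(trials = out, summary = do.call(rbind, summ))
}

#' Quarter-note-level inter-onset intervals of one repetition
#'
#' Performance rate is defined at the beat (quarter-note) level: off-beat
#' eighth-note onsets are excluded, and each half note is linearly
#' interpolated by inserting a virtual onset at the temporal midpoint of its
#' two-beat interval before successive differences are taken. An on-beat
#' eighth-note onset serves as its beat's onset.
#'
#' @param trial one repetition's retained events, with `matched_event_index`
#' @param melody a [make_melody_spec()] template
#' @return a list of class `ioi_series`: `values` (ms, one per beat
#'   interval), `mean_ioi_ms`, `rate_hz` (= 1000 / mean IOI), `n`
#' @export
quarter_level_iois <- function(trial, melody) {
  idx <- trial$matched_event_index
  if (is.null(idx)) stop("trial lacks matched_event_index; run the error filter first")
  on_beat <- melody$is_on_beat[idx]
  half <- melody$beat_value[idx] == 2
  onsets <- trial$onset_ms[on_beat]
  is_half <- half[on_beat]
  if (length(onsets) < 2) stop("too short: fewer than 2 beat-level onsets")
  # midpoint split of every half note that is followed by another onset
  pts <- list()
  for (k in seq_along(onsets)) {
    pts[[length(pts) + 1L]] <- onsets[k]
    if (is_half[k] && k < length(onsets)) {
      pts[[length(pts) + 1L]] <- (onsets[k] + onsets[k + 1]) / 2
    }
  }
  beat_onsets <- unlist(pts)
  values <- diff(beat_onsets)
  if (any(values <= 0)) stop("non-positive beat-level IOI")
  mean_ioi <- mean(values)
  structure(
    list(values = values, mean_ioi_ms = mean_ioi,
         rate_hz = 1000 / mean_ioi, n = length(values)),
    class = "ioi_series"
  )
}

# mean quarter-level IOI across the repetitions of a stream
mean_stream_ioi <- function(trials, melody) {
  key <- interaction(trials$trial, trials$repetition, drop = TRUE)
  vals <- vapply(split(trials, key),
                 function(p) quarter_level_iois(p, melody)$mean_ioi_ms,
                 numeric(1))
  mean(vals)
}

#' Duet tone-onset asynchronies for one leader/follower pair
#'
#' Signed asynchrony is the mean (Leader - Follower) onset difference over
#' tones the partners intended to perform simultaneously; absolute
#' asynchrony is the mean absolute difference. Both are normalized by the
#' mean duet IOI of the same performance (repetition): the average of the
#' two performers' quarter-level mean IOIs. Events are paired through
#' `matched_event_index`, so a substituted pitch does not desynchronize the
#' pairing; the leader's 8-tone count-in has no follower onsets and drops
#' out of the pairing automatically.
#'
#' @param leader_trials,follower_trials retained streams (post filter) of
#'   the two partners in one condition
#' @param melody a [make_melody_spec()] template
#' @return a list of class `asynchrony_result`: `signed_mean`,
#'   `absolute_mean` (proportions of the duet IOI), `n_events`,
#'   `per_repetition` (tibble with per-repetition values)
#' @export
duet_asynchronies <- function(leader_trials, follower_trials, melody) {
  key_L <- interaction(leader_trials$trial, leader_trials$repetition, drop = TRUE)
  key_F <- interaction(follower_trials$trial, follower_trials$repetition, drop = TRUE)
  common <- intersect(levels(droplevels(key_L)), levels(droplevels(key_F)))
  if (length(common) == 0) stop("no common repetitions between partners")
  rows <- list()
  for (k in common) {
    L <- leader_trials[key_L == k, ]
    F_ <- follower_trials[key_F == k, ]
    shared <- intersect(L$matched_event_index, F_$matched_event_index)
    shared <- shared[!is.na(shared)]
    if (length(shared) == 0) next
    dL <- L$onset_ms[match(shared, L$matched_event_index)]
    dF <- F_$onset_ms[match(shared, F_$matched_event_index)]
    ioi <- mean(c(quarter_level_iois(L, melody)$mean_ioi_ms,
                  quarter_level_iois(F_, melody)$mean_ioi_ms))
    rows[[length(rows) + 1L]] <- tibble::tibble(
      trial = L$trial[1], repetition = L$repetition[1],
      signed = mean(dL - dF) / ioi,
      absolute = mean(abs(dL - dF)) / ioi,
      duet_ioi_ms = ioi, n_events = length(shared)
    )
  }
  if (length(rows) == 0) stop("no common events between partners")
  per_rep <- do.call(rbind, rows)
  structure(
    list(signed_mean = mean(per_rep$signed),
         absolute_mean = mean(per_rep$absolute),
         n_events = sum(per_rep$n_events),
         per_repetition = per_rep),
    class = "asynchrony_result"
  )
}

#' Rank correlation of solo-rate detuning with signed duet asynchrony
#'
#' Tests the dynamical-systems prediction that how far the leader's onsets
#' precede or lag the follower's mirrors how much faster or slower the
#' leader's spontaneous (solo) rate is: a Spearman correlation of
#' (leader solo mean IOI - follower solo mean IOI) against the pair's
#' signed duet asynchrony, per condition.
#'
#' @param pairs a tibble with columns `detuning_ms` (leader minus follower
#'   solo mean IOI) and `signed_asynchrony`
#' @return a list with `rho`, `p` (two-sided), `n`
#' @export
detuning_vs_asynchrony <- function(pairs) {
  stopifnot(nrow(pairs) >= 4)
  if (stats::sd(pairs$detuning_ms) == 0 ||
      stats::sd(pairs$signed_asynchrony) == 0) {
    stop("constant input: correlation undefined")
  }
  ct <- stats::cor.test(pairs$detuning_ms, pairs$signed_asynchrony,
                        method = "spearman", exact = FALSE)
  list(rho = unname(ct$estimate), p = ct$p.value, n = nrow(pairs))
}

#' Regression of duet rate on the two partners' solo rates
#'
#' Ordinary least squares on standardized variables, quantifying whether the
#' leader's spontaneous rate dominates the pair's duet tempo.
#'
#' @param data a tibble with columns `duet_rate`, `leader_solo_rate`,
#'   `follower_solo_rate` (any consistent units)
#' @return a list with `beta_leader`, `beta_follower` (standardized),
#'   `r_squared`, `p` (overall F-test), `p_leader`, `p_follower`, `n`
#' @export
duet_rate_regression <- function(data) {
  stopifnot(nrow(data) >= 4)
  X <- scale(cbind(data$leader_solo_rate, data$follower_solo_rate))
  if (abs(stats::cor(X[, 1], X[, 2])) > 0.999) {
    stop("collinear predictors")
  }
  y <- as.numeric(scale(data$duet_rate))
  fit <- stats::lm(y ~ X[, 1] + X[, 2])
  s <- summary(fit)
  fstat <- s$fstatistic
  list(
    beta_leader = unname(stats::coef(fit)[2]),
    beta_follower = unname(stats::coef(fit)[3]),
    r_squared = s$r.squared,
    p = unname(stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)),
    p_leader = s$coefficients[2, 4],
    p_follower = s$coefficients[3, 4],
    n = nrow(data)
  )
}
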