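# Fixtures are built in code: a melody template shared across tests, and a
# constructor for perfectly timed performances at a given beat period.

melody <- make_melody_spec()

# one repetition played exactly on the grid at `period_ms` per beat,
# starting at `t0`; returns an event tibble in the simulator schema
perfect_trial <- function(period_ms = 500, t0 = 0, performer = "P1",
                          condition = "Solo", trial = 1L, repetition = 1L,
                          pitches = melody$pitch) {
  tibble::tibble(
    pair_id = 1L, performer = performer, role = "Solo",
    condition = condition, trial = trial, repetition = repetition,
    event_index = melody$event, nominal_pitch = melody$pitch,
    played_pitch = pitches,
    onset_ms = t0 + melody$beat * period_ms,
    beat_value = melody$beat_value, is_on_beat = melody$is_on_beat,
    injected_error = "none"
  )
}

# attach alignment output so measure functions can run without the filter
with_match <- function(trial) {
  cls <- classify_pitch_errors(trial, melody)
  trial$matched_event_index <- cls$matched_event_index
  trial
}

# steady-state signed onset asynchrony (ms) over the last repetition of a
# noise-free duet simulation
measured_fixed_point_ms <- function(T_L, T_F, alpha, beta = 0) {
  tc <- timing_sim_config(T_leader = T_L, T_follower = T_F, alpha = alpha,
                          beta = beta, sigma_timekeeper = 0, sigma_motor = 0,
                          n_trials = 1, n_repetitions = 3, seed = 1)
  d <- suppressWarnings(simulate_duet_timing(melody, tc))
  L <- d$leader[d$leader$repetition == 3, ]
  F_ <- d$follower[d$follower$repetition == 3, ]
  mean(L$onset_ms[match(F_$event_index, L$event_index)] - F_$onset_ms)
}
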