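#' Simulate EEG for a solo performance
#'
#' Single-performer counterpart of [simulate_duet_eeg()]: one oscillatory
#' source at the performer's own beat rate with a private amplitude
#' envelope, the same fronto-central topography, 1/f plus white background.
#' Solo recordings are what the SSD spatial filters are fitted on.
#'
#' @param trials a solo event tibble from [simulate_solo_timing()]
#' @param cfg an [eeg_sim_config()]
#' @param melody a [make_melody_spec()] template
#' @param tail_ms silence appended after the last onset
#' @return a list with `recording` (an [eeg_recording()]) and `f_source`
#' @export
simulate_solo_eeg <- function(trials, cfg, melody = make_melody_spec(),
                              tail_ms = 4000) {
  f0 <- estimate_beat_rate(list(trials), melody)
  if (f0 >= cfg$fs / 2) stop("source rate at or above Nyquist")
  n <- ceiling((max(trials$onset_ms) + tail_ms) / 1000 * cfg$fs)
  with_seed(cfg$seed, {
    bg <- cfg$bg_pink_sd * pink_noise_matrix(n, cfg$fs, cfg$n_channels) +
      matrix(rnorm(cfg$n_channels * n, 0, cfg$bg_white_sd), cfg$n_channels)
    if (identical(cfg$snr_db, -Inf)) {
      X <- bg
    } else {
      A <- softplus(2 + slow_process(n, cfg$fs, cfg$env_cutoff_hz) / 2)
      tt <- (seq_len(n) - 1) / cfg$fs
      src <- A * cos(2 * pi * f0 * tt + stats::runif(1, 0, 2 * pi))
      g <- source_gain(src, bg, cfg, f0)
      X <- outer(cfg$topography, g * src) + bg
    }
    rec <- eeg_recording(
      X, cfg$fs, cfg$channel_names,
      anchors = tibble::tibble(trial = trials$trial,
                               repetition = trials$repetition,
                               event_index = trials$event_index,
                               sample = as.integer(round(trials$onset_ms / 1000 * cfg$fs)))
    )
    list(recording = rec, f_source = f0)
  })
}

#' Pipeline configuration
#'
#' Collects every tunable of the synthetic cohort and the analysis into one
#' serializable object. Natural beat periods are drawn per performer from a
#' normal distribution (mean 470 ms, SD 65 ms, truncated to 300-650 ms),
#' matching the spread of spontaneous solo tempi reported for trained
#' pianists; all other defaults are the study conditions (6 duet trials of
#' 4 melody repetitions per condition, 3 solo trials, follower
#' phase-correction gain 0.5, 4% pitch-error rate).
#'
#' @param seed root seed; every stage derives a named substream from it
#' @param n_pairs number of duet pairs
#' @param period_mean_ms,period_sd_ms,period_range_ms natural-period
#'   distribution
#' @param alpha,beta phase-correction gains
#' @param sigma_timekeeper,sigma_motor timing noise SDs, ms
#' @param n_trials,n_repetitions duet trials per condition and repetitions
#'   per trial
#' @param solo_n_trials solo trials per performer
#' @param p_pitch_error pitch-error probability per repetition
#' @param conditions duet condition labels
#' @param rho_envelope,snr_db,distractor_alpha EEG generator controls
#'   (see [eeg_sim_config()])
#' @param with_eeg simulate and analyze EEG (turn off for purely
#'   behavioral cohorts)
#' @param surrogates compute the surrogate re-pairing null (the costly
#'   cohort-level step; requires at least 3 pairs)
#' @param out_dir if non-`NULL`, summary CSVs are written there
#' @return a list of class `run_config`
#' @export
run_config <- function(seed = 1L, n_pairs = 20L,
                       period_mean_ms = 470, period_sd_ms = 65,
                       period_range_ms = c(300, 650),
                       alpha = 0.5, beta = 0,
                       sigma_timekeeper = 10, sigma_motor = 4,
                       n_trials = 6L, n_repetitions = 4L,
                       solo_n_trials = 3L,
                       p_pitch_error = 0.04,
                       conditions = c("First-Leader", "Second-Leader"),
                       rho_envelope = 0.6, snr_db = 5,
                       distractor_alpha = FALSE,
                       with_eeg = TRUE, surrogates = TRUE, out_dir = NULL) {
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

#' Write / read a pipeline configuration as YAML
#'
#' The round trip is stable: `read_run_config(write_run_config(cfg, p))`
#' reproduces `cfg` exactly.
#'
#' @param cfg a [run_config()]
#' @param path YAML file path
#' @return the path / the configuration
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- do.call(run_config, raw[setdiff(names(raw), character(0))])
  cfg
}

#' Simulate one duet pair (behavior and optionally EEG)
#'
#' Draws both performers' natural periods, simulates solo performances,
#' both duet conditions (performer 1 leads the first, performer 2 the
#' second), injects pitch errors, and optionally generates the matching
#' solo and dual-brain EEG.
#'
#' @param cfg a [run_config()]
#' @param pair_id integer pair index (also selects the seed substream)
#' @param melody a [make_melody_spec()] template
#' @return a list with `events` (one tibble, all streams), `eeg` (or
#'   `NULL`), `periods`, `f_duet` per condition
#' @export
simulate_pair <- function(cfg, pair_id, melody = make_melody_spec()) {
  seed_of <- function(label) substream_seed(cfg$seed, sprintf("%s/pair%d", label, pair_id))
  periods <- with_seed(seed_of("periods"), {
    p <- rnorm(2, cfg$period_mean_ms, cfg$period_sd_ms)
    pmin(pmax(p, cfg$period_range_ms[1]), cfg$period_range_ms[2])
  })
  performers <- paste0("P", 1:2)
  base <- function(TL, TF, seed) {
    timing_sim_config(T_leader = TL, T_follower = TF, alpha = cfg$alpha,
                      beta = cfg$beta, sigma_timekeeper = cfg$sigma_timekeeper,
                      sigma_motor = cfg$sigma_motor, n_trials = cfg$n_trials,
                      n_repetitions = cfg$n_repetitions,
                      p_pitch_error = cfg$p_pitch_error, seed = seed)
  }
  events <- list(); eeg <- NULL
  # solo performances
  solos <- list()
  for (i in 1:2) {
    tc <- base(periods[i], periods[i], seed_of(paste0("solo", i)))
    tc$n_trials <- cfg$solo_n_trials
    solo <- simulate_solo_timing(melody, tc, period_ms = periods[i],
                                 pair_id = pair_id, performer_id = performers[i])
    solo <- inject_pitch_errors(solo, cfg$p_pitch_error,
                                seed_of(paste0("solo_err", i)))
    solos[[i]] <- solo
    events[[length(events) + 1L]] <- solo
  }
  # duet conditions
  duets <- list()
  for (ci in seq_along(cfg$conditions)) {
    lead <- if (ci == 1) 1L else 2L
    foll <- 3L - lead
    tc <- base(periods[lead], periods[foll], seed_of(paste0("duet", ci)))
    duo <- simulate_duet_timing(melody, tc, condition = cfg$conditions[ci],
                                pair_id = pair_id,
                                leader_id = performers[lead],
                                follower_id = performers[foll])
    both <- rbind(duo$leader, duo$follower)
    both <- inject_pitch_errors(both, cfg$p_pitch_error,
                                seed_of(paste0("duet_err", ci)))
    duets[[ci]] <- duo
    events[[length(events) + 1L]] <- both
  }
  events <- do.call(rbind, events)
  if (cfg$with_eeg) {
    eeg <- list(solo = list(), duet = list())
    for (i in 1:2) {
      ec <- eeg_sim_config(rho_envelope = 0, snr_db = cfg$snr_db,
                           distractor_alpha = cfg$distractor_alpha,
                           seed = seed_of(paste0("eeg_solo", i)))
      eeg$solo[[performers[i]]] <- simulate_solo_eeg(solos[[i]], ec, melody)
    }
    for (ci in seq_along(cfg$conditions)) {
      ec <- eeg_sim_config(rho_envelope = cfg$rho_envelope, snr_db = cfg$snr_db,
                           distractor_alpha = cfg$distractor_alpha,
                           seed = seed_of(paste0("eeg_duet", ci)))
      eeg$duet[[cfg$conditions[ci]]] <- simulate_duet_eeg(
        duets[[ci]]$leader, duets[[ci]]$follower, ec, melody)
    }
  }
  list(pair_id = pair_id, events = events, eeg = eeg, periods = periods,
       performers = performers)
}

# retained repetitions common to both partners of one condition
pair_retained_reps <- function(kept_leader, kept_follower) {
  kl <- unique(kept_leader[, c("trial", "repetition")])
  kf <- unique(kept_follower[, c("trial", "repetition")])
  merge(kl, kf)
}

#' Analyze one simulated (or loaded) duet pair end to end
#'
#' Runs the error filter, behavioral measures, spectral entrainment
#' measures, SSD fitting/selection on the solo EEG, and envelope
#' extraction, returning one summary row per condition plus the envelope
#' payloads needed for cohort-level surrogate analysis.
#'
#' @param sim output of [simulate_pair()]
#' @param cfg a [run_config()]
#' @param melody a [make_melody_spec()] template
#' @param scfg a [spectral_config()]
#' @return a list with `behavior` (tibble, one row per condition),
#'   `spectral` (tibble, one row per performer x condition),
#'   `envelopes` (per condition: leader/follower raw-envelope payloads and
#'   the observed AEC), `filters` (per performer), `exclusions`
#' @export
analyze_pair <- function(sim, cfg, melody = make_melody_spec(),
                         scfg = spectral_config()) {
  filt <- filter_pitch_errors(sim$events, melody)
  kept <- filt$trials
  performers <- sim$performers
  # solo rates
  solo_ioi <- sapply(performers, function(p) {
    mean_stream_ioi(kept[kept$performer == p & kept$condition == "Solo", ], melody)
  })
  behavior <- list(); spectral <- list(); env_payload <- list()
  filters <- NULL
  if (!is.null(sim$eeg)) {
    filters <- lapply(performers, function(p) {
      fitted <- fit_ssd(sim$eeg$solo[[p]]$recording)
      select_component(fitted, sim$eeg$solo[[p]]$recording, roi = scfg$roi)
    })
    names(filters) <- performers
  }
  for (ci in seq_along(cfg$conditions)) {
    cond <- cfg$conditions[ci]
    lead <- if (ci == 1) performers[1] else performers[2]
    foll <- setdiff(performers, lead)
    kl <- kept[kept$performer == lead & kept$condition == cond, ]
    kf <- kept[kept$performer == foll & kept$condition == cond, ]
    reps <- pair_retained_reps(kl, kf)
    sel <- function(tab) merge(tab, reps)[order(merge(tab, reps)$onset_ms), ]
    kl <- sel(kl); kf <- sel(kf)
    asyn <- duet_asynchronies(kl, kf, melody)
    duet_ioi <- mean(c(mean_stream_ioi(kl, melody), mean_stream_ioi(kf, melody)))
    f_duet <- 1000 / duet_ioi
    behavior[[ci]] <- tibble::tibble(
      pair_id = sim$pair_id, condition = cond,
      leader = lead, follower = foll,
      leader_solo_ioi_ms = solo_ioi[[lead]],
      follower_solo_ioi_ms = solo_ioi[[foll]],
      detuning_ms = solo_ioi[[lead]] - solo_ioi[[foll]],
      duet_ioi_ms = duet_ioi, duet_rate_hz = f_duet,
      signed_asynchrony = asyn$signed_mean,
      absolute_asynchrony = asyn$absolute_mean
    )
    if (!is.null(sim$eeg)) {
      duet_eeg <- sim$eeg$duet[[cond]]
      bounds <- repetition_boundaries(kl)
      bounds <- merge(bounds, reps)
      bounds <- bounds[order(bounds$trial, bounds$repetition), ]
      roles <- list(Leader = list(rec = duet_eeg$leader, tab = kl, who = lead),
                    Follower = list(rec = duet_eeg$follower, tab = kf, who = foll))
      env_cond <- list()
      for (role in names(roles)) {
        rec <- roles[[role]]$rec
        start_samples <- as.integer(round(bounds$start_ms / 1000 * scfg$fs))
        epochs <- suppressWarnings(epoch_fixed_window(rec, start_samples, scfg))
        mlp <- epoch_log_psd_mean(epochs, scfg)
        nn <- noise_normalize(mlp$log_power, scfg$noise_halfwidth_bins)
        rownames(nn$values) <- rec$channel_names
        nspec <- structure(list(freqs_hz = mlp$freq, values = nn$values,
                                edge = nn$edge), class = "normalized_spectrum")
        aligned <- align_to_duet_rate(nspec, f_duet, scfg)
        ch_mean <- colMeans(aligned$values)
        roi_m <- roi_mean(aligned$values, scfg$roi)
        pv_ch <- peak_values(ch_mean, scfg$peak_halfwidth_bins)
        pv_roi <- peak_values(roi_m, scfg$peak_halfwidth_bins)
        spectral[[length(spectral) + 1L]] <- tibble::tibble(
          pair_id = sim$pair_id, condition = cond, role = role,
          performer = roles[[role]]$who,
          psd_center_channel_mean = pv_ch$center,
          psd_neighbor_channel_mean = pv_ch$neighbor_mean,
          psd_center_roi = pv_roi$center,
          psd_neighbor_roi = pv_roi$neighbor_mean
        )
        # envelope payload for this performer
        flt <- filters[[roles[[role]]$who]]$filter
        envs <- suppressWarnings(
          extract_envelope(rec, flt, f_duet, bounds))
        anchors <- envelope_anchors(envs, kl, kf, role, bounds)
        env_cond[[tolower(role)]] <- list(
          raw = lapply(envs, `[[`, "samples"),
          anchors = anchors,
          trials = vapply(envs, `[[`, integer(1), "trial"),
          repetitions = vapply(envs, `[[`, integer(1), "repetition")
        )
      }
      # observed AEC on the pair's common grid
      L <- env_cond$leader; F_ <- env_cond$follower
      m <- grid_density(c(L$anchors, F_$anchors), melody)
      eL <- lapply(seq_along(L$raw), function(k)
        event_resample(L$raw[[k]], L$anchors[[k]], melody, m))
      eF <- lapply(seq_along(F_$raw), function(k)
        event_resample(F_$raw[[k]], F_$anchors[[k]], melody, m))
      obs <- aec(eL, eF, L$trials, L$repetitions, m)
      env_payload[[cond]] <- c(env_cond, list(observed = obs, m = m))
    }
  }
  list(behavior = do.call(rbind, behavior),
       spectral = if (length(spectral)) do.call(rbind, spectral) else NULL,
       envelopes = if (length(env_payload)) env_payload else NULL,
       filters = filters,
       exclusions = filt$summary)
}

# anchor vectors (33 values: events 1..32 plus repetition end) for each
# extracted envelope; the follower's missing count-in onsets are taken
# from the leader (intended-simultaneous events on the shared clock)
envelope_anchors <- function(envs, kl, kf, role, bounds) {
  lapply(envs, function(e) {
    own <- if (role == "Leader") kl else kf
    other <- if (role == "Leader") kf else kl
    o <- own[own$trial == e$trial & own$repetition == e$repetition, ]
    alt <- other[other$trial == e$trial & other$repetition == e$repetition, ]
    onset <- rep(NA_real_, 32)
    onset[o$matched_event_index] <- o$onset_ms
    miss <- which(is.na(onset))
    if (length(miss)) onset[miss] <- alt$onset_ms[match(miss, alt$matched_event_index)]
    if (anyNA(onset)) stop("unresolvable event anchors")
    end_ms <- bounds$end_ms[bounds$trial == e$trial & bounds$repetition == e$repetition]
    onset_anchor_samples(c(onset, end_ms), e$start_ms, e$fs)
  })
}

#' Run the full synthetic-cohort pipeline
#'
#' Simulates `n_pairs` duet pairs, analyzes each end to end, and assembles
#' the cohort-level statistics: detuning-asynchrony rank correlations and
#' duet-rate regressions per condition, Wilcoxon spectral peak tests
#' (channel mean and fronto-central ROI) per condition, PSD-synchrony
#' correlations per role and condition, and the observed-versus-surrogate
#' amplitude-envelope comparison with its exact binomial test. Re-running
#' with the same configuration and seed reproduces every output exactly.
#'
#' @param cfg a [run_config()]
#' @param melody a [make_melody_spec()] template
#' @param scfg a [spectral_config()]
#' @param progress print one line per pair
#' @return a list of class `duetsync_results` with elements `behavior`,
#'   `spectral`, `exclusions`, `detuning_correlation`, `rate_regression`,
#'   `peak_tests`, `psd_synchrony`, `aec` (per-pair observed and surrogate
#'   values plus the binomial test), and `config`
#' @export
run_pipeline <- function(cfg = run_config(), melody = make_melody_spec(),
                         scfg = spectral_config(), progress = FALSE) {
  behavior <- list(); spectral <- list(); exclus <- list()
  env_by_cond <- list()
  for (p in seq_len(cfg$n_pairs)) {
    sim <- simulate_pair(cfg, p, melody)
    res <- analyze_pair(sim, cfg, melody, scfg)
    behavior[[p]] <- res$behavior
    exclus[[p]] <- res$exclusions
    if (!is.null(res$spectral)) spectral[[p]] <- res$spectral
    if (!is.null(res$envelopes)) {
      for (cond in names(res$envelopes)) {
        env_by_cond[[cond]][[p]] <- res$envelopes[[cond]]
      }
    }
    if (progress) message(sprintf("pair %d/%d done", p, cfg$n_pairs))
  }
  behavior <- do.call(rbind, behavior)
  exclusions <- do.call(rbind, exclus)
  out <- list(behavior = behavior, exclusions = exclusions, config = cfg)
  # cohort behavioral statistics
  out$detuning_correlation <- lapply(stats::setNames(cfg$conditions, cfg$conditions),
    function(cond) {
      b <- behavior[behavior$condition == cond, ]
      detuning_vs_asynchrony(tibble::tibble(
        detuning_ms = b$detuning_ms, signed_asynchrony = b$signed_asynchrony))
    })
  out$rate_regression <- lapply(stats::setNames(cfg$conditions, cfg$conditions),
    function(cond) {
      b <- behavior[behavior$condition == cond, ]
      duet_rate_regression(tibble::tibble(
        duet_rate = 1000 / b$duet_ioi_ms,
        leader_solo_rate = 1000 / b$leader_solo_ioi_ms,
        follower_solo_rate = 1000 / b$follower_solo_ioi_ms))
    })
  if (length(spectral)) {
    spectral <- do.call(rbind, spectral)
    out$spectral <- spectral
    out$peak_tests <- lapply(stats::setNames(cfg$conditions, cfg$conditions),
      function(cond) {
        s <- spectral[spectral$condition == cond, ]
        list(channel_mean = peak_test(s$psd_center_channel_mean,
                                      s$psd_neighbor_channel_mean),
             roi = peak_test(s$psd_center_roi, s$psd_neighbor_roi))
      })
    out$psd_synchrony <- lapply(stats::setNames(cfg$conditions, cfg$conditions),
      function(cond) {
        s <- spectral[spectral$condition == cond, ]
        b <- behavior[behavior$condition == cond, ]
        lapply(stats::setNames(c("Leader", "Follower"), c("Leader", "Follower")),
          function(role) {
            sr <- s[s$role == role, ]
            sr <- sr[match(b$pair_id, sr$pair_id), ]
            psd_synchrony_correlation(sr$psd_center_channel_mean,
                                      b$absolute_asynchrony)
          })
      })
  }
  if (length(env_by_cond)) {
    conds <- names(env_by_cond)
    obs_z <- sur_z <- matrix(NA_real_, cfg$n_pairs, length(conds),
                             dimnames = list(NULL, conds))
    for (cond in conds) {
      payload <- env_by_cond[[cond]]
      obs_z[, cond] <- vapply(payload, function(x) x$observed$fisher_z_mean,
                              numeric(1))
      if (isTRUE(cfg$surrogates) && cfg$n_pairs >= 3) {
        sur <- surrogate_aecs(payload, melody)
        sur_z[, cond] <- sur$surrogate_z_mean
      }
    }
    observed_r <- fisher_r(rowMeans(obs_z))
    surrogate_r <- fisher_r(rowMeans(sur_z))
    aec_tab <- tibble::tibble(pair_id = seq_len(cfg$n_pairs),
                              observed_r = observed_r,
                              surrogate_r = surrogate_r)
    out$aec <- list(pairs = aec_tab,
                    mean_observed_r = fisher_r(mean(rowMeans(obs_z))),
                    binomial = if (!anyNA(surrogate_r))
                      binomial_comparison(observed_r, surrogate_r) else NULL)
  }
  class(out) <- "duetsync_results"
  if (!is.null(cfg$out_dir)) write_results(out, cfg$out_dir)
  out
}

#' Write the cohort summary tables as CSV
#'
#' @param results a `duetsync_results` bundle
#' @param dir output directory (created if needed)
#' @return the directory, invisibly
#' @export
write_results <- function(results, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(results$behavior, file.path(dir, "behavior.csv"),
                   row.names = FALSE)
  utils::write.csv(results$exclusions, file.path(dir, "exclusions.csv"),
                   row.names = FALSE)
  if (!is.null(results$spectral)) {
    utils::write.csv(results$spectral, file.path(dir, "spectral.csv"),
                     row.names = FALSE)
  }
  if (!is.null(results$aec)) {
    utils::write.csv(results$aec$pairs, file.path(dir, "aec.csv"),
                     row.names = FALSE)
  }
  invisible(dir)
}
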