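# Synthetic EEG for the intermittent-rivalry paradigm.
#
# Each display onset (S1 and S2) evokes three stereotyped components:
# a posterior P1, a posterior N1, and a broad centro-parietal late positivity
# (LP). Component waveforms are Gaussian-windowed half-period cosines (the LP
# uses an asymmetric raised-cosine ramp peaking at 400 ms and decaying to
# 800 ms); scalp patterns are Gaussian falloffs in geodesic distance from a
# component-specific centre (parieto-occipital for P1/N1, vertex for the LP),
# optionally replaced by forward-projected dipoles from a gain matrix.
#
# The two predictive effects are injected on rivalry trials whose percept
# changes at the second display: the S1 N1 is deepened by
# `n1_extra_negativity_uV` and the S1 late positivity is reduced by
# `lp_reduction_uV`. Fusion trials never carry outcome-dependent S1 effects.

.POSTERIOR_CENTER <- c(0, sin(-54 * pi / 180), cos(-54 * pi / 180))  # POz
.CENTRAL_CENTER <- c(0, 0, 1)                                        # Cz
.FRONTAL_CENTER <- c(0, sin(72 * pi / 180), cos(72 * pi / 180))      # Fpz

#' ERP component and effect parameters
#'
#' Amplitudes are in microvolts at the component's scalp centre; latencies and
#' widths in milliseconds post display onset. The study reports no component
#' amplitudes, so base amplitudes are conventional visual-ERP magnitudes and
#' the effect sizes are free parameters. Setting the four `*_extra`/
#' `*_reduction`/`*_boost` effect amplitudes to zero yields a null dataset in
#' which no condition differences exist (used for Type-I calibration).
#'
#' @param p1_amplitude_uV,p1_latency_ms,p1_width_ms Posterior P1.
#' @param n1_amplitude_uV,n1_latency_ms,n1_width_ms Posterior N1 (negative).
#' @param lp_amplitude_uV,lp_onset_ms,lp_peak_ms,lp_offset_ms Central late
#'   positivity, rising from `lp_onset_ms` to a peak at `lp_peak_ms` and
#'   decaying to zero at `lp_offset_ms`.
#' @param n1_extra_negativity_uV Extra S1 N1 negativity (in microvolts, added
#'   with negative sign) on rivalry trials whose percept later changes.
#' @param lp_reduction_uV Reduction of the S1 late positivity on the same
#'   trials.
#' @param s2_lp_reduction_uV Second-display analogue: post-S2 300-800 ms
#'   voltage is more negative on rivalry change trials.
#' @param s2_fusion_change_boost Fractional P1/N1 enlargement after S2 on
#'   fusion trials whose gratings changed physically.
#' @param posterior_topo_width,central_topo_width Gaussian scalp-topography
#'   scale (radians of geodesic distance).
#' @return An `effect_params` list.
#' @export
effect_params <- function(p1_amplitude_uV = 5, p1_latency_ms = 100,
                          p1_width_ms = 80,
                          n1_amplitude_uV = -8, n1_latency_ms = 180,
                          n1_width_ms = 110,
                          lp_amplitude_uV = 6, lp_onset_ms = 300,
                          lp_peak_ms = 400, lp_offset_ms = 800,
                          n1_extra_negativity_uV = 2, lp_reduction_uV = 1.5,
                          s2_lp_reduction_uV = 2, s2_fusion_change_boost = 0.3,
                          posterior_topo_width = 0.6,
                          central_topo_width = 0.9) {
  p <- as.list(environment())
  stopifnot(all(vapply(p, is.numeric, logical(1))),
            all(is.finite(unlist(p))))
  if (p1_latency_ms < 0 || n1_latency_ms < 0 || lp_onset_ms < 0) {
    stopf("component latencies must be non-negative")
  }
  if (!(lp_onset_ms < lp_peak_ms && lp_peak_ms < lp_offset_ms)) {
    stopf("late positivity requires onset < peak < offset")
  }
  structure(p, class = "effect_params")
}

#' Zero out all condition-dependent effect amplitudes
#'
#' @param effects An [effect_params()] object.
#' @return The same object with every predictive effect set to 0 (base
#'   components untouched), i.e. a null-hypothesis generator.
#' @export
null_effects <- function(effects = effect_params()) {
  effects$n1_extra_negativity_uV <- 0
  effects$lp_reduction_uV <- 0
  effects$s2_lp_reduction_uV <- 0
  effects$s2_fusion_change_boost <- 0
  effects
}

#' Background and artifact noise parameters
#'
#' @param background_rms_uV RMS of the 1/f-shaped background EEG per channel.
#' @param background_exponent Spectral exponent of the background (amplitude
#'   proportional to f^(-exponent/2)).
#' @param sensor_white_rms_uV RMS of additive white sensor noise.
#' @param blink_rate_hz Poisson rate of eye blinks.
#' @param blink_amplitude_uV Blink peak amplitude at the vertical EOG; the
#'   default deliberately exceeds the 60 uV EOG rejection bound.
#' @param blink_width_ms Gaussian SD of the blink transient.
#' @return A `noise_params` list.
#' @export
noise_params <- function(background_rms_uV = 8, background_exponent = 1,
                         sensor_white_rms_uV = 1, blink_rate_hz = 0.1,
                         blink_amplitude_uV = 200, blink_width_ms = 60) {
  p <- as.list(environment())
  if (any(unlist(p) < 0)) stopf("noise parameters must be non-negative")
  structure(p, class = "noise_params")
}

# Gaussian-windowed half-period cosine peaking (value 1) at `lat`.
.component_wave <- function(times_ms, lat, width) {
  u <- times_ms - lat
  env <- exp(-0.5 * (u / (width / 2.355))^2)
  carrier <- cos(pi * u / (2 * width))
  ifelse(abs(u) <= width, env * carrier, 0)
}

# Asymmetric raised-cosine bump: 0 at onset, 1 at peak, 0 at offset.
.lp_wave <- function(times_ms, onset, peak, offset) {
  w <- numeric(length(times_ms))
  up <- times_ms >= onset & times_ms <= peak
  dn <- times_ms > peak & times_ms <= offset
  w[up] <- (1 - cos(pi * (times_ms[up] - onset) / (peak - onset))) / 2
  w[dn] <- (1 + cos(pi * (times_ms[dn] - peak) / (offset - peak))) / 2
  w
}

# Gaussian-geodesic scalp weights (1 at the centre direction).
.topo_weights <- function(montage, center, width) {
  d <- geodesic_dist(montage_positions(montage), center)
  exp(-0.5 * (d / width)^2)
}

# Scalp pattern from a gain matrix: radial dipole at the voxel nearest
# 0.75 * center direction, normalised to unit maximum over scalp channels.
.gain_topo <- function(gain, montage, center) {
  grid <- attr(gain, "grid")
  chans <- attr(gain, "channels")
  tgt <- 0.75 * center
  d2 <- (grid$x - tgt[1])^2 + (grid$y - tgt[2])^2 + (grid$z - tgt[3])^2
  v <- which.min(d2)
  rv <- .norm3(c(grid$x[v], grid$y[v], grid$z[v]))
  g <- gain[, 3L * (v - 1L) + 1:3, drop = FALSE] %*% rv
  w <- numeric(nrow(montage))
  idx <- match(chans, montage$name)
  if (anyNA(idx)) stopf("gain matrix channels not all present in montage")
  w[idx] <- g / max(abs(g))
  w
}

# Reference a channels x samples matrix (or a weight vector) the way the
# amplifier / offline re-referencing would.
.apply_reference <- function(x, montage, state) {
  ref_of <- function(rows) {
    if (is.matrix(x)) colMeans(x[rows, , drop = FALSE]) else mean(x[rows])
  }
  if (state == "recording_reference") {
    i <- which(montage$name == "FCz")
    if (length(i) == 0L) return(x)  # reference electrode outside this subset
    r <- ref_of(i)
  } else if (state == "linked_earlobes") {
    i <- which(montage$role == "earlobe")
    if (length(i) < 2L) return(x)
    r <- ref_of(i)
  } else {
    return(x)
  }
  if (is.matrix(x)) sweep(x, 2, r) else x - r
}

# Amplitudes of the three components for one display of one trial type.
.display_amplitudes <- function(effects, stimulus, change, display) {
  p1 <- effects$p1_amplitude_uV
  n1 <- effects$n1_amplitude_uV
  lp <- effects$lp_amplitude_uV
  if (stimulus == "rivalry" && isTRUE(change)) {
    if (display == 1L) {
      n1 <- n1 - effects$n1_extra_negativity_uV
      lp <- lp - effects$lp_reduction_uV
    } else {
      lp <- lp - effects$s2_lp_reduction_uV
    }
  }
  if (stimulus == "fusion" && isTRUE(change) && display == 2L) {
    p1 <- p1 * (1 + effects$s2_fusion_change_boost)
    n1 <- n1 * (1 + effects$s2_fusion_change_boost)
  }
  c(p1 = p1, n1 = n1, lp = lp)
}

# Noiseless channels x samples response to one display, on a relative time
# base (ms since display onset), before any referencing.
.display_response <- function(times_ms, amps, effects, topo_post, topo_cent) {
  wav <- amps[["p1"]] *
    .component_wave(times_ms, effects$p1_latency_ms, effects$p1_width_ms) +
    amps[["n1"]] *
    .component_wave(times_ms, effects$n1_latency_ms, effects$n1_width_ms)
  lp <- amps[["lp"]] *
    .lp_wave(times_ms, effects$lp_onset_ms, effects$lp_peak_ms,
             effects$lp_offset_ms)
  outer(topo_post, wav) + outer(topo_cent, lp)
}

#' Noiseless condition-mean ERP predicted by the generator
#'
#' Returns the channels-by-samples signal a participant's condition-averaged
#' ERP converges to (S1-locked, including the second-display response at
#' 1200 ms), under the requested reference. This is the analytic expectation
#' against which parameter-recovery checks compare pipeline output.
#'
#' @param condition One of `rivalry_changed`, `rivalry_same`,
#'   `fusion_changed`, `fusion_same`.
#' @param effects [effect_params()].
#' @param montage Montage `data.frame`.
#' @param times_ms Epoch time base in ms relative to S1 onset.
#' @param reference `"linked_earlobes"` (default, the analysis reference),
#'   `"recording_reference"`, or `"none"`.
#' @param gain Optional gain matrix (see [make_leadfield()]) from which scalp
#'   patterns are derived instead of the Gaussian topography templates.
#' @return Matrix channels x samples (microvolts), rownames = channel names.
#' @export
erp_signal <- function(condition, effects = effect_params(),
                       montage = default_montage(),
                       times_ms = seq(-100, 2000, by = 2),
                       reference = "linked_earlobes", gain = NULL) {
  condition <- match.arg(condition, c("rivalry_changed", "rivalry_same",
                                      "fusion_changed", "fusion_same"))
  stimulus <- sub("_.*", "", condition)
  change <- endsWith(condition, "changed")
  if (is.null(gain)) {
    topo_post <- .topo_weights(montage, .POSTERIOR_CENTER,
                               effects$posterior_topo_width)
    topo_cent <- .topo_weights(montage, .CENTRAL_CENTER,
                               effects$central_topo_width)
  } else {
    topo_post <- .gain_topo(gain, montage, .POSTERIOR_CENTER)
    topo_cent <- .gain_topo(gain, montage, .CENTRAL_CENTER)
  }
  sig <- .display_response(times_ms,
                           .display_amplitudes(effects, stimulus, change, 1L),
                           effects, topo_post, topo_cent) +
    .display_response(times_ms - (TRIAL_MS[["s1"]] + TRIAL_MS[["gap"]]),
                      .display_amplitudes(effects, stimulus, change, 2L),
                      effects, topo_post, topo_cent)
  rownames(sig) <- montage$name
  .apply_reference(sig, montage, reference)
}

# Map a trial row to its event code / label.
.trial_event <- function(condition, outcome, response_correct) {
  if (condition == "rivalry") {
    switch(outcome,
           changed = c(1L, "S1_rivalry_changed"),
           same = c(2L, "S1_rivalry_same"),
           no_response = c(3L, "S1_rivalry_noresponse"))
  } else if (isTRUE(response_correct)) {
    if (outcome == "changed") c(4L, "S1_fusion_change_correct")
    else c(5L, "S1_fusion_same_correct")
  } else {
    c(6L, "S1_fusion_incorrect")
  }
}

# 1/f-shaped Gaussian noise, one column per channel, each scaled to `rms`.
.one_over_f <- function(n, n_ch, exponent, rms) {
  w <- matrix(stats::rnorm(n * n_ch), n, n_ch)
  if (exponent <= 0) return(w * rms / apply(w, 2, stats::sd))
  f <- c(0, pmin(seq_len(n - 1), n - seq_len(n - 1)))
  scale <- c(0, f[-1]^(-exponent / 2))
  shaped <- Re(stats::mvfft(stats::mvfft(w) * scale, inverse = TRUE)) / n
  sweep(shaped, 2, rms / apply(shaped, 2, stats::sd), `*`)
}

#' Simulate a continuous EEG recording for a trial table
#'
#' Produces a channels-by-samples recording (microvolts) at `fs` Hz spanning
#' all trials, with every S1/S2 onset evoking the component waveforms of
#' [effect_params()], outcome-dependent effects injected on rivalry change
#' trials, 1/f background plus white sensor noise, event markers for each
#' display onset, and data referenced at the recording reference (FCz, whose
#' own trace is therefore flat until re-referencing).
#'
#' @param trials Trial table with outcomes (see [simulate_behavior()]).
#' @param effects [effect_params()].
#' @param noise [noise_params()] (blinks are added separately by
#'   [inject_blinks()]).
#' @param montage Montage `data.frame`.
#' @param gain Optional gain matrix for forward-projected topographies.
#' @param fs Sampling rate in Hz (the study recorded at 500 Hz).
#' @param pad_ms Recording lead-in before the first S1 onset (and tail after
#'   the last trial), so the first epoch's baseline and the filter's edge
#'   region lie inside the record.
#' @param seed Optional seed.
#' @return An `eeg_recording`: list with `data` (channels x samples matrix),
#'   `fs`, `montage`, `events` (`data.frame` sample/code/label),
#'   `reference_state`, and the `trials` table.
#' @export
simulate_recording <- function(trials, effects = effect_params(),
                               noise = noise_params(),
                               montage = default_montage(), gain = NULL,
                               fs = 500, pad_ms = 2000, seed = NULL) {
  if (anyNA(trials$outcome)) {
    stopf("trials must carry outcomes; run simulate_behavior() first")
  }
  if (!is.null(gain) && !identical(sort(attr(gain, "channels")),
                                   sort(montage$name[montage$role == "scalp"]))) {
    stopf("gain matrix channels do not match the montage's scalp channels")
  }
  n_ch <- nrow(montage)
  pad <- round(pad_ms * fs / 1000)
  n_smp <- round((max(trials$s1_onset_ms) + TRIAL_TOTAL_MS) * fs / 1000) +
    2L * pad + 1L
  if (is.null(gain)) {
    topo_post <- .topo_weights(montage, .POSTERIOR_CENTER,
                               effects$posterior_topo_width)
    topo_cent <- .topo_weights(montage, .CENTRAL_CENTER,
                               effects$central_topo_width)
  } else {
    topo_post <- .gain_topo(gain, montage, .POSTERIOR_CENTER)
    topo_cent <- .gain_topo(gain, montage, .CENTRAL_CENTER)
  }
  # response support: components end by lp_offset_ms
  t_rel <- seq(0, ceiling(effects$lp_offset_ms / 100) * 100, by = 1000 / fs)
  len <- length(t_rel)
  resp_cache <- new.env(parent = emptyenv())
  response_for <- function(stimulus, change, display) {
    key <- paste(stimulus, change, display)
    if (is.null(resp_cache[[key]])) {
      amps <- .display_amplitudes(effects, stimulus, change, display)
      resp_cache[[key]] <- .display_response(t_rel, amps, effects,
                                             topo_post, topo_cent)
    }
    resp_cache[[key]]
  }
  with_seed(seed, {
    dat <- if (noise$background_rms_uV > 0) {
      t(.one_over_f(n_smp, n_ch, noise$background_exponent,
                    noise$background_rms_uV))
    } else {
      matrix(0, n_ch, n_smp)
    }
    if (noise$sensor_white_rms_uV > 0) {
      dat <- dat + matrix(stats::rnorm(n_ch * n_smp,
                                       sd = noise$sensor_white_rms_uV),
                          n_ch, n_smp)
    }
    events <- vector("list", 3L * nrow(trials))
    s2_off <- TRIAL_MS[["s1"]] + TRIAL_MS[["gap"]]
    for (i in seq_len(nrow(trials))) {
      tr <- trials[i, ]
      change1 <- tr$condition == "rivalry" && tr$outcome == "changed"
      change2 <- if (tr$condition == "rivalry") tr$outcome == "changed"
                 else isTRUE(tr$s2_physical_change)
      o1 <- round(tr$s1_onset_ms * fs / 1000) + pad + 1L
      o2 <- o1 + round(s2_off * fs / 1000)
      idx1 <- o1:(o1 + len - 1L)
      idx2 <- o2:(o2 + len - 1L)
      dat[, idx1] <- dat[, idx1] + response_for(tr$condition, change1, 1L)
      dat[, idx2] <- dat[, idx2] + response_for(tr$condition, change2, 2L)
      ev <- .trial_event(tr$condition, tr$outcome, tr$response_correct)
      events[[3L * i - 2L]] <- data.frame(sample = o1,
                                          code = as.integer(ev[1]),
                                          label = ev[2])
      events[[3L * i - 1L]] <- data.frame(sample = o2, code = 10L,
                                          label = "S2_onset")
      events[[3L * i]] <- data.frame(
        sample = o2 + round(TRIAL_MS[["s2"]] * fs / 1000), code = 11L,
        label = "mask_onset")
    }
    dat <- .apply_reference(dat, montage, "recording_reference")
    rownames(dat) <- montage$name
    structure(list(data = dat, fs = fs, montage = montage,
                   events = do.call(rbind, events),
                   reference_state = "recording_reference",
                   trials = trials),
              class = "eeg_recording")
  })
}

#' Add blink artifacts to a recording
#'
#' Blink transients (Gaussian time course, frontal-dominant spatial decay,
#' peak `blink_amplitude_uV` at the vertical EOG) are placed at Poisson times,
#' or at explicitly supplied `times_ms`. The returned recording carries the
#' ground-truth blink times in `$blinks_ms` for rejection testing.
#'
#' @param raw An `eeg_recording`.
#' @param noise [noise_params()] supplying rate, amplitude and width.
#' @param seed Optional seed.
#' @param times_ms Optional explicit blink peak times (overrides the Poisson
#'   draw).
#' @return The recording with blinks added and `blinks_ms` recorded.
#' @export
inject_blinks <- function(raw, noise = noise_params(), seed = NULL,
                          times_ms = NULL) {
  m <- raw$montage
  if (!any(m$role == "eog")) stopf("montage has no EOG channels")
  dur_ms <- (ncol(raw$data) - 1L) / raw$fs * 1000
  with_seed(seed, {
    if (is.null(times_ms)) {
      if (noise$blink_rate_hz <= 0) {
        raw$blinks_ms <- numeric(0)
        return(raw)
      }
      n_exp <- stats::rpois(1, noise$blink_rate_hz * dur_ms / 1000)
      times_ms <- sort(stats::runif(n_exp, 0, dur_ms))
    }
    w <- numeric(nrow(m))
    w[m$role == "eog" & startsWith(m$name, "VEOG")] <- 1
    w[m$role == "eog" & startsWith(m$name, "HEOG")] <- 0.3
    scalp <- m$role == "scalp"
    d <- geodesic_dist(montage_positions(m)[scalp, , drop = FALSE],
                       .FRONTAL_CENTER)
    w[scalp] <- 0.8 * exp(-0.5 * (d / 0.5)^2)
    w[m$role == "earlobe"] <- 0.05
    w <- .apply_reference(w, m, raw$reference_state)
    half <- ceiling(3.5 * noise$blink_width_ms * raw$fs / 1000)
    t_rel <- (-half:half) / raw$fs * 1000
    shape <- exp(-0.5 * (t_rel / noise$blink_width_ms)^2)
    for (tm in times_ms) {
      ctr <- round(tm * raw$fs / 1000) + 1L
      idx <- (ctr - half):(ctr + half)
      ok <- idx >= 1L & idx <= ncol(raw$data)
      raw$data[, idx[ok]] <- raw$data[, idx[ok]] +
        noise$blink_amplitude_uV * outer(w, shape[ok])
    }
    raw$blinks_ms <- times_ms
    raw
  })
}

#' Simulate participant-level condition-averaged ERPs directly
#'
#' Fast path for simulation studies: generates the `erp_set` that the full
#' epoch-and-average pipeline would converge to, i.e. the noiseless
#' condition-mean signal of [erp_signal()] scaled by a participant-specific
#' amplitude factor, plus residual ERP noise whose per-cell SD is
#' `noise_sd_uV` (the noise left after trial averaging). Noise is temporally
#' white by default, which makes cell-level binomial calibration checks exact;
#' `smooth_sd_ms > 0` applies Gaussian temporal smoothing instead.
#'
#' @param n_participants Number of participants (the study analysed 11).
#' @param effects [effect_params()].
#' @param montage Montage (already subset to the channels of interest).
#' @param times_ms Epoch time base.
#' @param noise_sd_uV Residual ERP noise SD per (channel, sample) cell.
#' @param participant_sd SD of the participant amplitude factor around 1.
#' @param smooth_sd_ms Gaussian SD of optional temporal noise smoothing (0 =
#'   white).
#' @param n_trials Nominal trials averaged per condition (bookkeeping only).
#' @param seed Optional seed.
#' @return An `erp_set` (see [average_erps()]).
#' @export
simulate_erp_study <- function(n_participants = 11,
                               effects = effect_params(),
                               montage = default_montage(),
                               times_ms = seq(-100, 2000, by = 2),
                               noise_sd_uV = 1, participant_sd = 0.2,
                               smooth_sd_ms = 0, n_trials = 120,
                               seed = NULL) {
  conds <- c("rivalry_changed", "rivalry_same", "fusion_changed",
             "fusion_same")
  base <- lapply(conds, erp_signal, effects = effects, montage = montage,
                 times_ms = times_ms, reference = "linked_earlobes")
  names(base) <- conds
  n_ch <- nrow(montage)
  n_smp <- length(times_ms)
  dt <- if (n_smp > 1) diff(times_ms[1:2]) else 1
  kern <- NULL
  if (smooth_sd_ms > 0) {
    half <- ceiling(3 * smooth_sd_ms / dt)
    kern <- stats::dnorm((-half:half) * dt, sd = smooth_sd_ms)
    kern <- kern / sqrt(sum(kern^2))  # preserve marginal SD
  }
  with_seed(seed, {
    dat <- array(NA_real_,
                 dim = c(n_participants, length(conds), n_ch, n_smp),
                 dimnames = list(sprintf("P%02d", seq_len(n_participants)),
                                 conds, montage$name, NULL))
    for (p in seq_len(n_participants)) {
      mult <- 1 + participant_sd * stats::rnorm(1)
      for (ci in seq_along(conds)) {
        eps <- matrix(stats::rnorm(n_ch * n_smp, sd = noise_sd_uV),
                      n_ch, n_smp)
        if (!is.null(kern)) {
          eps <- t(apply(eps, 1, function(x) {
            stats::filter(c(rev(x[seq_along(kern)]), x,
                            rev(x[n_smp + 1 - seq_along(kern)])),
                          kern, sides = 2)[length(kern) + seq_len(n_smp)]
          }))
        }
        dat[p, ci, , ] <- mult * base[[ci]] + eps
      }
    }
    structure(list(data = dat, times_ms = times_ms, montage = montage,
                   conditions = conds,
                   n_trials = matrix(n_trials, n_participants, length(conds),
                                     dimnames = dimnames(dat)[1:2])),
              class = "erp_set")
  })
}

#' Analytic window-mean condition difference injected by the generator
#'
#' The expected changed-minus-same difference of [window_mean()] values for
#' rivalry trials, computed from the generator's own signal model. Used to
#' check that the full pipeline recovers the injected effect without bias.
#'
#' @param effects [effect_params()].
#' @param montage Montage.
#' @param window A [window_spec()].
#' @param reference Reference of the analysed data.
#' @return Scalar expected difference in microvolts.
#' @export
injected_window_difference <- function(effects, montage, window,
                                       reference = "linked_earlobes") {
  times <- seq(window$t_start_ms, window$t_end_ms - 1e-9, by = 2)
  a <- erp_signal("rivalry_changed", effects, montage, times, reference)
  b <- erp_signal("rivalry_same", effects, montage, times, reference)
  i <- match(window$electrodes, montage$name)
  if (anyNA(i)) stopf("window electrodes missing from montage")
  mean(a[i, , drop = FALSE]) - mean(b[i, , drop = FALSE])
}
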