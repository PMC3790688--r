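# Preprocessing: linked-earlobe re-referencing, Kaiser windowed sinc FIR
# bandpass filtering with group-delay compensation, S1-locked epoching with
# inclusive endpoints, baseline correction, and peak-to-peak artifact
# rejection at the study's thresholds (60 uV EOG / 150 uV EEG).

#' Bandpass FIR filter specification
#'
#' Defaults reproduce the study's filter: 0.3-35 Hz Kaiser windowed sinc FIR,
#' 1857 points, Kaiser beta 5.65326 (the beta corresponding to 60 dB design
#' attenuation). An odd tap count gives exact linear phase with an integer
#' group delay of (n_taps - 1) / 2 samples.
#'
#' @param low_hz,high_hz Band edges (-6 dB cutoffs) in Hz.
#' @param n_taps Number of coefficients; must be odd.
#' @param kaiser_beta Kaiser window shape parameter.
#' @param fs Sampling rate in Hz.
#' @return A `filter_spec` list.
#' @export
filter_spec <- function(low_hz = 0.3, high_hz = 35, n_taps = 1857,
                        kaiser_beta = 5.65326, fs = 500) {
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < fs / 2)) {
    stopf("need 0 < low_hz < high_hz < fs/2")
  }
  if (n_taps %% 2L != 1L) stopf("n_taps must be odd (got %d)", n_taps)
  structure(list(low_hz = low_hz, high_hz = high_hz, n_taps = n_taps,
                 kaiser_beta = kaiser_beta, fs = fs),
            class = "filter_spec")
}

#' Kaiser window
#'
#' @param n Window length.
#' @param beta Shape parameter.
#' @return Numeric vector of length `n`.
#' @export
kaiser_window <- function(n, beta) {
  k <- seq_len(n) - 1
  x <- beta * sqrt(pmax(0, 1 - (2 * k / (n - 1) - 1)^2))
  besselI(x, 0) / besselI(beta, 0)
}

.sinc_lowpass <- function(fc_norm, n_taps) {
  # ideal lowpass kernel, cutoff fc_norm in cycles/sample, centred
  k <- seq_len(n_taps) - 1 - (n_taps - 1) / 2
  h <- 2 * fc_norm * sin(pi * 2 * fc_norm * k) / (pi * 2 * fc_norm * k)
  h[k == 0] <- 2 * fc_norm
  h
}

#' Design the Kaiser windowed sinc bandpass filter
#'
#' The bandpass kernel is the difference of two Kaiser-windowed sinc lowpass
#' kernels (cutoffs `high_hz` and `low_hz`), each normalised to unit DC gain
#' after windowing — necessary because the near-DC lowpass is strongly
#' truncation-affected at practicable tap counts. The result is an exactly
#' symmetric (linear-phase) coefficient vector with zero DC gain.
#'
#' @param spec A [filter_spec()].
#' @return Numeric coefficient vector of length `n_taps`, with the spec
#'   attached as attribute `"spec"`.
#' @export
design_fir <- function(spec = filter_spec()) {
  stopifnot(inherits(spec, "filter_spec"))
  w <- kaiser_window(spec$n_taps, spec$kaiser_beta)
  lp <- function(fc_hz) {
    k <- .sinc_lowpass(fc_hz / spec$fs, spec$n_taps) * w
    k / sum(k)
  }
  h <- lp(spec$high_hz) - lp(spec$low_hz)
  attr(h, "spec") <- spec
  h
}

#' Frequency response magnitude of an FIR filter
#'
#' @param coeffs FIR coefficients.
#' @param freq_hz Frequencies at which to evaluate.
#' @param fs Sampling rate (taken from the coefficients' spec if present).
#' @return Magnitude response (linear scale) at `freq_hz`.
#' @export
fir_response <- function(coeffs, freq_hz, fs = NULL) {
  fs <- fs %||% attr(coeffs, "spec")$fs
  if (is.null(fs)) stopf("supply fs or coefficients from design_fir()")
  k <- seq_along(coeffs) - 1
  vapply(freq_hz, function(f) {
    Mod(sum(coeffs * exp(-2i * pi * f * k / fs)))
  }, numeric(1))
}

#' Filter a recording with group-delay compensation
#'
#' Single-pass linear-phase FIR convolution; the output is shifted back by
#' the integer group delay `(n_taps - 1) / 2` so event latencies are
#' preserved. The first and last `(n_taps - 1) / 2` samples are edge-affected
#' and flagged via the recording's `edge_invalid` field.
#'
#' @param raw An `eeg_recording` longer than the kernel.
#' @param coeffs Coefficients from [design_fir()].
#' @return The filtered recording.
#' @export
filter_apply <- function(raw, coeffs) {
  n <- ncol(raw$data)
  L <- length(coeffs)
  if (n <= L) stopf("record (%d samples) not longer than kernel (%d taps)", n, L)
  M <- (L - 1L) %/% 2L
  nfft <- stats::nextn(n + L - 1L, 2)
  H <- stats::fft(c(coeffs, numeric(nfft - L)))
  out <- raw$data
  chunk <- max(1L, floor(2^24 / nfft))  # bound complex work matrix ~512 MB
  for (start in seq(1L, nrow(out), by = chunk)) {
    rows <- start:min(nrow(out), start + chunk - 1L)
    X <- stats::mvfft(rbind(t(raw$data[rows, , drop = FALSE]),
                            matrix(0, nfft - n, length(rows))))
    Y <- Re(stats::mvfft(X * H, inverse = TRUE)) / nfft
    out[rows, ] <- t(Y[(M + 1L):(M + n), , drop = FALSE])
  }
  raw$data <- out
  raw$edge_invalid <- M
  raw$filtered <- TRUE
  raw
}

#' Re-reference a recording to the linked earlobes
#'
#' Subtracts the mean of the two earlobe channels from every channel, turning
#' the former recording reference (FCz) into an ordinary scalp channel.
#' Re-referencing an already linked-earlobe recording is an error.
#'
#' @param raw An `eeg_recording` in `recording_reference` state.
#' @param targets Names of the earlobe channels (default: the montage's
#'   `earlobe` role channels).
#' @return The re-referenced recording (`reference_state = "linked_earlobes"`).
#' @export
rereference <- function(raw, targets = NULL) {
  if (!identical(raw$reference_state, "recording_reference")) {
    stopf("recording is already re-referenced (state: %s)",
          raw$reference_state)
  }
  targets <- targets %||% raw$montage$name[raw$montage$role == "earlobe"]
  if (length(targets) != 2L || !all(targets %in% rownames(raw$data))) {
    stopf("need both earlobe channels present (got: %s)",
          paste(targets, collapse = ", "))
  }
  ref <- colMeans(raw$data[targets, , drop = FALSE])
  raw$data <- sweep(raw$data, 2, ref)
  raw$reference_state <- "linked_earlobes"
  raw
}

#' Epoch specification
#'
#' The study's 2100-ms analysis window: -100 to 2000 ms around S1 onset with a
#' baseline from -100 to 0 ms. Both window endpoints are inclusive on the
#' sample grid, so at 500 Hz an epoch holds 2100/2 + 1 = 1051 samples.
#'
#' @param tmin_ms,tmax_ms Epoch limits in ms relative to the locking event.
#' @param baseline Length-2 baseline interval in ms (inclusive).
#' @return An `epoch_spec` list.
#' @export
epoch_spec <- function(tmin_ms = -100, tmax_ms = 2000,
                       baseline = c(-100, 0)) {
  if (!(tmin_ms < 0 && tmax_ms >= 0)) stopf("need tmin_ms < 0 <= tmax_ms")
  if (baseline[1] < tmin_ms || baseline[2] > tmax_ms) {
    stopf("baseline must lie within the epoch window")
  }
  structure(list(tmin_ms = tmin_ms, tmax_ms = tmax_ms, baseline = baseline),
            class = "epoch_spec")
}

#' Extract event-locked epochs
#'
#' Cuts one epoch per S1 event (codes 1-6), inclusive of both endpoints.
#' Epochs that would overlap the record boundaries are dropped and counted.
#'
#' @param raw A filtered, re-referenced `eeg_recording`.
#' @param espec An [epoch_spec()].
#' @param lock `"S1"` (the only supported lock; S2 responses live inside the
#'   S1-locked window).
#' @return An `epoch_set`: list with `data` (trials x channels x samples),
#'   `times_ms`, `meta` (event sample/code/label and the mapped analysis
#'   condition), `keep` (logical mask, all `TRUE` initially), `montage`,
#'   `fs`, and `n_dropped_boundary`.
#' @export
extract_epochs <- function(raw, espec = epoch_spec(), lock = "S1") {
  stopifnot(identical(lock, "S1"))
  ev <- raw$events[raw$events$code %in% 1:6, , drop = FALSE]
  if (nrow(ev) == 0L) stopf("no S1 events in recording")
  fs <- raw$fs
  off <- round(espec$tmin_ms * fs / 1000):round(espec$tmax_ms * fs / 1000)
  n_smp <- length(off)
  ok <- ev$sample + off[1L] >= 1L & ev$sample + off[n_smp] <= ncol(raw$data)
  n_drop <- sum(!ok)
  if (n_drop > 0L) {
    message(sprintf("dropping %d epoch(s) overlapping record boundaries",
                    n_drop))
  }
  ev <- ev[ok, , drop = FALSE]
  dat <- array(NA_real_, dim = c(nrow(ev), nrow(raw$data), n_smp),
               dimnames = list(NULL, rownames(raw$data), NULL))
  for (i in seq_len(nrow(ev))) {
    dat[i, , ] <- raw$data[, ev$sample[i] + off, drop = FALSE]
  }
  cond_map <- c(S1_rivalry_changed = "rivalry_changed",
                S1_rivalry_same = "rivalry_same",
                S1_fusion_change_correct = "fusion_changed",
                S1_fusion_same_correct = "fusion_same")
  meta <- data.frame(sample = ev$sample, code = ev$code, label = ev$label,
                     condition = unname(cond_map[ev$label]),
                     stringsAsFactors = FALSE)
  structure(list(data = dat, times_ms = off * 1000 / fs, meta = meta,
                 keep = rep(TRUE, nrow(ev)), montage = raw$montage, fs = fs,
                 n_dropped_boundary = n_drop, baselined = FALSE),
            class = "epoch_set")
}

#' Baseline-correct epochs
#'
#' Subtracts, per epoch and channel, the mean voltage over the baseline
#' interval (inclusive of both endpoints). Idempotent.
#'
#' @param epochs An `epoch_set`.
#' @param baseline Baseline interval in ms (default the interval recorded at
#'   epoching).
#' @return The corrected `epoch_set`.
#' @export
baseline_correct <- function(epochs, baseline = c(-100, 0)) {
  sel <- epochs$times_ms >= baseline[1] & epochs$times_ms <= baseline[2]
  if (!any(sel)) stopf("baseline interval contains no samples")
  bl <- apply(epochs$data[, , sel, drop = FALSE], c(1, 2), mean)
  epochs$data <- epochs$data - as.vector(bl)  # recycles over samples
  epochs$baselined <- TRUE
  epochs
}

#' Peak-to-peak rejection thresholds
#'
#' @param eog_p2p_uV Threshold for EOG channels (study: 60 uV).
#' @param eeg_p2p_uV Threshold for scalp EEG channels (study: 150 uV).
#' @return A `rejection_spec` list.
#' @export
rejection_spec <- function(eog_p2p_uV = 60, eeg_p2p_uV = 150) {
  if (eog_p2p_uV <= 0 || eeg_p2p_uV <= 0) stopf("thresholds must be > 0")
  structure(list(eog_p2p_uV = eog_p2p_uV, eeg_p2p_uV = eeg_p2p_uV),
            class = "rejection_spec")
}

#' Reject artifact-contaminated epochs
#'
#' Marks `keep = FALSE` for any epoch whose within-epoch peak-to-peak voltage
#' exceeds the EOG threshold on any EOG channel or the EEG threshold on any
#' scalp channel. Counts per criterion are attached as the `rejection_report`
#' field.
#'
#' @param epochs An `epoch_set`.
#' @param rspec A [rejection_spec()].
#' @return The `epoch_set` with its `keep` mask updated (an epoch already
#'   marked `FALSE` stays `FALSE`).
#' @export
reject_artifacts <- function(epochs, rspec = rejection_spec()) {
  m <- epochs$montage
  eog <- which(m$role == "eog")
  scalp <- which(m$role == "scalp")
  n_tr <- dim(epochs$data)[1L]
  bad_eog <- bad_eeg <- logical(n_tr)
  for (i in seq_len(n_tr)) {
    p2p <- apply(epochs$data[i, , , drop = TRUE], 1, function(x) {
      r <- range(x); r[2] - r[1]
    })
    bad_eog[i] <- any(p2p[eog] > rspec$eog_p2p_uV)
    bad_eeg[i] <- any(p2p[scalp] > rspec$eeg_p2p_uV)
  }
  epochs$keep <- epochs$keep & !bad_eog & !bad_eeg
  epochs$rejection_report <- list(
    n_epochs = n_tr,
    n_rejected_eog = sum(bad_eog),
    n_rejected_eeg = sum(bad_eeg),
    n_rejected = sum(bad_eog | bad_eeg),
    n_kept = sum(epochs$keep),
    thresholds = unclass(rspec)
  )
  epochs
}
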