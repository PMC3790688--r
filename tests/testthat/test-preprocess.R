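# Filtering, re-referencing, epoching, baseline, and artifact rejection.

zero_recording <- function(montage, n_smp, fs = 500) {
  dat <- matrix(0, nrow(montage), n_smp)
  rownames(dat) <- montage$name
  structure(list(data = dat, fs = fs, montage = montage,
                 events = data.frame(sample = integer(0), code = integer(0),
                                     label = character(0)),
                 reference_state = "recording_reference", trials = NULL),
            class = "eeg_recording")
}

test_that("filter kernel is symmetric with near-zero DC gain", {
  h <- fir_coeffs()
  expect_equal(length(h), 1857)
  expect_lt(max(abs(unclass(h) - rev(unclass(h)))), 1e-15)
  expect_lt(abs(sum(h)), 1e-12)
  expect_error(filter_spec(n_taps = 100), "odd")
  expect_error(filter_spec(low_hz = 40, high_hz = 35), "low_hz < high_hz")
})

test_that("steady-state sinusoid gain matches the transfer function", {
  m <- test_montage()[1:2, ]
  fs <- 500
  n <- 6000
  t <- (seq_len(n) - 1) / fs
  raw <- zero_recording(m, n)
  raw$data[1, ] <- sin(2 * pi * 10 * t)
  raw$data[2, ] <- 100  # DC offset
  out <- filter_apply(raw, fir_coeffs())
  mid <- 2500:3499  # away from edges, an integer number of cycles
  gain10 <- sqrt(2 * mean(out$data[1, mid]^2))
  expect_equal(gain10, fir_response(fir_coeffs(), 10), tolerance = 1e-3)
  expect_lt(max(abs(out$data[2, mid])), 100 * 10^(-50 / 20))
})

test_that("group delay is compensated: impulse stays put, shifts commute", {
  m <- test_montage()[1, , drop = FALSE]
  n <- 5000
  k <- 2500
  raw <- zero_recording(m, n)
  raw$data[1, k] <- 1
  out <- filter_apply(raw, fir_coeffs())
  expect_equal(which.max(out$data[1, ]), k)
  expect_equal(out$edge_invalid, (1857 - 1) / 2)
  # shift-equivariance
  shift <- 40
  raw2 <- zero_recording(m, n)
  raw2$data[1, k + shift] <- 1
  out2 <- filter_apply(raw2, fir_coeffs())
  interior <- (1000 + shift):(n - 1000)
  expect_equal(out2$data[1, interior], out$data[1, interior - shift],
               tolerance = 1e-12)
  expect_error(filter_apply(zero_recording(m, 100), fir_coeffs()),
               "not longer than kernel")
})

test_that("linked-earlobe re-referencing subtracts the earlobe mean once", {
  m <- test_montage()
  raw <- zero_recording(m, 100)
  set.seed(1)
  raw$data[] <- rnorm(length(raw$data))
  ct <- sin(seq_len(100) / 5)
  raw$data["A1", ] <- ct
  raw$data["A2", ] <- ct
  before <- raw$data
  out <- rereference(raw)
  expect_equal(out$data, sweep(before, 2, ct), ignore_attr = TRUE)
  expect_equal(out$reference_state, "linked_earlobes")
  # earlobes themselves: channel - mean(earlobes) sums to zero
  expect_equal(colSums(out$data[c("A1", "A2"), ]), rep(0, 100))
  expect_error(rereference(out), "already re-referenced")
  # zero earlobes leave data unchanged
  raw2 <- zero_recording(m, 50)
  raw2$data[] <- 3
  raw2$data[c("A1", "A2"), ] <- 0
  expect_equal(rereference(raw2)$data[m$name == "Cz", ], rep(3, 50))
})

test_that("epoching yields 1051 inclusive samples and drops boundary events", {
  m <- test_montage()[1:3, ]
  raw <- zero_recording(m, 3000)
  raw$events <- data.frame(sample = c(1L, 600L, 1500L, 2990L),
                           code = c(1L, 1L, 2L, 2L),
                           label = c("S1_rivalry_changed",
                                     "S1_rivalry_changed",
                                     "S1_rivalry_same", "S1_rivalry_same"))
  expect_message(ep <- extract_epochs(raw), "dropping 2 epoch")
  expect_equal(dim(ep$data), c(2, 3, 1051))
  expect_equal(range(ep$times_ms), c(-100, 2000))
  expect_equal(ep$meta$sample, c(600L, 1500L))
  expect_equal(ep$meta$condition, c("rivalry_changed", "rivalry_same"))
  expect_error(extract_epochs(zero_recording(m, 100)), "no S1 events")
})

test_that("baseline correction zeroes the baseline mean and is idempotent", {
  m <- test_montage()[1:2, ]
  raw <- zero_recording(m, 3000)
  raw$events <- data.frame(sample = 1000L, code = 1L,
                           label = "S1_rivalry_changed")
  raw$data[1, ] <- 5
  raw$data[2, ] <- seq_len(3000)  # linear ramp
  ep <- extract_epochs(raw)
  bc <- baseline_correct(ep)
  expect_equal(max(abs(bc$data[1, 1, ])), 0)
  bl <- bc$times_ms >= -100 & bc$times_ms <= 0
  expect_equal(mean(bc$data[1, 2, bl]), 0, tolerance = 1e-10)
  bc2 <- baseline_correct(bc)
  expect_equal(bc2$data, bc$data)
})

test_that("peak-to-peak rejection applies the 60/150 uV role thresholds", {
  m <- test_montage()
  raw <- zero_recording(m, 4500)
  raw$events <- data.frame(sample = c(500L, 1800L, 3100L), code = 1L,
                           label = "S1_rivalry_changed")
  ep <- baseline_correct(extract_epochs(raw))
  out <- reject_artifacts(ep)
  expect_true(all(out$keep))  # all-zero epochs all kept
  # 200 uV spike on one EOG channel inside epoch 2 only
  ep2 <- ep
  ep2$data[2, which(m$name == "VEOGU"), 500] <- 200
  out2 <- reject_artifacts(ep2)
  expect_equal(out2$keep, c(TRUE, FALSE, TRUE))
  expect_equal(out2$rejection_report$n_rejected_eog, 1)
  # 100 uV on a scalp channel: over EOG bound but under the 150 uV EEG bound
  ep3 <- ep
  ep3$data[1, which(m$name == "Oz"), 300] <- 100
  expect_true(all(reject_artifacts(ep3)$keep))
  ep3$data[1, which(m$name == "Oz"), 300] <- 160
  expect_equal(reject_artifacts(ep3)$keep, c(FALSE, TRUE, TRUE))
  # infinite thresholds keep everything (monotone limit)
  out4 <- reject_artifacts(ep2, rejection_spec(Inf, Inf))
  expect_true(all(out4$keep))
})

test_that("raising thresholds never rejects more epochs", {
  m <- test_montage()
  set.seed(4)
  raw <- zero_recording(m, 6000)
  raw$data[] <- rnorm(length(raw$data), sd = 30)
  raw$events <- data.frame(sample = seq(200L, 4800L, by = 1150L), code = 1L,
                           label = "S1_rivalry_changed")
  ep <- baseline_correct(extract_epochs(raw))
  kept <- vapply(c(20, 60, 120, 500), function(th) {
    sum(reject_artifacts(ep, rejection_spec(th, th * 2.5))$keep)
  }, numeric(1))
  expect_true(all(diff(kept) >= 0))
})

test_that("rejected epochs equal ground-truth blink epochs end to end", {
  m <- test_montage()
  # clean background so only blinks can trip the thresholds
  noise <- noise_params(background_rms_uV = 0, sensor_white_rms_uV = 0.1,
                        blink_amplitude_uV = 200)
  tr <- simulate_behavior(make_design(1, 8, seed = 21), seed = 22)
  raw <- simulate_recording(tr, montage = m, noise = noise, seed = 23)
  # blink peaks centred in epochs 2 and 5, plus one in trial 7's ITI
  # (times are in recording time: S1 event samples include the lead-in pad)
  s1_ms <- (raw$events$sample[raw$events$code %in% 1:6] - 1) / raw$fs * 1000
  blink_in <- s1_ms[c(2, 5)] + 1000
  blink_out <- s1_ms[7] + 4000  # 2000..5100 ms post-S1 is outside any epoch
  raw <- inject_blinks(raw, noise, times_ms = c(blink_in, blink_out))
  raw <- filter_apply(rereference(raw), fir_coeffs())
  ep <- reject_artifacts(baseline_correct(extract_epochs(raw)))
  expect_equal(which(!ep$keep), c(2L, 5L))
})
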