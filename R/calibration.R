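# Simulation studies over the generator: Type-I calibration of the
# spatiotemporal t-maps and power / parameter recovery for the windowed
# repeated-measures ANOVA.

#' Type-I calibration of pointwise and permutation t-maps
#'
#' Runs `n_datasets` replicate studies of `n_participants` each through
#' [simulate_erp_study()] restricted to the ROI's electrodes and window
#' (white ERP noise, so cell-level significance counts are exactly binomial)
#' and measures the fraction of ROI cells flagged at the maps' alpha:
#' for the rivalry changed-vs-same contrast under a null generator, for the
#' same contrast by sign-flip permutation, and for the fusion contrast under
#' an effect-bearing generator (the negative control: fusion S1 responses
#' never depend on the later percept, so any fusion significance is Type-I
#' error by construction).
#'
#' @param n_datasets Number of replicate studies.
#' @param n_participants Participants per study.
#' @param effects Effect parameters for the effect-bearing (fusion-control)
#'   branch; the rivalry branches always use [null_effects()].
#' @param noise_sd_uV Residual ERP noise SD.
#' @param montage Montage; defaults to the ROI channels of the default
#'   montage (plus nothing else — the calibration needs no other channels).
#' @param roi ROI specification.
#' @param seed Master seed.
#' @return List with per-map mean significant fractions (`pointwise`,
#'   `permutation`, `fusion`), the per-dataset fractions, cell counts, and
#'   the 99% binomial band around alpha for the pooled cell count.
#' @export
calibrate_type1 <- function(n_datasets = 200, n_participants = 11,
                            effects = effect_params(), noise_sd_uV = 1,
                            montage = NULL, roi = NULL, seed = 1) {
  full <- default_montage()
  roi <- roi %||% roi_spec(full)
  montage <- montage %||%
    montage_subset(full, roi$electrodes, keep_support = FALSE)
  times <- seq(roi$t_start_ms, roi$t_end_ms - 1e-9, by = 2)
  seeds <- spawn_seeds(seed, n_datasets)
  frac <- matrix(NA_real_, n_datasets, 3L,
                 dimnames = list(NULL, c("pointwise", "permutation",
                                         "fusion")))
  for (r in seq_len(n_datasets)) {
    null_set <- simulate_erp_study(n_participants, null_effects(effects),
                                   montage, times, noise_sd_uV,
                                   participant_sd = 0.2, seed = seeds[r])
    pw <- pointwise_tmap(null_set, "rivalry_changed", "rivalry_same",
                         alpha = roi$alpha)
    pm <- permutation_tmap(null_set, "rivalry_changed", "rivalry_same",
                           alpha = roi$alpha)
    eff_set <- simulate_erp_study(n_participants, effects, montage, times,
                                  noise_sd_uV, participant_sd = 0.2,
                                  seed = seeds[r] + 1L)
    fu <- pointwise_tmap(eff_set, "fusion_changed", "fusion_same",
                         alpha = roi$alpha)
    frac[r, ] <- c(roi_count(pw, roi)$fraction,
                   roi_count(pm, roi)$fraction,
                   roi_count(fu, roi)$fraction)
  }
  n_cells <- length(roi$electrodes) * length(times)
  total <- n_datasets * n_cells
  band <- roi$alpha + c(-1, 1) * stats::qnorm(0.995) *
    sqrt(roi$alpha * (1 - roi$alpha) / total)
  list(pointwise = mean(frac[, "pointwise"]),
       permutation = mean(frac[, "permutation"]),
       fusion = mean(frac[, "fusion"]),
       per_dataset = frac, n_cells = n_cells, n_total = total,
       alpha = roi$alpha, band99 = band)
}

#' Power and recovery of the N1 window ANOVA
#'
#' Replicates the 170-190 ms parieto-occipital window analysis on studies
#' with a known injected N1 effect: per replicate, the changed-vs-same
#' repeated-measures ANOVA on rivalry window means, and the recovered
#' changed-minus-same window difference. The injected effect's analytic
#' window-mean value comes from [injected_window_difference()].
#'
#' @param n_replicates Number of replicate studies.
#' @param n_participants Participants per study.
#' @param n1_extra_negativity_uV Injected extra N1 negativity; the default is
#'   three times the ERP noise SD.
#' @param noise_sd_uV Residual ERP noise SD.
#' @param alpha ANOVA rejection level.
#' @param seed Master seed.
#' @return List with `power` (rejection fraction), `mean_recovered`,
#'   `expected` (analytic injected difference), `ci99` of the mean recovered
#'   difference, and the per-replicate values.
#' @export
power_n1 <- function(n_replicates = 100, n_participants = 11,
                     n1_extra_negativity_uV = 3, noise_sd_uV = 1,
                     alpha = 0.05, seed = 1) {
  full <- default_montage()
  win <- default_windows(full)$posterior
  effects <- effect_params(n1_extra_negativity_uV = n1_extra_negativity_uV)
  montage <- montage_subset(full, win$electrodes, keep_support = TRUE)
  times <- seq(win$t_start_ms, win$t_end_ms - 1e-9, by = 2)
  expected <- injected_window_difference(effects, montage, win)
  seeds <- spawn_seeds(seed, n_replicates)
  pvals <- diffs <- numeric(n_replicates)
  for (r in seq_len(n_replicates)) {
    es <- simulate_erp_study(n_participants, effects, montage, times,
                             noise_sd_uV, participant_sd = 0.2,
                             seed = seeds[r])
    wm <- window_mean(es, win)
    riv <- wm[wm$condition %in% c("rivalry_changed", "rivalry_same"), ]
    an <- rm_anova(riv, within = "condition")
    pvals[r] <- an$p[1L]
    ag <- tapply(riv$value, riv$condition, mean)
    diffs[r] <- ag[["rivalry_changed"]] - ag[["rivalry_same"]]
  }
  se <- stats::sd(diffs) / sqrt(n_replicates)
  ci <- mean(diffs) + c(-1, 1) * stats::qt(0.995, n_replicates - 1) * se
  list(power = mean(pvals < alpha), mean_recovered = mean(diffs),
       expected = expected, ci99 = ci, p_values = pvals,
       recovered = diffs)
}
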