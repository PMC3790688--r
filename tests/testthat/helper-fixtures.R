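# Shared fixtures: a reduced montage (full ROI + both analysis clusters +
# support channels) and the study filter, built once per test run.

ROI10 <- c("PO9", "PO7", "PO3", "POz", "PO4", "PO8", "PO10", "O1", "Oz", "O2")
POST6 <- c("PO3", "POz", "PO4", "O1", "Oz", "O2")
CENT6 <- c("FC1", "FCz", "FC2", "C1", "Cz", "C2")

test_montage <- function() {
  montage_subset(default_montage(), unique(c(ROI10, CENT6, "Fz", "Pz")))
}

fir_coeffs <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- design_fir(filter_spec())
    cache
  }
})

# Simulate one participant end to end (continuous record -> cleaned epochs).
simulate_participant_epochs <- function(seed, n_blocks = 2,
                                        trials_per_block = 8,
                                        effects = effect_params(),
                                        noise = noise_params(),
                                        montage = test_montage(),
                                        blinks = FALSE) {
  tr <- make_design(n_blocks, trials_per_block, seed = seed)
  tr <- simulate_behavior(tr, seed = seed + 1L)
  raw <- simulate_recording(tr, effects, noise, montage, seed = seed + 2L)
  if (blinks) raw <- inject_blinks(raw, noise, seed = seed + 3L)
  raw <- rereference(raw)
  raw <- filter_apply(raw, fir_coeffs())
  ep <- baseline_correct(extract_epochs(raw))
  reject_artifacts(ep)
}

# Independent repeated-measures ANOVA oracle via stats::aov error strata.
aov_oracle <- function(data, within, subject = "participant") {
  data[[subject]] <- factor(data[[subject]])
  for (w in within) data[[w]] <- factor(data[[w]])
  rhs <- paste(within, collapse = "*")
  form <- stats::as.formula(sprintf(
    "value ~ %s + Error(%s/(%s))", rhs, subject, rhs))
  fit <- summary(stats::aov(form, data = data))
  out <- list()
  for (stratum in fit) {
    tab <- stratum[[1L]]
    eff <- trimws(rownames(tab))
    for (i in which(eff != "Residuals")) {
      out[[eff[i]]] <- c(F = tab$`F value`[i], df1 = tab$Df[i],
                         df2 = tab$Df[eff == "Residuals"],
                         p = tab$`Pr(>F)`[i],
                         ss = tab$`Sum Sq`[i],
                         ss_e = tab$`Sum Sq`[eff == "Residuals"])
    }
  }
  out
}
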