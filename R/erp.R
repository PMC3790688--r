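# Condition-averaged ERPs and the statistical battery: pointwise paired
# t-maps, ROI significance counting with the chi-square check, sign-flip
# permutation tests, window averages, and repeated-measures ANOVAs with
# partial eta squared.
#
# Sample conventions: the 80-250 ms ROI and all analysis windows use
# half-open intervals [start, end) on the 2-ms sample grid, the only
# convention under which the ROI holds exactly 10 x 85 = 850 cells.

.ERP_CONDITIONS <- c("rivalry_changed", "rivalry_same", "fusion_changed",
                     "fusion_same")

#' Average kept epochs into per-participant condition ERPs
#'
#' @param epoch_sets List of `epoch_set`s, one per participant (names become
#'   participant ids). Only kept epochs with a mapped analysis condition
#'   (rivalry no-response and incorrect fusion trials are unmapped) enter the
#'   averages.
#' @return An `erp_set`: list with `data` (participants x conditions x
#'   channels x samples array), `times_ms`, `montage`, `conditions`, and the
#'   per-participant `n_trials` count matrix. A participant with an empty
#'   condition cell is excluded with a warning (mirroring the study's
#'   participant-exclusion rule) and recorded in attribute `"excluded"`.
#' @export
average_erps <- function(epoch_sets) {
  stopifnot(length(epoch_sets) >= 1L)
  ids <- names(epoch_sets) %||% sprintf("P%02d", seq_along(epoch_sets))
  ids[ids == ""] <- sprintf("P%02d", which(ids == ""))
  tmpl <- epoch_sets[[1L]]
  n_ch <- dim(tmpl$data)[2L]
  n_smp <- dim(tmpl$data)[3L]
  dat <- array(NA_real_, c(length(ids), 4L, n_ch, n_smp),
               dimnames = list(ids, .ERP_CONDITIONS,
                               dimnames(tmpl$data)[[2L]], NULL))
  counts <- matrix(0L, length(ids), 4L,
                   dimnames = list(ids, .ERP_CONDITIONS))
  for (p in seq_along(epoch_sets)) {
    ep <- epoch_sets[[p]]
    if (!isTRUE(all.equal(ep$times_ms, tmpl$times_ms))) {
      stopf("epoch time bases differ across participants")
    }
    for (ci in seq_along(.ERP_CONDITIONS)) {
      sel <- which(ep$keep & !is.na(ep$meta$condition) &
                     ep$meta$condition == .ERP_CONDITIONS[ci])
      counts[p, ci] <- length(sel)
      if (length(sel)) {
        dat[p, ci, , ] <- apply(ep$data[sel, , , drop = FALSE], c(2, 3), mean)
      }
    }
  }
  empty <- rowSums(counts == 0L) > 0L
  excluded <- ids[empty]
  if (any(empty)) {
    warnf("excluding participant(s) with an empty condition cell: %s",
          paste(excluded, collapse = ", "))
    dat <- dat[!empty, , , , drop = FALSE]
    counts <- counts[!empty, , drop = FALSE]
  }
  structure(list(data = dat, times_ms = tmpl$times_ms,
                 montage = tmpl$montage, conditions = .ERP_CONDITIONS,
                 n_trials = counts),
            class = "erp_set", excluded = excluded)
}

# Participant x cell matrix of condition differences, plus geometry.
.paired_diffs <- function(erps, condition_a, condition_b) {
  stopifnot(inherits(erps, "erp_set"))
  for (cnd in c(condition_a, condition_b)) {
    if (!cnd %in% erps$conditions) stopf("unknown condition: %s", cnd)
  }
  d <- erps$data[, condition_a, , , drop = FALSE] -
    erps$data[, condition_b, , , drop = FALSE]
  n <- dim(erps$data)[1L]
  list(D = matrix(d, nrow = n), n = n,
       n_ch = dim(erps$data)[3L], n_smp = dim(erps$data)[4L],
       channels = dimnames(erps$data)[[3L]])
}

.as_stat_map <- function(tval, p, df, erps, alpha, n) {
  sig <- !is.na(p) & p < alpha
  if (anyNA(tval)) {
    warnf("%d cell(s) with zero variance: t undefined, flagged not significant",
          sum(is.na(tval)))
  }
  structure(list(t = tval, p = p, sig = sig, df = df, alpha = alpha,
                 channels = rownames(tval), times_ms = erps$times_ms, n = n),
            class = "stat_map")
}

#' Pointwise paired t-map between two conditions
#'
#' At every (electrode, sample) cell, a two-sided paired t-test across
#' participants on the A-minus-B participant-level ERP difference, with
#' df = n - 1 (df = 10 for the study's 11 participants).
#'
#' @param erps An `erp_set`.
#' @param condition_a,condition_b Condition names.
#' @param alpha Significance threshold for the `sig` mask (study: .01,
#'   uncorrected).
#' @return A `stat_map`: `t`, `p`, `sig` (channels x samples matrices), `df`,
#'   `alpha`, `channels`, `times_ms`.
#' @export
pointwise_tmap <- function(erps, condition_a, condition_b, alpha = 0.01) {
  g <- .paired_diffs(erps, condition_a, condition_b)
  if (g$n < 2L) stopf("need at least 2 participants")
  m <- colMeans(g$D)
  v <- (colSums(g$D^2) - g$n * m^2) / (g$n - 1)
  tv <- ifelse(v > 0, m / sqrt(v / g$n), NA_real_)
  p <- 2 * stats::pt(-abs(tv), df = g$n - 1)
  dim(tv) <- dim(p) <- c(g$n_ch, g$n_smp)
  rownames(tv) <- rownames(p) <- g$channels
  .as_stat_map(tv, p, g$n - 1L, erps, alpha, g$n)
}

#' Sign-flip permutation t-map
#'
#' Refers each cell's observed paired t to the distribution obtained by
#' independently negating participants' condition differences. With
#' n <= 12 participants all 2^n sign assignments are enumerated (2048 for the
#' study's 11), making the test exact and seed-free; otherwise `n_perm`
#' random assignments are drawn. Two-sided permutation p values; the
#' identity assignment is always included, so p >= 1/2^n.
#'
#' @inheritParams pointwise_tmap
#' @param n_perm Number of random sign assignments when enumeration is not
#'   used; a value below 100 draws a warning.
#' @param seed Seed for the random-assignment branch.
#' @return A `stat_map` with permutation p values (the `t` slot holds the
#'   observed t).
#' @export
permutation_tmap <- function(erps, condition_a, condition_b, n_perm = 2048,
                             seed = NULL, alpha = 0.01) {
  g <- .paired_diffs(erps, condition_a, condition_b)
  n <- g$n
  if (n < 2L) stopf("need at least 2 participants")
  full <- n <= 12L
  flips <- if (full) {
    as.matrix(expand.grid(rep(list(c(1, -1)), n)))  # row 1 = identity
  } else {
    if (n_perm < 100L) warnf("n_perm = %d is very small", n_perm)
    with_seed(seed, {
      f <- matrix(sample(c(1, -1), n_perm * n, replace = TRUE), n_perm, n)
      f[1L, ] <- 1  # include the observed assignment
      f
    })
  }
  n_f <- nrow(flips)
  m_obs <- colMeans(g$D)
  ss <- colSums(g$D^2)
  v_obs <- (ss - n * m_obs^2) / (n - 1)
  t_obs <- ifelse(v_obs > 0, m_obs / sqrt(v_obs / n), NA_real_)
  p <- rep(NA_real_, length(t_obs))
  chunk <- max(1L, floor(4e6 / n_f))
  for (start in seq(1L, length(t_obs), by = chunk)) {
    cols <- start:min(length(t_obs), start + chunk - 1L)
    M <- (flips %*% g$D[, cols, drop = FALSE]) / n
    Vp <- (rep(ss[cols], each = n_f) - n * M^2) / (n - 1)
    Tp <- abs(M) * sqrt(n) / sqrt(Vp)
    # threshold at the identity assignment's own |t| (row 1), so the
    # observed case counts itself even where t is numerically delicate
    thr <- rep(Tp[1L, ] * (1 - 1e-12), each = n_f)
    cnt <- colSums(matrix(Tp >= thr, n_f))
    p[cols] <- ifelse(is.na(t_obs[cols]), NA_real_, cnt / n_f)
  }
  tv <- t_obs
  dim(tv) <- dim(p) <- c(g$n_ch, g$n_smp)
  rownames(tv) <- rownames(p) <- g$channels
  .as_stat_map(tv, p, n - 1L, erps, alpha, n)
}

#' Spatiotemporal region of interest
#'
#' The study's pre-declared ROI: the parieto-occipital/occipital electrodes
#' (all channels with row label `PO` or `O`; 10 in the default montage) over
#' 80-250 ms. Samples follow the half-open convention `[t_start, t_end)`, so
#' at 500 Hz the window holds 85 samples and the ROI 850 cells.
#'
#' @param montage Montage supplying the default electrode list.
#' @param electrodes Electrode names (default: row label `PO` or `O`).
#' @param t_start_ms,t_end_ms Window in ms.
#' @param alpha Per-cell significance level.
#' @return A `roi_spec` list.
#' @export
roi_spec <- function(montage = default_montage(), electrodes = NULL,
                     t_start_ms = 80, t_end_ms = 250, alpha = 0.01) {
  electrodes <- electrodes %||%
    montage$name[montage$row_label %in% c("PO", "O")]
  if (length(electrodes) == 0L) stopf("empty ROI electrode set")
  if (!(alpha > 0 && alpha < 1)) stopf("alpha must lie in (0, 1)")
  structure(list(electrodes = electrodes, t_start_ms = t_start_ms,
                 t_end_ms = t_end_ms, alpha = alpha),
            class = "roi_spec")
}

#' Count significant cells inside the ROI
#'
#' @param map A `stat_map`.
#' @param roi A [roi_spec()].
#' @return List with `count` (significant cells), `n_cells` (grid size; 850
#'   at the defaults), `n_electrodes`, `n_samples`, and the fraction.
#' @export
roi_count <- function(map, roi = roi_spec()) {
  i <- match(roi$electrodes, map$channels)
  if (anyNA(i)) {
    stopf("ROI electrodes missing from map: %s",
          paste(roi$electrodes[is.na(i)], collapse = ", "))
  }
  j <- which(map$times_ms >= roi$t_start_ms & map$times_ms < roi$t_end_ms)
  if (length(j) == 0L) stopf("ROI window contains no samples")
  sig <- map$sig[i, j, drop = FALSE]
  list(count = sum(sig), n_cells = length(sig),
       n_electrodes = length(i), n_samples = length(j),
       fraction = mean(sig))
}

#' One-degree-of-freedom chi-square on a significance count
#'
#' Goodness-of-fit chi-square comparing the observed number of significant
#' tests against the count expected under the null (`n_tests * alpha`), over
#' the two cells significant / not significant:
#' chi2 = (O - E)^2 / E + (O - E)^2 / (N - E). For the study's ROI
#' (34 significant of 850 at alpha .01, expectation 8.5) this gives
#' chi2(1) = 77.27.
#'
#' @param observed Number of significant tests.
#' @param n_tests Total number of tests.
#' @param alpha Nominal per-test level.
#' @return List with `chi2`, `df` (1), `p`, `observed`, `expected`.
#' @export
count_chisq <- function(observed, n_tests, alpha) {
  if (!(alpha > 0 && alpha < 1)) stopf("alpha must lie in (0, 1)")
  if (observed < 0 || observed > n_tests) {
    stopf("observed must lie in [0, n_tests]")
  }
  e <- n_tests * alpha
  chi2 <- (observed - e)^2 / e + (observed - e)^2 / (n_tests - e)
  list(chi2 = chi2, df = 1L,
       p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       observed = observed, expected = e)
}

#' Electrode-cluster analysis window
#'
#' Window presets follow the study: the N1 window 170-190 ms over a
#' parieto-occipital cluster and the late-positivity window 380-420 ms over a
#' central cluster, each of six electrodes. Samples are half-open
#' `[t_start, t_end)` (10 and 20 samples at 500 Hz).
#'
#' @param electrodes Cluster electrode names.
#' @param t_start_ms,t_end_ms Window in ms.
#' @return A `window_spec` list.
#' @export
window_spec <- function(electrodes, t_start_ms, t_end_ms) {
  if (length(electrodes) == 0L) stopf("empty electrode cluster")
  if (!(t_start_ms < t_end_ms)) stopf("need t_start_ms < t_end_ms")
  structure(list(electrodes = electrodes, t_start_ms = t_start_ms,
                 t_end_ms = t_end_ms),
            class = "window_spec")
}

#' Default six-electrode clusters
#'
#' @param montage Montage (cluster membership is configuration, not fact; the
#'   study shows its clusters only schematically).
#' @return List with `posterior` (PO/O) and `central` (FC/C) window specs at
#'   the study's windows.
#' @export
default_windows <- function(montage = default_montage()) {
  list(
    posterior = window_spec(c("PO3", "POz", "PO4", "O1", "Oz", "O2"),
                            170, 190),
    central = window_spec(c("FC1", "FCz", "FC2", "C1", "Cz", "C2"),
                          380, 420)
  )
}

#' Window-averaged voltage per participant and condition
#'
#' @param erps An `erp_set`.
#' @param window A [window_spec()].
#' @return `data.frame` with columns `participant`, `condition`, `value`
#'   (mean microvolts over the cluster's electrodes and the window's
#'   half-open sample range).
#' @export
window_mean <- function(erps, window) {
  i <- match(window$electrodes, dimnames(erps$data)[[3L]])
  if (anyNA(i)) {
    stopf("unknown electrode(s): %s",
          paste(window$electrodes[is.na(i)], collapse = ", "))
  }
  j <- which(erps$times_ms >= window$t_start_ms &
               erps$times_ms < window$t_end_ms)
  if (length(j) == 0L) stopf("window contains no samples")
  ids <- dimnames(erps$data)[[1L]]
  out <- expand.grid(participant = ids, condition = erps$conditions,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$value <- mapply(function(p, cnd) {
    mean(erps$data[p, cnd, i, j])
  }, out$participant, out$condition)
  out
}

#' Repeated-measures ANOVA with partial eta squared
#'
#' Sums-of-squares decomposition for fully crossed one- or two-way
#' within-subject designs with one observation per cell. Each effect is
#' tested against its own subject-by-effect interaction; partial eta squared
#' is SS_effect / (SS_effect + SS_error). For a single two-level factor, F
#' equals the squared paired t.
#'
#' @param data Long-format `data.frame`.
#' @param dv Name of the response column.
#' @param within Character vector of one or two within-subject factor
#'   columns.
#' @param subject Name of the subject id column.
#' @return `data.frame` of class `anova_rm` with one row per effect:
#'   `effect`, `df1`, `df2`, `ss`, `ss_error`, `F`, `p`, `pes`.
#' @export
rm_anova <- function(data, dv = "value", within, subject = "participant") {
  if (!length(within) %in% 1:2) stopf("one or two within factors supported")
  cols <- c(subject, within, dv)
  if (!all(cols %in% names(data))) {
    stopf("missing columns: %s", paste(setdiff(cols, names(data)),
                                       collapse = ", "))
  }
  f <- lapply(data[within], function(x) factor(x, levels = unique(x)))
  s <- factor(data[[subject]], levels = unique(data[[subject]]))
  y <- data[[dv]]
  cnt <- table(c(list(s), f))
  if (any(cnt == 0L)) stopf("missing cells in the within-subject design")
  if (any(cnt > 1L)) stopf("more than one observation per cell; aggregate first")
  Y <- tapply(y, c(list(s), f), identity)  # subjects x A (x B)
  n <- dim(Y)[1L]
  if (n < 2L) stopf("need at least 2 subjects")
  G <- mean(Y)
  res <- list()
  if (length(within) == 1L) {
    a <- dim(Y)[2L]
    mA <- colMeans(Y); mS <- rowMeans(Y)
    ss_a <- n * sum((mA - G)^2)
    ss_as <- sum((Y - outer(mS, rep(1, a)) - outer(rep(1, n), mA) + G)^2)
    res[[within]] <- c(ss = ss_a, ss_e = ss_as, df1 = a - 1,
                       df2 = (a - 1) * (n - 1))
  } else {
    a <- dim(Y)[2L]; b <- dim(Y)[3L]
    mA <- apply(Y, 2, mean); mB <- apply(Y, 3, mean)
    mS <- apply(Y, 1, mean)
    mSA <- apply(Y, c(1, 2), mean); mSB <- apply(Y, c(1, 3), mean)
    mAB <- apply(Y, c(2, 3), mean)
    ss_a <- n * b * sum((mA - G)^2)
    ss_b <- n * a * sum((mB - G)^2)
    ss_ab <- n * sum((mAB - outer(mA, rep(1, b)) -
                        outer(rep(1, a), mB) + G)^2)
    ss_as <- b * sum((mSA - outer(mS, rep(1, a)) -
                        outer(rep(1, n), mA) + G)^2)
    ss_bs <- a * sum((mSB - outer(mS, rep(1, b)) -
                        outer(rep(1, n), mB) + G)^2)
    fit <- array(0, dim(Y))
    for (i in seq_len(n)) for (jj in seq_len(a)) for (k in seq_len(b)) {
      fit[i, jj, k] <- mSA[i, jj] + mSB[i, k] + mAB[jj, k] -
        mS[i] - mA[jj] - mB[k] + G
    }
    ss_abs <- sum((Y - fit)^2)
    res[[within[1L]]] <- c(ss = ss_a, ss_e = ss_as, df1 = a - 1,
                           df2 = (a - 1) * (n - 1))
    res[[within[2L]]] <- c(ss = ss_b, ss_e = ss_bs, df1 = b - 1,
                           df2 = (b - 1) * (n - 1))
    res[[paste(within, collapse = ":")]] <-
      c(ss = ss_ab, ss_e = ss_abs, df1 = (a - 1) * (b - 1),
        df2 = (a - 1) * (b - 1) * (n - 1))
  }
  out <- do.call(rbind, lapply(names(res), function(nm) {
    x <- res[[nm]]
    ms <- x[["ss"]] / x[["df1"]]
    mse <- x[["ss_e"]] / x[["df2"]]
    Fv <- if (mse > 0) ms / mse else if (ms == 0) 0 else Inf
    data.frame(effect = nm, df1 = x[["df1"]], df2 = x[["df2"]],
               ss = x[["ss"]], ss_error = x[["ss_e"]], F = Fv,
               p = stats::pf(Fv, x[["df1"]], x[["df2"]], lower.tail = FALSE),
               pes = if (x[["ss"]] + x[["ss_e"]] > 0) {
                 x[["ss"]] / (x[["ss"]] + x[["ss_e"]])
               } else 0,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("anova_rm", "data.frame")
  out
}

#' Convert a stat map to a long data frame
#'
#' @param x A `stat_map`.
#' @param ... Unused.
#' @return `data.frame` with columns `electrode`, `time_ms`, `t`, `p`, `sig`.
#' @export
as.data.frame.stat_map <- function(x, ...) {
  data.frame(electrode = rep(x$channels, times = length(x$times_ms)),
             time_ms = rep(x$times_ms, each = length(x$channels)),
             t = as.vector(x$t), p = as.vector(x$p), sig = as.vector(x$sig),
             stringsAsFactors = FALSE)
}

#' Raster plot of a t-map
#'
#' Renders |t| (masked at the map's alpha) as an electrode-by-time raster
#' with frontal rows at the top and occipital rows at the bottom.
#'
#' @param map A `stat_map`.
#' @param montage Montage used to order electrodes by row.
#' @param main Plot title.
#' @return Invisibly, the electrode ordering used.
#' @export
plot_tmap_raster <- function(map, montage = default_montage(),
                             main = "pointwise t map") {
  row_order <- c("F", "FC", "C", "CP", "P", "PO", "O", "other")
  m <- montage[match(map$channels, montage$name), , drop = FALSE]
  ord <- order(match(m$row_label, row_order), m$name)
  z <- abs(map$t[ord, , drop = FALSE])
  z[!map$sig[ord, , drop = FALSE]] <- NA
  graphics::image(x = map$times_ms, y = seq_along(ord), z = t(z),
                  ylim = c(length(ord) + 0.5, 0.5),
                  col = grDevices::hcl.colors(32, "Reds", rev = TRUE),
                  xlab = "time (ms)", ylab = "", yaxt = "n", main = main)
  graphics::axis(2, at = seq_along(ord), labels = map$channels[ord],
                 las = 2, cex.axis = 0.5)
  invisible(map$channels[ord])
}
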