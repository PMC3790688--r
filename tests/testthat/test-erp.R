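# ERP averaging, t-maps, ROI counting, chi-square, permutation, window
# means, and the repeated-measures ANOVA.

# Small hand-built erp_set: n participants, ROI-window times, given montage.
toy_erps <- function(n = 6, montage = test_montage(),
                     times = seq(80, 248, by = 2), fill = 0) {
  conds <- c("rivalry_changed", "rivalry_same", "fusion_changed",
             "fusion_same")
  dat <- array(fill, c(n, 4, nrow(montage), length(times)),
               dimnames = list(sprintf("P%02d", 1:n), conds, montage$name,
                               NULL))
  structure(list(data = dat, times_ms = times, montage = montage,
                 conditions = conds,
                 n_trials = matrix(10L, n, 4,
                                   dimnames = list(sprintf("P%02d", 1:n),
                                                   conds))),
            class = "erp_set")
}

test_that("averaging reproduces trivial epoch algebra", {
  m <- test_montage()[1:2, ]
  mk_ep <- function(trials) {
    n_tr <- dim(trials)[1]
    structure(list(data = trials, times_ms = c(0, 2, 4),
                   meta = data.frame(sample = seq_len(n_tr), code = 1L,
                                     label = "S1_rivalry_changed",
                                     condition = rep(c("rivalry_changed",
                                                       "rivalry_same",
                                                       "fusion_changed",
                                                       "fusion_same"),
                                                     length.out = n_tr)),
                   keep = rep(TRUE, n_tr), montage = m, fs = 500,
                   baselined = TRUE),
              class = "epoch_set")
  }
  # identical epochs average to any one of them
  tr <- array(rep(1:6, each = 8), c(8, 2, 3))
  erps <- average_erps(list(A = mk_ep(tr)))
  expect_equal(erps$data[1, "rivalry_changed", , ], tr[1, , ])
  # +v and -v average to zero
  tr2 <- array(0, c(8, 2, 3))
  tr2[1, , ] <- 5; tr2[5, , ] <- -5
  erps2 <- average_erps(list(A = mk_ep(tr2)))
  expect_equal(max(abs(erps2$data[1, "rivalry_changed", , ])), 0)
  expect_equal(erps2$n_trials[1, ], c(rivalry_changed = 2L,
                                      rivalry_same = 2L,
                                      fusion_changed = 2L,
                                      fusion_same = 2L))
  # a participant with an empty cell is excluded with a warning
  tr3 <- tr[1:3, , , drop = FALSE]
  expect_warning(e3 <- average_erps(list(A = mk_ep(tr), B = mk_ep(tr3))),
                 "empty condition cell")
  expect_equal(dim(e3$data)[1], 1L)
  expect_equal(attr(e3, "excluded"), "B")
})

test_that("trial averaging shrinks noise like one over root n", {
  set.seed(8)
  n_tr <- 50
  x <- array(rnorm(n_tr * 1 * 400, sd = 3), c(n_tr, 1, 400))
  avg <- apply(x, c(2, 3), mean)
  expect_equal(sd(avg), 3 / sqrt(n_tr), tolerance = 0.12)
})

test_that("t-map trivial cases: equality, constant sign, df", {
  erps <- toy_erps(n = 6)
  set.seed(2)
  noise <- array(rnorm(length(erps$data[, 1, , ])), dim(erps$data[, 1, , ]))
  erps$data[, "rivalry_changed", , ] <- noise
  erps$data[, "rivalry_same", , ] <- noise  # A == B
  mp <- suppressWarnings(pointwise_tmap(erps, "rivalry_changed",
                                        "rivalry_same"))
  expect_true(all(mp$t == 0 | is.na(mp$t)))
  expect_false(any(mp$sig))
  expect_equal(mp$df, 5L)
  # positive difference with nonzero variance -> all t positive
  erps$data[, "rivalry_changed", , ] <- noise + 2 +
    array(rnorm(length(noise), sd = 0.1), dim(noise))
  mp2 <- pointwise_tmap(erps, "rivalry_changed", "rivalry_same")
  expect_true(all(mp2$t > 0))
  # zero-variance cells flagged not significant with a warning
  erps$data[, "fusion_changed", , ] <- 1
  erps$data[, "fusion_same", , ] <- 0
  expect_warning(mp3 <- pointwise_tmap(erps, "fusion_changed", "fusion_same"),
                 "zero variance")
  expect_false(any(mp3$sig))
})

test_that("ROI counting uses the half-open 85-sample convention", {
  m <- default_montage()
  roi <- roi_spec(m)
  expect_length(roi$electrodes, 10)
  erps <- toy_erps(n = 5, montage = m, times = seq(-100, 2000, by = 2))
  set.seed(3)
  erps$data[, 1, , ] <- rnorm(length(erps$data[, 1, , ]))
  mp <- pointwise_tmap(erps, "rivalry_changed", "rivalry_same")
  rc <- roi_count(mp, roi)
  expect_equal(rc$n_samples, 85)
  expect_equal(rc$n_cells, 850)
  # all-null map counts zero; saturated map counts the grid size
  mp0 <- mp; mp0$sig[] <- FALSE
  expect_equal(roi_count(mp0, roi)$count, 0)
  mp1 <- mp; mp1$sig[] <- TRUE
  expect_equal(roi_count(mp1, roi)$count, 850)
})

test_that("count chi-square matches hand and reference computations", {
  cs <- count_chisq(34, 850, 0.01)
  expect_equal(round(cs$chi2, 2), 77.27)
  expect_equal(cs$df, 1L)
  expect_lt(cs$p, 1e-4)
  expect_equal(cs$expected, 8.5)
  # observed equal to expected gives exactly zero
  expect_equal(count_chisq(8.5, 850, 0.01)$chi2, 0)
  # reference value from the two-cell formula, frozen:
  # 8.5^2/8.5 + 8.5^2/841.5 = 8.585859...
  expect_equal(count_chisq(17, 850, 0.01)$chi2, 8.5858585858586,
               tolerance = 1e-10)
  # agrees with the stats::chisq.test goodness-of-fit oracle
  oracle <- suppressWarnings(
    stats::chisq.test(c(34, 816), p = c(0.01, 0.99)))
  expect_equal(cs$chi2, unname(oracle$statistic), tolerance = 1e-12)
  expect_equal(cs$p, oracle$p.value, tolerance = 1e-12)
  # symmetric in the two cells
  a <- count_chisq(30, 100, 0.2)
  b <- count_chisq(70, 100, 0.8)
  expect_equal(a$chi2, b$chi2)
  expect_error(count_chisq(5, 10, 1.5), "alpha")
  expect_error(count_chisq(11, 10, 0.1), "observed")
})

test_that("permutation map: identity p for A == B, symmetry, agreement", {
  m <- test_montage()[1:4, ]
  erps <- toy_erps(n = 8, montage = m, times = seq(80, 98, by = 2))
  set.seed(5)
  noise <- array(rnorm(length(erps$data[, 1, , ])), dim(erps$data[, 1, , ]))
  erps$data[, "rivalry_changed", , ] <- noise
  erps$data[, "rivalry_same", , ] <- noise
  pm <- suppressWarnings(permutation_tmap(erps, "rivalry_changed",
                                          "rivalry_same"))
  expect_true(all(is.na(pm$p) | pm$p == 1))  # t = 0 is the centre
  # strong effect: p bounded below, significant everywhere
  erps$data[, "rivalry_changed", , ] <- noise + 10 +
    array(rnorm(length(noise), sd = 0.05), dim(noise))
  pm2 <- permutation_tmap(erps, "rivalry_changed", "rivalry_same")
  expect_equal(unique(as.vector(pm2$p)), 2 / 2^8)  # +/- global flips tie
  expect_true(all(pm2$sig))
  # permutation p tracks the parametric p under the null
  erps$data[, "rivalry_changed", , ] <- noise +
    array(rnorm(length(noise), sd = 0.5), dim(noise))
  pm3 <- permutation_tmap(erps, "rivalry_changed", "rivalry_same")
  pt3 <- pointwise_tmap(erps, "rivalry_changed", "rivalry_same")
  expect_gt(cor(as.vector(pm3$p), as.vector(pt3$p)), 0.98)
})

test_that("window means follow the half-open convention and trivial algebra", {
  m <- test_montage()
  erps <- toy_erps(n = 3, montage = m, times = seq(-100, 2000, by = 2),
                   fill = 2)
  win <- window_spec(POST6, 170, 190)
  wm <- window_mean(erps, win)
  expect_equal(nrow(wm), 12)
  expect_true(all(wm$value == 2))
  # one electrode, one sample
  one <- window_spec("POz", 170, 172)
  i <- match("POz", m$name)
  j <- match(170, erps$times_ms)
  erps$data[1, "rivalry_changed", i, j] <- 9
  wm1 <- window_mean(erps, one)
  expect_equal(wm1$value[wm1$participant == "P01" &
                           wm1$condition == "rivalry_changed"], 9)
  expect_error(window_mean(erps, window_spec("NOPE", 170, 190)),
               "unknown electrode")
})

test_that("one-factor rm-ANOVA equals the frozen hand computation", {
  # table {(1,2),(2,4),(3,3)}: SS_cond = 1.5, SS_error = 1.0, F = 3
  tab <- data.frame(participant = rep(1:3, each = 2),
                    condition = rep(c("a", "b"), 3),
                    value = c(1, 2, 2, 4, 3, 3))
  an <- rm_anova(tab, within = "condition")
  expect_equal(an$ss, 1.5)
  expect_equal(an$ss_error, 1.0)
  expect_equal(an$F, 3)
  expect_equal(an$df1, 1)
  expect_equal(an$df2, 2)
  expect_equal(an$pes, 0.6)
})

test_that("rm-ANOVA agrees with the aov oracle on random tables", {
  set.seed(10)
  cases <- list(c(n = 4, a = 3, b = 3), c(n = 8, a = 2, b = 4),
                c(n = 11, a = 2, b = 2), c(n = 5, a = 4, b = 2))
  for (cs in cases) {
    tab <- expand.grid(participant = seq_len(cs["n"]),
                       A = letters[seq_len(cs["a"])],
                       B = LETTERS[seq_len(cs["b"])])
    tab$value <- rnorm(nrow(tab))
    mine <- rm_anova(tab, within = c("A", "B"))
    orc <- aov_oracle(tab, within = c("A", "B"))
    for (eff in c("A", "B", "A:B")) {
      expect_equal(mine$F[mine$effect == eff], unname(orc[[eff]]["F"]),
                   tolerance = 1e-10)
      expect_equal(mine$p[mine$effect == eff], unname(orc[[eff]]["p"]),
                   tolerance = 1e-10)
      expect_equal(mine$ss[mine$effect == eff], unname(orc[[eff]]["ss"]),
                   tolerance = 1e-10)
      expect_equal(mine$df2[mine$effect == eff], unname(orc[[eff]]["df2"]))
    }
    # one-factor path
    sub <- tab[tab$B == "A", ]
    m1 <- rm_anova(sub, within = "A")
    o1 <- aov_oracle(sub, within = "A")
    expect_equal(m1$F, unname(o1[["A"]]["F"]), tolerance = 1e-10)
  }
})

test_that("two-level rm-ANOVA F equals the squared paired t exactly", {
  set.seed(11)
  for (rep in 1:5) {
    n <- sample(5:12, 1)
    a <- rnorm(n); b <- rnorm(n)
    tab <- data.frame(participant = rep(seq_len(n), 2),
                      condition = rep(c("x", "y"), each = n),
                      value = c(a, b))
    an <- rm_anova(tab, within = "condition")
    tt <- t.test(a, b, paired = TRUE)
    expect_equal(an$F, unname(tt$statistic)^2, tolerance = 1e-12)
    expect_equal(an$p, tt$p.value, tolerance = 1e-12)
    expect_equal(an$df2, unname(tt$parameter))
  }
  # identical columns: F = 0, partial eta^2 = 0
  tab0 <- data.frame(participant = rep(1:4, 2),
                     condition = rep(c("x", "y"), each = 4),
                     value = rep(rnorm(4), 2))
  an0 <- rm_anova(tab0, within = "condition")
  expect_equal(an0$F, 0)
  expect_equal(an0$pes, 0)
  # missing cells are an explicit error
  expect_error(rm_anova(tab0[-1, ], within = "condition"), "missing cells")
})
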