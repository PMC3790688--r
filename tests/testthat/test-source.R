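# Spherical leadfield, smoothness-penalised inverse, and Hotelling SPMs.

# Shared small forward fixture: default montage, 305-voxel grid.
source_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      m <- default_montage()
      g <- make_source_grid(0.2)
      G <- make_leadfield(m, g)
      rr <- sqrt(g$x^2 + g$y^2 + g$z^2)
      cand <- which(rr > 0.6 & g$y < -0.4 & g$z > 0)  # posterior, superficial
      v0 <- cand[which.max(rr[cand])]
      rv <- as.numeric(g[v0, ]) / rr[v0]
      cache <<- list(montage = m, grid = g, gain = G, v0 = v0,
                     moment = rv,
                     y = as.vector(G[, 3 * (v0 - 1) + 1:3] %*% rv))
    }
    cache
  }
})

toy_solution_set <- function(fx, n = 11, noise_frac, seed = 7) {
  conds <- c("rivalry_changed", "rivalry_same", "fusion_changed",
             "fusion_same")
  E <- nrow(fx$gain)
  times <- seq(170, 188, by = 2)
  set.seed(seed)
  dat <- array(0, c(n, 4, E, length(times)),
               dimnames = list(sprintf("P%02d", 1:n), conds,
                               rownames(fx$gain), NULL))
  for (p in 1:n) for (ci in 1:4) {
    base <- matrix(rnorm(E * length(times),
                         sd = noise_frac * max(abs(fx$y))),
                   E, length(times))
    if (ci == 1) base <- base + fx$y
    dat[p, ci, , ] <- base
  }
  structure(list(data = dat, times_ms = times, montage = fx$montage,
                 conditions = conds, n_trials = matrix(100, n, 4)),
            class = "erp_set")
}

test_that("leadfield geometry: radial dipole is maximal under its electrode", {
  fx <- source_fixture()
  m <- fx$montage
  poz <- as.numeric(m[m$name == "POz", c("x", "y", "z")])
  d2 <- (fx$grid$x - 0.8 * poz[1])^2 + (fx$grid$y - 0.8 * poz[2])^2 +
    (fx$grid$z - 0.8 * poz[3])^2
  v <- which.min(d2)
  rv <- as.numeric(fx$grid[v, ])
  rv <- rv / sqrt(sum(rv^2))
  pot <- fx$gain[, 3 * (v - 1) + 1:3] %*% rv
  expect_equal(rownames(fx$gain)[which.max(abs(pot))], "POz")
})

test_that("leadfield is linear with finite, non-identical columns", {
  fx <- source_fixture()
  expect_true(all(is.finite(fx$gain)))
  cols <- fx$gain[, c(1, 4, 7, 100, 200)]
  expect_gt(min(dist(t(cols))), 0)
  # doubling the moment doubles all sensor values (linearity)
  v <- fx$v0
  g1 <- fx$gain[, 3 * (v - 1) + 1:3] %*% fx$moment
  g2 <- fx$gain[, 3 * (v - 1) + 1:3] %*% (2 * fx$moment)
  expect_equal(g2, 2 * g1)
  # voxel outside the sphere is rejected
  bad <- make_source_grid(0.2)
  bad$x[1] <- 1.2
  expect_error(make_leadfield(fx$montage, bad), "outside")
})

test_that("inverse operator: ridge limit, linearity, GCV selection", {
  fx <- source_fixture()
  scale <- mean(diag(fx$gain %*% t(fx$gain)))
  inv_small <- inverse_operator(fx$gain, lambda = 1e-8 * scale)
  inv_huge <- inverse_operator(fx$gain, lambda = 1e8 * scale)
  j_small <- as.vector(unclass(inv_small) %*% fx$y)
  j_huge <- as.vector(unclass(inv_huge) %*% fx$y)
  expect_lt(sqrt(sum(j_huge^2)), 1e-6 * sqrt(sum(j_small^2)))
  # linearity
  y2 <- rev(fx$y)
  expect_equal(as.vector(unclass(inv_small) %*% (2 * fx$y - 3 * y2)),
               2 * j_small - 3 * as.vector(unclass(inv_small) %*% y2),
               tolerance = 1e-9)
  # GCV picks a lambda and errors without data
  inv_gcv <- inverse_operator(fx$gain, lambda = NULL, data_for_gcv = fx$y)
  expect_gt(attr(inv_gcv, "lambda"), 0)
  expect_error(inverse_operator(fx$gain, lambda = NULL), "data_for_gcv")
  expect_error(inverse_operator(fx$gain, lambda = -1), "lambda")
})

test_that("noiseless single dipole localises within one grid spacing", {
  fx <- source_fixture()
  sp <- attr(fx$grid, "spacing")
  inv <- inverse_operator(fx$gain, lambda = NULL, smooth_weight = 0.2,
                          data_for_gcv = fx$y)
  j <- matrix(as.vector(unclass(inv) %*% fx$y), ncol = 3, byrow = TRUE)
  pk <- which.max(sqrt(rowSums(j^2)))
  err <- sqrt(sum((fx$grid[pk, ] - fx$grid[fx$v0, ])^2))
  expect_lte(err, sp + 1e-9)
})

test_that("zero and equal-condition solutions behave trivially", {
  fx <- source_fixture()
  erps <- toy_solution_set(fx, n = 6, noise_frac = 0)
  erps$data[, , , ] <- 0
  inv <- inverse_operator(fx$gain, lambda = 1)
  sol <- localize_window(erps, window_spec("POz", 170, 190), inv)
  expect_equal(max(abs(sol)), 0)
  spm <- spm_hotelling(sol, "rivalry_changed")
  expect_false(any(spm$sig))
  expect_true(all(is.na(spm$statistic)))
  # identical conditions give identical solutions
  erps2 <- toy_solution_set(fx, n = 6, noise_frac = 0.05)
  erps2$data[, "rivalry_same", , ] <- erps2$data[, "rivalry_changed", , ]
  sol2 <- localize_window(erps2, window_spec("POz", 170, 190), inv)
  expect_equal(sol2[, "rivalry_same", , ], sol2[, "rivalry_changed", , ])
  spm2 <- spm_condition_contrast(sol2, "rivalry_changed", "rivalry_same")
  expect_false(any(spm2$sig))
})

test_that("Hotelling SPM has F df (3, 8) at n = 11 and finds a common dipole", {
  fx <- source_fixture()
  erps <- toy_solution_set(fx, n = 11, noise_frac = 0.2)
  inv <- inverse_operator(fx$gain, lambda = NULL, smooth_weight = 0.2,
                          data_for_gcv = fx$y)
  sol <- localize_window(erps, window_spec("POz", 170, 190), inv)
  spm <- spm_hotelling(sol, "rivalry_changed")
  expect_equal(attr(spm, "df"), c(3L, 8L))
  expect_true(any(spm$sig))
  # the true voxel region is flagged
  sp <- attr(fx$grid, "spacing")
  pk <- which.max(spm$statistic)
  expect_lte(sqrt(sum((fx$grid[pk, ] - fx$grid[fx$v0, ])^2)), 2 * sp + 1e-9)
  erps3 <- toy_solution_set(fx, n = 3, noise_frac = 0.2)
  sol3 <- localize_window(erps3, window_spec("POz", 170, 190), inv)
  expect_error(spm_hotelling(sol3, "rivalry_changed"), "participants")
})

test_that("condition-contrast SPM is confined to the injected source region", {
  fx <- source_fixture()
  sp <- attr(fx$grid, "spacing")
  erps <- toy_solution_set(fx, n = 11, noise_frac = 0.2)
  inv <- inverse_operator(fx$gain, lambda = NULL, smooth_weight = 0.2,
                          data_for_gcv = fx$y)
  sol <- localize_window(erps, window_spec("POz", 170, 190), inv)
  spm <- spm_condition_contrast(sol, "rivalry_changed", "rivalry_same")
  sig <- which(spm$sig)
  expect_gt(length(sig), 0)
  d <- sqrt((fx$grid$x[sig] - fx$grid$x[fx$v0])^2 +
              (fx$grid$y[sig] - fx$grid$y[fx$v0])^2 +
              (fx$grid$z[sig] - fx$grid$z[fx$v0])^2)
  expect_lte(max(d), 2 * sp + 1e-9)
  # swapping conditions leaves the significance map unchanged
  spm_sw <- spm_condition_contrast(sol, "rivalry_same", "rivalry_changed")
  expect_equal(spm_sw$sig, spm$sig)
  expect_equal(spm_sw$statistic, spm$statistic)
  # contrast between identically generated conditions is null
  spm0 <- spm_condition_contrast(sol, "fusion_changed", "fusion_same")
  expect_false(any(spm0$sig))
})
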