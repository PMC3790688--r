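# Simplified distributed source analysis.
#
# Forward model: quasi-static dipole in a homogeneous unit sphere
# (conductivity 1), evaluated by the truncated Legendre-series expansion of
# the surface potential. Inverse: Tikhonov-regularised least squares with a
# discrete-Laplacian spatial smoothness penalty on the voxel grid (the
# smoothest-current-density idea, without the atlas restriction of the full
# method). Group statistics: voxelwise one-sample Hotelling T-squared on the
# 3-component current vectors, Bonferroni-corrected.

#' Cubic voxel grid inside the model head
#'
#' @param spacing Voxel edge length (head radius = 1; the full-scale analysis
#'   grid of 3,244 voxels of 7 mm corresponds to spacing ~0.08 at a 9 cm head
#'   radius — the default test-scale grid is far smaller).
#' @param radius Radius of the spherical brain mask.
#' @return A `source_grid` `data.frame` (columns `x`, `y`, `z`) with
#'   attributes `spacing` and `radius`.
#' @export
make_source_grid <- function(spacing = 0.2, radius = 0.84) {
  if (spacing <= 0) stopf("spacing must be > 0")
  ax <- seq(-floor(radius / spacing) * spacing, radius, by = spacing)
  g <- expand.grid(x = ax, y = ax, z = ax, KEEP.OUT.ATTRS = FALSE)
  g <- g[sqrt(g$x^2 + g$y^2 + g$z^2) <= radius, , drop = FALSE]
  rownames(g) <- NULL
  structure(g, spacing = spacing, radius = radius,
            class = c("source_grid", "data.frame"))
}

# Surface potential of a dipole at radius f (< 1) inside the unit sphere,
# via the Legendre series
#   V = 1/(4 pi) * sum_n f^(n-1) [ (2n+1) m_r P_n(c) + (2n+1)/n m_t P_n^1(c) ]
# with c the cosine between voxel and electrode directions, m_r the radial
# and m_t the tangential-toward-electrode moment components.
.dipole_potentials <- function(elec_pos, r_q, n_terms) {
  f <- sqrt(sum(r_q^2))
  rq_hat <- if (f < 1e-12) c(0, 0, 1) else r_q / f
  cth <- as.vector(elec_pos %*% rq_hat)
  cth <- pmin(1, pmax(-1, cth))
  sth <- sqrt(pmax(0, 1 - cth^2))
  # tangential unit vectors (toward each electrode), zero where undefined
  et <- elec_pos - outer(cth, rq_hat)
  nz <- sth > 1e-12
  et[nz, ] <- et[nz, , drop = FALSE] / sth[nz]
  et[!nz, ] <- 0
  s_rad <- numeric(length(cth))
  s_tan <- numeric(length(cth))
  p_prev <- rep(1, length(cth))  # P_0
  p_cur <- cth                   # P_1
  fpow <- 1                      # f^(n-1)
  for (n in seq_len(n_terms)) {
    # associated P_n^1 = n (P_{n-1} - c P_n) / sin(theta)
    pn1 <- numeric(length(cth))
    pn1[nz] <- n * (p_prev[nz] - cth[nz] * p_cur[nz]) / sth[nz]
    s_rad <- s_rad + fpow * (2 * n + 1) * p_cur
    s_tan <- s_tan + fpow * (2 * n + 1) / n * pn1
    p_next <- ((2 * n + 1) * cth * p_cur - n * p_prev) / (n + 1)
    p_prev <- p_cur
    p_cur <- p_next
    fpow <- fpow * f
    if (fpow * (2 * n + 3) < 1e-12) break
  }
  # columns: potentials for unit moments along x, y, z
  (outer(s_rad, rq_hat) + s_tan * et) / (4 * pi)
}

#' Leadfield (gain matrix) for a montage and source grid
#'
#' Quasi-static single-sphere dipole leadfield: sensors x (voxels x 3)
#' linear operator mapping dipole moments (x, y, z components, voxel-major
#' ordering) to scalp potentials. Deterministic; the same operator is meant
#' to be consumed by both forward simulation and the inverse.
#'
#' @param montage Montage; scalp channels become the operator's rows.
#' @param grid A [make_source_grid()]; every voxel must lie strictly inside
#'   the sphere.
#' @param n_terms Series truncation order.
#' @param reference `"linked_earlobes"` (rows referenced like the analysed
#'   data; requires earlobe channels in the montage), `"average"`, or
#'   `"infinity"` (raw series potentials).
#' @return Matrix with attributes `grid`, `channels`, `reference`.
#' @export
make_leadfield <- function(montage, grid, n_terms = 120,
                           reference = c("linked_earlobes", "average",
                                         "infinity")) {
  reference <- match.arg(reference)
  scalp <- montage$role == "scalp"
  pos_all <- montage_positions(montage)
  rr <- sqrt(rowSums(as.matrix(grid[, c("x", "y", "z")])^2))
  if (any(rr >= 1)) stopf("grid voxel outside the model sphere")
  use <- scalp | montage$role == "earlobe"
  pos <- pos_all[use, , drop = FALSE]
  G <- matrix(0, sum(use), 3L * nrow(grid))
  for (v in seq_len(nrow(grid))) {
    G[, 3L * (v - 1L) + 1:3] <-
      .dipole_potentials(pos, as.numeric(grid[v, c("x", "y", "z")]), n_terms)
  }
  rownames(G) <- montage$name[use]
  if (reference == "linked_earlobes") {
    ear <- montage$name[use][montage$role[use] == "earlobe"]
    if (length(ear) != 2L) {
      stopf("linked-earlobe reference needs 2 earlobe channels in the montage")
    }
    G <- sweep(G, 2, colMeans(G[ear, , drop = FALSE]))
  } else if (reference == "average") {
    G <- sweep(G, 2, colMeans(G))
  }
  G <- G[montage$name[scalp], , drop = FALSE]
  structure(G, grid = grid, channels = montage$name[scalp],
            reference = reference)
}

# Graph Laplacian over the 6-neighbourhood of the voxel grid.
grid_laplacian <- function(grid) {
  sp <- attr(grid, "spacing")
  key <- paste(round(grid$x / sp), round(grid$y / sp), round(grid$z / sp))
  idx <- seq_len(nrow(grid))
  names(idx) <- key
  L <- matrix(0, nrow(grid), nrow(grid))
  shifts <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                  c(0, 0, 1), c(0, 0, -1))
  for (s in seq_len(nrow(shifts))) {
    nk <- paste(round(grid$x / sp) + shifts[s, 1],
                round(grid$y / sp) + shifts[s, 2],
                round(grid$z / sp) + shifts[s, 3])
    j <- idx[nk]
    ok <- !is.na(j)
    L[cbind(idx[ok], j[ok])] <- -1
    diag(L)[ok] <- diag(L)[ok] + 1
  }
  L
}

#' Linear inverse operator (smoothness-penalised minimum norm)
#'
#' Solves, for scalp data y,
#' `min_j ||y - G j||^2 + lambda (||j||^2 + w ||L j||^2)` where `L` is the
#' grid's discrete Laplacian applied per dipole component, yielding the
#' spatially smoothest current density compatible with the data at the given
#' regularisation. The solution is linear in y; the operator is returned as
#' a (3 voxels) x sensors matrix.
#'
#' @param gain A [make_leadfield()] operator.
#' @param lambda Regularisation weight (> 0), or `NULL` to choose it by
#'   generalized cross-validation on `data_for_gcv`.
#' @param smooth_weight Weight `w` of the Laplacian penalty relative to the
#'   identity.
#' @param data_for_gcv Sensor vector (e.g. the group-average window mean)
#'   used when `lambda` is `NULL`.
#' @return An `inverse_operator` matrix with attributes `lambda`, `grid`,
#'   `channels`.
#' @export
inverse_operator <- function(gain, lambda = NULL, smooth_weight = 0.2,
                             data_for_gcv = NULL) {
  grid <- attr(gain, "grid")
  L <- grid_laplacian(grid)
  R <- diag(3L * nrow(grid)) +
    smooth_weight * kronecker(crossprod(L), diag(3))
  RinvGt <- solve(R, t(gain))
  K <- gain %*% RinvGt
  K <- (K + t(K)) / 2
  if (is.null(lambda)) {
    if (is.null(data_for_gcv)) {
      stopf("supply lambda or data_for_gcv for GCV selection")
    }
    eig <- eigen(K, symmetric = TRUE)
    yh <- as.vector(crossprod(eig$vectors, data_for_gcv))
    lam_grid <- 10^seq(-8, 2, by = 0.25) * mean(diag(K))
    gcv <- vapply(lam_grid, function(l) {
      shr <- l / (eig$values + l)
      sum((shr * yh)^2) / (mean(shr))^2
    }, numeric(1))
    lambda <- lam_grid[which.min(gcv)]
  }
  if (lambda <= 0) stopf("lambda must be > 0")
  W <- RinvGt %*% solve(K + lambda * diag(nrow(K)))
  structure(W, lambda = lambda, grid = grid,
            channels = attr(gain, "channels"), class = "inverse_operator")
}

#' Localise window-averaged ERPs
#'
#' Applies the inverse operator to each participant's and condition's
#' window-averaged scalp vector, giving a 3-component primary current
#' density estimate per voxel.
#'
#' @param erps An `erp_set`.
#' @param window A [window_spec()] whose electrodes are ignored: the full
#'   operator channel set is used; only the time window matters here.
#' @param inv An [inverse_operator()].
#' @return A `source_solution`: array participants x conditions x voxels x 3
#'   with the grid attached.
#' @export
localize_window <- function(erps, window, inv) {
  chans <- attr(inv, "channels")
  i <- match(chans, dimnames(erps$data)[[3L]])
  if (anyNA(i)) {
    stopf("inverse operator channels missing from ERP set: %s",
          paste(chans[is.na(i)], collapse = ", "))
  }
  j <- which(erps$times_ms >= window$t_start_ms &
               erps$times_ms < window$t_end_ms)
  if (length(j) == 0L) stopf("window contains no samples")
  grid <- attr(inv, "grid")
  n_p <- dim(erps$data)[1L]
  conds <- erps$conditions
  sol <- array(NA_real_, c(n_p, length(conds), nrow(grid), 3L),
               dimnames = list(dimnames(erps$data)[[1L]], conds, NULL,
                               c("jx", "jy", "jz")))
  for (p in seq_len(n_p)) {
    for (ci in seq_along(conds)) {
      y <- rowMeans(array(erps$data[p, ci, i, j, drop = FALSE],
                          c(length(i), length(j))))
      jvec <- as.vector(unclass(inv) %*% y)
      sol[p, ci, , ] <- matrix(jvec, ncol = 3L, byrow = TRUE)
    }
  }
  structure(sol, grid = grid, class = "source_solution")
}

# One-sample Hotelling T^2 of n x 3 rows against zero -> list(F, p) or NA.
.hotelling_f <- function(X) {
  n <- nrow(X)
  xbar <- colMeans(X)
  S <- stats::cov(X)
  si <- tryCatch(solve(S, xbar), error = function(e) NULL)
  if (is.null(si)) return(c(Fv = NA_real_, p = NA_real_))
  t2 <- n * sum(xbar * si)
  Fv <- t2 * (n - 3) / (3 * (n - 1))
  c(Fv = Fv, p = stats::pf(Fv, 3, n - 3, lower.tail = FALSE))
}

.spm_from_F <- function(Fp, grid, n, alpha) {
  p_corr <- pmin(1, Fp[, "p"] * nrow(grid))
  out <- data.frame(grid[, c("x", "y", "z")], statistic = Fp[, "Fv"],
                    p = Fp[, "p"], p_corrected = p_corr,
                    sig = !is.na(p_corr) & p_corr < alpha)
  structure(out, df = c(3L, n - 3L), alpha = alpha, correction = "bonferroni",
            class = c("spm", "data.frame"))
}

#' Voxelwise Hotelling T-squared SPM against zero
#'
#' One-sample Hotelling T-squared of each voxel's 3-component current
#' vectors across participants against zero, F-transformed as
#' `T^2 (n - 3) / (3 (n - 1))` with df (3, n - 3), Bonferroni-corrected over
#' voxels. Needs more participants than components (n > 3); voxels with a
#' singular covariance are flagged untestable (`NA`, never significant).
#'
#' @param solutions A [localize_window()] result.
#' @param condition Condition to test.
#' @param alpha Corrected significance level (default .01, matching the
#'   Bonferroni-corrected maps of the study).
#' @return An `spm` data frame: voxel coordinates, `statistic` (F), `p`,
#'   `p_corrected`, `sig`.
#' @export
spm_hotelling <- function(solutions, condition, alpha = 0.01) {
  grid <- attr(solutions, "grid")
  n <- dim(solutions)[1L]
  if (n <= 3L) stopf("Hotelling T^2 on 3 components needs > 3 participants")
  Fp <- t(vapply(seq_len(nrow(grid)), function(v) {
    .hotelling_f(solutions[, condition, v, , drop = TRUE])
  }, c(Fv = 0, p = 0)))
  .spm_from_F(Fp, grid, n, alpha)
}

#' Condition-contrast SPM (paired Hotelling T-squared)
#'
#' Repeated-measures contrast between two conditions: Hotelling T-squared of
#' the paired per-participant 3-vector differences against zero (equivalent
#' to the two-level within-factor multivariate ANOVA), Bonferroni-corrected.
#' Symmetric in the two conditions.
#'
#' @param solutions A [localize_window()] result.
#' @param condition_a,condition_b Conditions to contrast.
#' @param alpha Corrected level.
#' @return An `spm` data frame.
#' @export
spm_condition_contrast <- function(solutions, condition_a, condition_b,
                                   alpha = 0.01) {
  grid <- attr(solutions, "grid")
  n <- dim(solutions)[1L]
  if (n <= 3L) stopf("Hotelling T^2 on 3 components needs > 3 participants")
  Fp <- t(vapply(seq_len(nrow(grid)), function(v) {
    D <- solutions[, condition_a, v, , drop = TRUE] -
      solutions[, condition_b, v, , drop = TRUE]
    .hotelling_f(D)
  }, c(Fv = 0, p = 0)))
  .spm_from_F(Fp, grid, n, alpha)
}

#' Glass-brain scatter of an SPM
#'
#' Three orthogonal projections (axial, coronal, sagittal) with significant
#' voxels highlighted.
#'
#' @param spm An `spm` data frame.
#' @param main Title.
#' @return Invisibly, the number of significant voxels.
#' @export
plot_glass_brain <- function(spm, main = "SPM") {
  op <- graphics::par(mfrow = c(1, 3), mar = c(4, 4, 3, 1))
  on.exit(graphics::par(op))
  panes <- list(c("x", "y"), c("x", "z"), c("y", "z"))
  for (pn in panes) {
    graphics::plot(spm[[pn[1]]], spm[[pn[2]]], pch = 16, cex = 0.4,
                   col = "grey80", asp = 1, xlab = pn[1], ylab = pn[2],
                   main = main)
    sig <- spm$sig %in% TRUE
    if (any(sig)) {
      graphics::points(spm[[pn[1]]][sig], spm[[pn[2]]][sig], pch = 16,
                       cex = 0.8, col = "red")
    }
  }
  invisible(sum(spm$sig %in% TRUE))
}
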