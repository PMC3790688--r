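# Electrode montage: a modified 10-20 layout of 65 active channels
# (59 informative scalp channels including the recovered reference FCz,
# 4 EOG channels, 2 earlobe channels) on a unit sphere.

.ROW_PREFIXES <- c("FC", "CP", "PO", "F", "C", "P", "O")

#' Infer the electrode row label from a channel name
#'
#' Rows follow the longest-prefix rule over `FC`, `CP`, `PO`, `F`, `C`, `P`,
#' `O`; any other name (including EOG, earlobe, `Fp`-free names like `T7`,
#' `AF3`, `Iz`) maps to `"other"`. Note `FC3` is row `FC`, not `F`.
#'
#' @param name Character vector of channel names.
#' @return Character vector of row labels.
#' @export
#' @examples
#' infer_row_label(c("POz", "FC3", "Oz", "T7"))
infer_row_label <- function(name) {
  vapply(name, function(nm) {
    hits <- .ROW_PREFIXES[startsWith(nm, .ROW_PREFIXES)]
    if (length(hits) == 0L) return("other")
    hits[which.max(nchar(hits))]
  }, character(1), USE.NAMES = FALSE)
}

# Unit-sphere position from a front-back rotation u (degrees, + toward nasion)
# and a lateral rotation lam (degrees, + toward the right ear).
.chan_pos <- function(u, lam) {
  u <- u * pi / 180
  lam <- lam * pi / 180
  c(x = sin(lam) * cos(u), y = sin(u), z = cos(lam) * cos(u))
}

.norm3 <- function(v) v / sqrt(sum(v^2))

#' Default 65-channel montage
#'
#' Constructs the package's default electrode set: 59 scalp channels on a
#' modified 10-20 grid (with `FCz` present as an ordinary scalp channel, as it
#' becomes after off-line re-referencing away from the recording reference),
#' four EOG channels and two earlobe channels. Positions are unit-sphere
#' coordinates with +x right, +y anterior, +z superior. Exactly 10 channels
#' carry row label `PO` or `O`; these form the default region of interest.
#'
#' @return A `data.frame` with columns `name`, `role`
#'   (`scalp`/`eog`/`earlobe`), `x`, `y`, `z`, `row_label`.
#' @export
#' @examples
#' m <- default_montage()
#' table(m$role)
#' sum(m$row_label %in% c("PO", "O"))
default_montage <- function() {
  # name, front-back angle u, lateral angle lam
  scalp <- list(
    c("Fp1", 72, -18), c("Fpz", 72, 0), c("Fp2", 72, 18),
    c("AF7", 54, -72), c("AF3", 54, -36), c("AF4", 54, 36), c("AF8", 54, 72),
    c("F7", 36, -72), c("F5", 36, -54), c("F3", 36, -36), c("F1", 36, -18),
    c("Fz", 36, 0), c("F2", 36, 18), c("F4", 36, 36), c("F6", 36, 54),
    c("F8", 36, 72),
    c("FC5", 18, -54), c("FC3", 18, -36), c("FC1", 18, -18), c("FCz", 18, 0),
    c("FC2", 18, 18), c("FC4", 18, 36), c("FC6", 18, 54),
    c("T7", 0, -90), c("C5", 0, -54), c("C3", 0, -36), c("C1", 0, -18),
    c("Cz", 0, 0), c("C2", 0, 18), c("C4", 0, 36), c("C6", 0, 54),
    c("T8", 0, 90),
    c("CP5", -18, -54), c("CP3", -18, -36), c("CP1", -18, -18),
    c("CPz", -18, 0), c("CP2", -18, 18), c("CP4", -18, 36), c("CP6", -18, 54),
    c("P7", -36, -72), c("P5", -36, -54), c("P3", -36, -36), c("P1", -36, -18),
    c("Pz", -36, 0), c("P2", -36, 18), c("P4", -36, 36), c("P6", -36, 54),
    c("P8", -36, 72),
    c("PO9", -54, -90), c("PO7", -54, -72), c("PO3", -54, -36),
    c("POz", -54, 0), c("PO4", -54, 36), c("PO8", -54, 72), c("PO10", -54, 90),
    c("O1", -72, -18), c("Oz", -72, 0), c("O2", -72, 18),
    c("Iz", -90, 0)
  )
  nm <- vapply(scalp, `[`, character(1), 1L)
  pos <- t(vapply(scalp, function(s) .chan_pos(as.numeric(s[2]), as.numeric(s[3])),
                  numeric(3)))
  aux <- rbind(
    HEOGL = .norm3(c(-0.80, 0.55, -0.15)),
    HEOGR = .norm3(c(0.80, 0.55, -0.15)),
    VEOGU = .norm3(c(0.15, 0.95, 0.10)),
    VEOGD = .norm3(c(0.15, 0.95, -0.25)),
    A1 = .norm3(c(-0.95, -0.05, -0.30)),
    A2 = .norm3(c(0.95, -0.05, -0.30))
  )
  m <- data.frame(
    name = c(nm, rownames(aux)),
    role = c(rep("scalp", length(nm)), rep("eog", 4), rep("earlobe", 2)),
    x = c(pos[, 1], aux[, 1]),
    y = c(pos[, 2], aux[, 2]),
    z = c(pos[, 3], aux[, 3]),
    stringsAsFactors = FALSE
  )
  m$row_label <- ifelse(m$role == "scalp", infer_row_label(m$name), "other")
  rownames(m) <- NULL
  m
}

#' Load a montage from a tab-separated file
#'
#' Expects columns `name`, `role`, `x`, `y`, `z`. Positions are normalised to
#' the unit sphere (with a warning when any deviates), duplicate names are an
#' error, and the `row_label` column is derived from the name prefix. With no
#' `path`, the packaged default 65-channel fixture is loaded.
#'
#' @param path Path to a montage TSV, or `NULL` for the packaged fixture.
#' @return Montage `data.frame` as from [default_montage()].
#' @export
load_montage <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "montage_default.tsv", package = "rivalerp")
  }
  if (!file.exists(path)) stopf("montage file not found: %s", path)
  m <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "role", "x", "y", "z")
  if (!all(need %in% names(m))) {
    stopf("montage file must have columns: %s", paste(need, collapse = ", "))
  }
  if (anyDuplicated(m$name)) {
    stopf("duplicate channel names in montage: %s",
          paste(unique(m$name[duplicated(m$name)]), collapse = ", "))
  }
  nrm <- sqrt(m$x^2 + m$y^2 + m$z^2)
  if (any(abs(nrm - 1) > 1e-6)) {
    warnf("%d electrode position(s) not on the unit sphere; normalising",
          sum(abs(nrm - 1) > 1e-6))
    m$x <- m$x / nrm; m$y <- m$y / nrm; m$z <- m$z / nrm
  }
  m$row_label <- ifelse(m$role == "scalp", infer_row_label(m$name), "other")
  m[need[1:2]] <- lapply(m[need[1:2]], as.character)
  rownames(m) <- NULL
  m[, c("name", "role", "x", "y", "z", "row_label")]
}

#' Write a montage to a tab-separated file
#'
#' @param montage Montage `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_montage <- function(montage, path) {
  utils::write.table(montage[, c("name", "role", "x", "y", "z")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Subset a montage by channel name
#'
#' @param montage Montage `data.frame`.
#' @param channels Channel names to keep (order preserved).
#' @param keep_support Also keep all EOG and earlobe channels (default `TRUE`),
#'   which artifact rejection and re-referencing require.
#' @return Montage `data.frame` restricted to the requested channels.
#' @export
montage_subset <- function(montage, channels, keep_support = TRUE) {
  missing <- setdiff(channels, montage$name)
  if (length(missing)) {
    stopf("channels not in montage: %s", paste(missing, collapse = ", "))
  }
  if (keep_support) {
    channels <- c(channels, montage$name[montage$role %in% c("eog", "earlobe")])
    channels <- channels[!duplicated(channels)]
  }
  out <- montage[match(channels, montage$name), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Positions matrix (n x 3) of a montage, rownames = channel names.
montage_positions <- function(montage) {
  p <- as.matrix(montage[, c("x", "y", "z")])
  rownames(p) <- montage$name
  p
}
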