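# BrainVision triplet (.vhdr/.vmrk/.eeg) reader and writer.
#
# One fixed binary dialect is used: multiplexed IEEE float32, little-endian,
# resolution 1 uV, which makes round trips exact to float32 precision and the
# payload size exactly 4 * channels * samples bytes.

#' Event code table
#'
#' Bijective mapping between marker codes and their meanings; written as a
#' comment block into every marker file header.
#'
#' @return `data.frame` with columns `code`, `label`.
#' @export
event_code_table <- function() {
  data.frame(
    code = c(1:6, 10L, 11L),
    label = c("S1_rivalry_changed", "S1_rivalry_same", "S1_rivalry_noresponse",
              "S1_fusion_change_correct", "S1_fusion_same_correct",
              "S1_fusion_incorrect", "S2_onset", "mask_onset"),
    stringsAsFactors = FALSE
  )
}

#' Write a recording as a BrainVision triplet
#'
#' Writes `<basename>.vhdr` (header), `<basename>.vmrk` (markers) and
#' `<basename>.eeg` (multiplexed IEEE float32 little-endian voltages in uV).
#'
#' @param raw An `eeg_recording`.
#' @param basename Output path without extension.
#' @return `basename`, invisibly.
#' @export
write_brainvision <- function(raw, basename) {
  stopifnot(inherits(raw, "eeg_recording"))
  base <- basename(basename)
  hdr <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    sprintf("; ReferenceState=%s", raw$reference_state),
    "",
    "[Common Infos]",
    sprintf("DataFile=%s.eeg", base),
    sprintf("MarkerFile=%s.vmrk", base),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    sprintf("NumberOfChannels=%d", nrow(raw$data)),
    sprintf("SamplingInterval=%g", 1e6 / raw$fs),
    "",
    "[Binary Infos]",
    "BinaryFormat=IEEE_FLOAT_32",
    "",
    "[Channel Infos]",
    sprintf("Ch%d=%s,,1,uV", seq_len(nrow(raw$data)), rownames(raw$data))
  )
  writeLines(hdr, paste0(basename, ".vhdr"))
  tab <- event_code_table()
  mrk <- c(
    "Brain Vision Data Exchange Marker File, Version 1.0",
    sprintf("; Code table: %s",
            paste(sprintf("%d=%s", tab$code, tab$label), collapse = "; ")),
    "",
    "[Common Infos]",
    sprintf("DataFile=%s.eeg", base),
    "",
    "[Marker Infos]",
    "Mk1=New Segment,,1,1,0"
  )
  if (nrow(raw$events %||% data.frame())) {
    mrk <- c(mrk, sprintf("Mk%d=Stimulus,S%3d,%d,1,0",
                          seq_len(nrow(raw$events)) + 1L,
                          raw$events$code, raw$events$sample))
  }
  writeLines(mrk, paste0(basename, ".vmrk"))
  con <- file(paste0(basename, ".eeg"), "wb")
  on.exit(close(con))
  writeBin(as.vector(raw$data), con, size = 4L, endian = "little")
  invisible(basename)
}

.parse_ini_value <- function(lines, key) {
  hit <- grep(paste0("^", key, "="), lines, value = TRUE)
  if (length(hit) == 0L) return(NULL)
  sub(paste0("^", key, "="), "", hit[1L])
}

#' Read a BrainVision triplet
#'
#' Reads the triplet written by [write_brainvision()] (and any BrainVision
#' file using the multiplexed IEEE float32 little-endian dialect). Unknown
#' header keys are ignored. A payload whose size is not an exact multiple of
#' `4 * NumberOfChannels`, or that disagrees in sample count with the header,
#' is a size-mismatch error, never a silent truncation.
#'
#' @param basename Path without extension.
#' @param montage Optional montage supplying channel roles/positions; by
#'   default channels are matched by name against [default_montage()].
#' @return An `eeg_recording`.
#' @export
read_brainvision <- function(basename, montage = NULL) {
  vhdr <- paste0(basename, ".vhdr")
  vmrk <- paste0(basename, ".vmrk")
  eeg <- paste0(basename, ".eeg")
  for (f in c(vhdr, vmrk, eeg)) {
    if (!file.exists(f)) stopf("missing BrainVision file: %s", f)
  }
  hdr <- readLines(vhdr, warn = FALSE)
  fmt <- .parse_ini_value(hdr, "BinaryFormat")
  if (!identical(fmt, "IEEE_FLOAT_32")) {
    stopf("unsupported BinaryFormat: %s", fmt %||% "<missing>")
  }
  orient <- .parse_ini_value(hdr, "DataOrientation")
  if (!identical(orient, "MULTIPLEXED")) {
    stopf("unsupported DataOrientation: %s", orient %||% "<missing>")
  }
  n_ch <- as.integer(.parse_ini_value(hdr, "NumberOfChannels"))
  if (is.na(n_ch) || n_ch < 1L) stopf("invalid NumberOfChannels in %s", vhdr)
  si <- as.numeric(.parse_ini_value(hdr, "SamplingInterval"))
  if (is.na(si) || si <= 0) stopf("invalid SamplingInterval in %s", vhdr)
  fs <- 1e6 / si
  ch_lines <- grep("^Ch[0-9]+=", hdr, value = TRUE)
  ch_names <- vapply(strsplit(sub("^Ch[0-9]+=", "", ch_lines), ","),
                     `[`, character(1), 1L)
  if (length(ch_names) != n_ch) {
    stopf("header declares %d channels but lists %d channel infos",
          n_ch, length(ch_names))
  }
  nbytes <- file.size(eeg)
  if (nbytes %% (4L * n_ch) != 0L) {
    stopf("size mismatch: %s has %d bytes, not a multiple of 4 x %d channels (truncated file?)",
          eeg, nbytes, n_ch)
  }
  n_smp <- nbytes / (4L * n_ch)
  con <- file(eeg, "rb")
  vals <- readBin(con, numeric(), n = n_ch * n_smp, size = 4L,
                  endian = "little")
  close(con)
  dat <- matrix(vals, nrow = n_ch, ncol = n_smp)
  rownames(dat) <- ch_names
  mrk <- readLines(vmrk, warn = FALSE)
  stim <- grep("^Mk[0-9]+=Stimulus,", mrk, value = TRUE)
  events <- if (length(stim)) {
    parts <- strsplit(sub("^Mk[0-9]+=", "", stim), ",")
    code <- as.integer(sub("^S\\s*", "", vapply(parts, `[`, character(1), 2L)))
    tab <- event_code_table()
    data.frame(sample = as.integer(vapply(parts, `[`, character(1), 3L)),
               code = code,
               label = tab$label[match(code, tab$code)],
               stringsAsFactors = FALSE)
  } else {
    data.frame(sample = integer(0), code = integer(0), label = character(0))
  }
  if (is.null(montage)) {
    dflt <- default_montage()
    idx <- match(ch_names, dflt$name)
    montage <- if (anyNA(idx)) {
      data.frame(name = ch_names, role = "scalp", x = NA_real_, y = NA_real_,
                 z = NA_real_, row_label = infer_row_label(ch_names),
                 stringsAsFactors = FALSE)
    } else {
      m <- dflt[idx, , drop = FALSE]; rownames(m) <- NULL; m
    }
  } else if (!identical(montage$name, ch_names)) {
    stopf("supplied montage channel names do not match the file's channels")
  }
  ref <- .parse_ini_value(sub("^; ", "", hdr), "ReferenceState") %||%
    "recording_reference"
  structure(list(data = dat, fs = fs, montage = montage, events = events,
                 reference_state = ref, trials = NULL),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s), %d events, reference: %s\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs,
              nrow(x$events %||% data.frame()), x$reference_state))
  invisible(x)
}
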