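# Minimal European Data Format (EDF) reader/writer.
#
# EDF stores a fixed-width ASCII header (256 bytes + 256 per signal) followed
# by data records of little-endian 16-bit integers, one block per signal per
# record, linearly mapped between a digital and a physical range. Only the
# plain EDF layout with a common sampling rate across signals is supported;
# amplitudes are interpreted as microvolts throughout the package.

fmt_field <- function(x, width) {
  s <- as.character(x)
  if (nchar(s) > width) stop_lfpdbs(
    sprintf("EDF header field '%s' exceeds %d chars", s, width),
    "lfpdbs_format_error")
  formatC(s, width = width, flag = "-")
}

fmt_num8 <- function(x) {
  for (digits in 7:1) {
    s <- formatC(x, digits = digits, format = "g", width = 0)
    if (nchar(s) <= 8) return(fmt_field(s, 8))
  }
  stop_lfpdbs(sprintf("cannot format %g in 8 chars", x), "lfpdbs_format_error")
}

#' Write a recording to an EDF file
#'
#' Samples are quantized to 16-bit integers over a symmetric physical range
#' `[-A, A]` with `A` the per-channel absolute maximum, so the round-trip
#' error is at most `A / 32767` per channel. If the recording spans a whole
#' number of seconds (and `fs` is an integer), 1-second data records are
#' used; otherwise the whole recording is stored as a single record.
#'
#' @param rec an [recording()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  x <- rec$samples
  n <- nrow(x); nc <- ncol(x)
  fs <- rec$fs
  if (abs(fs - round(fs)) < 1e-9 && n %% round(fs) == 0) {
    spr <- as.integer(round(fs)); dur <- 1; nrec <- n %/% spr
  } else {
    spr <- n; dur <- n / fs; nrec <- 1L
  }
  pmax <- apply(abs(x), 2L, max)
  pmax[pmax == 0] <- 1
  pmax <- signif(pmax * 1.000001, 6)  # guard against round-up clipping
  gain <- pmax / 32767
  dig <- round(sweep(x, 2L, gain, "/"))
  storage.mode(dig) <- "integer"

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    fmt_field("0", 8),
    fmt_field("X X X X", 80),
    fmt_field("Startdate X X X X", 80),
    fmt_field("01.01.00", 8), fmt_field("00.00.00", 8),
    fmt_field(256 * (nc + 1L), 8),
    fmt_field("", 44),
    fmt_field(nrec, 8),
    fmt_num8(dur),
    fmt_field(nc, 4))
  sig <- paste0(
    paste(vapply(rec$channels, fmt_field, "", width = 16), collapse = ""),
    paste(rep(fmt_field("", 80), nc), collapse = ""),
    paste(rep(fmt_field("uV", 8), nc), collapse = ""),
    paste(vapply(-pmax, fmt_num8, ""), collapse = ""),
    paste(vapply(pmax, fmt_num8, ""), collapse = ""),
    paste(rep(fmt_field(-32767, 8), nc), collapse = ""),
    paste(rep(fmt_field(32767, 8), nc), collapse = ""),
    paste(rep(fmt_field("", 80), nc), collapse = ""),
    paste(rep(fmt_field(spr, 8), nc), collapse = ""),
    paste(rep(fmt_field("", 32), nc), collapse = ""))
  writeChar(paste0(hdr, sig), con, eos = NULL)
  for (r in seq_len(nrec)) {
    rows <- ((r - 1L) * spr + 1L):(r * spr)
    for (j in seq_len(nc)) writeBin(dig[rows, j], con, size = 2L,
                                    endian = "little")
  }
  invisible(path)
}

#' Read a recording from an EDF file
#'
#' Parses the EDF header, applies each signal's physical scaling (so sample
#' values are returned in the header's physical unit, expected to be uV) and
#' returns an [recording()]. All signals must share one effective sampling
#' rate; mixed-rate layouts are rejected.
#'
#' @param path EDF file path.
#' @return an `lfp_recording`.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) {
    raw <- readBin(con, "raw", w)
    if (length(raw) < w)
      stop_lfpdbs("truncated EDF header", "lfpdbs_format_error")
    trimws(rawToChar(raw))
  }
  rd(8)                       # version
  rd(80); rd(80); rd(8); rd(8)
  hbytes <- suppressWarnings(as.integer(rd(8)))
  rd(44)
  nrec <- suppressWarnings(as.integer(rd(8)))
  dur <- suppressWarnings(as.numeric(rd(8)))
  nc <- suppressWarnings(as.integer(rd(4)))
  if (is.na(nc) || nc < 1L || is.na(nrec) || is.na(dur) || dur <= 0 ||
      is.na(hbytes) || hbytes != 256L * (nc + 1L))
    stop_lfpdbs("malformed EDF header", "lfpdbs_format_error")
  rdv <- function(w) vapply(seq_len(nc), function(i) rd(w), "")
  labels <- rdv(16)
  rdv(80)                     # transducer
  rdv(8)                      # physical dimension
  pmin <- as.numeric(rdv(8)); pmax <- as.numeric(rdv(8))
  dmin <- as.numeric(rdv(8)); dmax <- as.numeric(rdv(8))
  rdv(80)                     # prefilter
  spr <- as.integer(rdv(8))
  rdv(32)
  if (any(is.na(c(pmin, pmax, dmin, dmax, spr))) || any(dmax <= dmin))
    stop_lfpdbs("malformed EDF signal headers", "lfpdbs_format_error")
  if (length(unique(spr)) != 1L)
    stop_lfpdbs("signals with unequal sampling rates are not supported",
                "lfpdbs_unsupported_layout_error")
  spr <- spr[1L]
  fs <- spr / dur
  out <- matrix(0, nrow = nrec * spr, ncol = nc)
  for (r in seq_len(nrec)) {
    rows <- ((r - 1L) * spr + 1L):(r * spr)
    for (j in seq_len(nc)) {
      d <- readBin(con, "integer", n = spr, size = 2L, signed = TRUE,
                   endian = "little")
      if (length(d) < spr)
        stop_lfpdbs("truncated EDF data record", "lfpdbs_format_error")
      out[rows, j] <- pmin[j] + (d - dmin[j]) *
        (pmax[j] - pmin[j]) / (dmax[j] - dmin[j])
    }
  }
  recording(out, fs = fs, channels = labels, t0 = 0)
}
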