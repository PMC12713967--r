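# Minimal EDF (European Data Format) codec in base R.
# EDF stores a 256-byte ASCII global header, 256 ASCII bytes per signal of
# per-signal headers (field-major), then fixed-duration data records of
# little-endian 16-bit integers. Physical values are recovered by linear
# rescaling between the digital and physical min/max declared per signal.

edf_pad <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = -width, flag = " ")
}

edf_num <- function(x, width) edf_pad(format(x, trim = TRUE, digits = 8), width)

#' Write signals to an EDF file
#'
#' Writes one or more uniformly sampled signals to a plain EDF file with
#' 1-second data records. Sampling rates must be positive integers. The
#' last data record is padded by repeating the final sample; readers should
#' rely on the true sample counts implied by the caller's bookkeeping (the
#' padding is at most one record).
#'
#' @param signals a list of signals, each a list with elements `label`
#'   (character, <= 16 bytes), `rate` (samples/s, integer), `values`
#'   (numeric vector) and optionally `unit` (physical dimension string).
#' @param path output file path.
#' @param start_datetime POSIXct recording start; defaults to a fixed epoch
#'   so that output is byte-reproducible.
#' @return `path`, invisibly.
#' @seealso [read_edf_channel()]
#' @export
write_edf <- function(signals, path,
                      start_datetime = as.POSIXct("2000-01-01 22:00:00",
                                                  tz = "UTC")) {
  stopifnot(is.list(signals), length(signals) > 0)
  ns <- length(signals)
  for (s in signals) {
    stopifnot(!is.null(s$label), !is.null(s$rate), !is.null(s$values))
    if (s$rate != round(s$rate) || s$rate <= 0)
      stop("EDF writer supports integer sampling rates only")
  }
  nrec <- max(vapply(signals, function(s)
    ceiling(length(s$values) / s$rate), numeric(1)))
  dig_min <- -32768; dig_max <- 32767
  sig <- lapply(signals, function(s) {
    v <- as.numeric(s$values)
    pmin <- min(v); pmax <- max(v)
    if (pmax <= pmin) pmax <- pmin + 1  # constant signal: avoid zero range
    need <- nrec * s$rate
    if (length(v) < need) v <- c(v, rep(v[length(v)], need - length(v)))
    dig <- as.integer(round((v - pmin) / (pmax - pmin) *
                              (dig_max - dig_min) + dig_min))
    list(label = s$label, rate = as.integer(s$rate),
         unit = if (is.null(s$unit)) "" else s$unit,
         pmin = pmin, pmax = pmax, dig = dig)
  })
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8),
    edf_pad("X X X X", 80),
    edf_pad("Startdate 01-JAN-2000 X X X", 80),
    edf_pad(format(start_datetime, "%d.%m.%y"), 8),
    edf_pad(format(start_datetime, "%H.%M.%S"), 8),
    edf_num(256 * (ns + 1), 8),
    edf_pad("", 44),
    edf_num(nrec, 8),
    edf_num(1, 8),
    edf_num(ns, 4))
  field <- function(f, width) paste(vapply(sig, function(s)
    edf_pad(f(s), width), character(1)), collapse = "")
  hdr <- paste0(hdr,
    field(function(s) s$label, 16),
    field(function(s) "", 80),
    field(function(s) s$unit, 8),
    field(function(s) edf_num(s$pmin, 8), 8),
    field(function(s) edf_num(s$pmax, 8), 8),
    field(function(s) edf_num(dig_min, 8), 8),
    field(function(s) edf_num(dig_max, 8), 8),
    field(function(s) "", 80),
    field(function(s) edf_num(s$rate, 8), 8),
    field(function(s) "", 32))
  writeChar(hdr, con, eos = NULL, useBytes = TRUE)
  for (r in seq_len(nrec)) {
    for (s in sig) {
      idx <- ((r - 1) * s$rate + 1):(r * s$rate)
      writeBin(s$dig[idx], con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

read_edf_header <- function(con) {
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  h <- list(version = trimws(rd(8)), patient = trimws(rd(80)),
            recording = trimws(rd(80)), startdate = trimws(rd(8)),
            starttime = trimws(rd(8)),
            header_bytes = as.integer(rd(8)))
  rd(44)
  h$n_records <- as.integer(rd(8))
  h$record_duration <- as.numeric(rd(8))
  h$ns <- as.integer(rd(4))
  ns <- h$ns
  rdv <- function(w) trimws(vapply(seq_len(ns), function(i) rd(w),
                                   character(1)))
  h$labels <- rdv(16); rdv(80)
  h$units <- rdv(8)
  h$pmin <- as.numeric(rdv(8)); h$pmax <- as.numeric(rdv(8))
  h$dmin <- as.numeric(rdv(8)); h$dmax <- as.numeric(rdv(8))
  rdv(80)
  h$samples_per_record <- as.integer(rdv(8))
  rdv(32)
  h
}

#' Read one channel from an EDF file
#'
#' @param path EDF/EDF+ file path.
#' @param channel_name the signal label to extract (exact match after
#'   trimming whitespace).
#' @return A list with `values` (physical units), `rate` (samples/s),
#'   `unit`, and `label`.
#' @export
read_edf_channel <- function(path, channel_name) {
  con <- file(path, "rb")
  on.exit(close(con))
  h <- read_edf_header(con)
  i <- match(channel_name, h$labels)
  if (is.na(i))
    stop("channel '", channel_name, "' not found; available: ",
         paste(h$labels, collapse = ", "))
  spr <- h$samples_per_record
  out <- integer(h$n_records * spr[i])
  pos <- 0L
  for (r in seq_len(h$n_records)) {
    for (j in seq_len(h$ns)) {
      x <- readBin(con, "integer", n = spr[j], size = 2, signed = TRUE,
                   endian = "little")
      if (j == i) {
        out[(pos + 1):(pos + spr[j])] <- x
        pos <- pos + spr[j]
      }
    }
  }
  phys <- (out - h$dmin[i]) * (h$pmax[i] - h$pmin[i]) /
    (h$dmax[i] - h$dmin[i]) + h$pmin[i]
  list(values = phys, rate = spr[i] / h$record_duration,
       unit = h$units[i], label = h$labels[i])
}
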