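# EDF / EDF+ (16-bit) container support.
#
# The format is a 256-byte fixed-layout ASCII header, one 256-byte ASCII
# block per signal, then data records of little-endian int16 samples scaled
# linearly between a digital and a physical range. Continuous EDF and EDF+C
# are accepted; discontinuous EDF+D files are rejected because every
# downstream estimator assumes a contiguous time axis.

edf_field <- function(x, width) {
  x <- as.character(x)[1]
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)  # left-justified, space-padded
}

# pick a data-record duration (s) for which every channel has an integral
# number of samples per record
edf_record_duration <- function(rates) {
  for (d in c(1, 2, 5, 10, 30, 60)) {
    if (all(abs(rates * d - round(rates * d)) < 1e-9)) return(d)
  }
  stop("cannot find a data-record duration with whole samples per record",
       call. = FALSE)
}

#' Write a sleep recording to an EDF file
#'
#' Serializes the three channels as a continuous EDF+C file with 16-bit
#' samples. The physical range of each channel is taken from its data, so the
#' round-trip error of any sample is at most one digital quantization step
#' (range / 65535).
#'
#' @param rec A [sleep_recording()].
#' @param path Output file path.
#' @param record_duration Data-record length in seconds, or `NULL` to choose
#'   the smallest duration giving whole samples per record for every channel.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, record_duration = NULL) {
  stopifnot(inherits(rec, "sleep_recording"))
  channels <- list(rec$flow, rec$thoracic, rec$spo2)
  rates <- vapply(channels, function(s) s$rate, 0)
  if (is.null(record_duration)) record_duration <- edf_record_duration(rates)
  spr <- rates * record_duration            # samples per record, per signal
  if (any(abs(spr - round(spr)) > 1e-9)) {
    stop("record_duration must give a whole number of samples per record",
         call. = FALSE)
  }
  spr <- as.integer(round(spr))
  n_rec <- length(rec$flow$values) / spr[1]
  if (abs(n_rec - round(n_rec)) > 1e-9) {
    stop(sprintf(
      "recording duration (%g s) is not a whole number of %g-s data records",
      rec$total_duration, record_duration), call. = FALSE)
  }
  n_rec <- as.integer(round(n_rec))
  for (i in 2:3) {
    if (length(channels[[i]]$values) != n_rec * spr[i]) {
      stop(sprintf("channel '%s' length inconsistent with record layout",
                   channels[[i]]$label), call. = FALSE)
    }
  }

  phys_min <- phys_max <- dig <- vector("list", 3)
  for (i in 1:3) {
    v <- channels[[i]]$values
    lo <- min(v); hi <- max(v)
    if (hi - lo < 1e-12) { lo <- lo - 1; hi <- hi + 1 }  # constant channel
    phys_min[[i]] <- lo; phys_max[[i]] <- hi
    # linear map physical -> digital [-32768, 32767]
    dig[[i]] <- as.integer(round((v - lo) / (hi - lo) * 65535 - 32768))
  }

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_field("0", 8),
    edf_field("X X X X", 80),
    edf_field("Startdate X X X X", 80),
    edf_field("01.01.00", 8),
    edf_field("00.00.00", 8),
    edf_field(256 * (1 + 3), 8),
    edf_field("EDF+C", 44),
    edf_field(n_rec, 8),
    edf_field(format(record_duration, nsmall = 0), 8),
    edf_field(3, 4)
  )
  per_sig <- function(f, width) {
    paste0(vapply(1:3, function(i) edf_field(f(i), width), ""), collapse = "")
  }
  dims <- c("", "", "%")
  hdr <- paste0(
    hdr,
    per_sig(function(i) channels[[i]]$label, 16),
    per_sig(function(i) "", 80),
    per_sig(function(i) dims[i], 8),
    per_sig(function(i) formatC(phys_min[[i]], digits = 6, format = "g"), 8),
    per_sig(function(i) formatC(phys_max[[i]], digits = 6, format = "g"), 8),
    per_sig(function(i) "-32768", 8),
    per_sig(function(i) "32767", 8),
    per_sig(function(i) "", 80),
    per_sig(function(i) spr[i], 8),
    per_sig(function(i) "", 32)
  )
  writeChar(hdr, con, eos = NULL)

  # interleave channels record by record
  out <- integer(n_rec * sum(spr))
  pos <- 0L
  offs <- c(0L, 0L, 0L)
  for (r in seq_len(n_rec)) {
    for (i in 1:3) {
      out[(pos + 1):(pos + spr[i])] <- dig[[i]][(offs[i] + 1):(offs[i] + spr[i])]
      pos <- pos + spr[i]
      offs[i] <- offs[i] + spr[i]
    }
  }
  writeBin(out, con, size = 2, endian = "little")
  invisible(path)
}

edf_read_header <- function(con) {
  rd <- function(w) {
    raw <- readChar(con, w, useBytes = TRUE)
    trimws(raw)
  }
  h <- list(
    version = rd(8), patient = rd(80), recording = rd(80),
    start_date = rd(8), start_time = rd(8),
    header_bytes = as.integer(rd(8)), reserved = rd(44),
    n_records = as.integer(rd(8)), record_duration = as.numeric(rd(8)),
    n_signals = as.integer(rd(4))
  )
  ns <- h$n_signals
  if (is.na(ns) || ns < 1) stop("unreadable EDF header", call. = FALSE)
  sig_field <- function(w, as = identity) {
    vapply(seq_len(ns), function(i) as(trimws(readChar(con, w, useBytes = TRUE))),
           if (identical(as, identity)) "" else 0)
  }
  h$labels <- sig_field(16)
  h$transducer <- sig_field(80)
  h$dim <- sig_field(8)
  h$phys_min <- sig_field(8, as.numeric)
  h$phys_max <- sig_field(8, as.numeric)
  h$dig_min <- sig_field(8, as.numeric)
  h$dig_max <- sig_field(8, as.numeric)
  h$prefilter <- sig_field(80)
  h$spr <- sig_field(8, as.numeric)
  h$sig_reserved <- sig_field(32)
  h
}

#' Read a sleep recording from an EDF file
#'
#' Parses EDF / EDF+C files and maps file channels onto the three
#' physiological roles via `channel_map`. Native per-channel sampling rates
#' are preserved. Discontinuous EDF+D files are rejected.
#'
#' @param path Path to an EDF or EDF+ file.
#' @param channel_map Named list or vector with entries `flow`, `thoracic`,
#'   `spo2` giving the channel labels in the file.
#' @return A [sleep_recording()].
#' @examples
#' \dontrun{
#' rec <- read_recording("night1.edf",
#'                       channel_map = list(flow = "Flow", thoracic = "Thorax",
#'                                          spo2 = "SpO2"))
#' }
#' @export
read_recording <- function(path,
                           channel_map = list(flow = "Flow",
                                              thoracic = "Thorax",
                                              spo2 = "SpO2")) {
  if (!file.exists(path)) {
    stop(sprintf("EDF file not found: '%s'", path), call. = FALSE)
  }
  for (role in c("flow", "thoracic", "spo2")) {
    if (is.null(channel_map[[role]])) {
      stop(sprintf("channel_map must name the '%s' channel", role),
           call. = FALSE)
    }
  }
  con <- file(path, "rb")
  on.exit(close(con))
  h <- edf_read_header(con)
  if (startsWith(h$reserved, "EDF+D")) {
    stop("discontinuous EDF+D recordings are not supported: the analysis assumes contiguous time",
         call. = FALSE)
  }
  spr <- as.integer(round(h$spr))
  ns <- h$n_signals
  seek(con, h$header_bytes)
  raw <- readBin(con, "integer", n = h$n_records * sum(spr),
                 size = 2, endian = "little", signed = TRUE)
  if (length(raw) < h$n_records * sum(spr)) {
    stop("EDF file truncated: fewer samples than the header declares",
         call. = FALSE)
  }

  pick <- function(role) {
    lab <- channel_map[[role]]
    i <- match(lab, h$labels)
    if (is.na(i)) {
      stop(sprintf("channel '%s' (mapped to %s) not present in EDF file; available: %s",
                   lab, role, paste(h$labels, collapse = ", ")), call. = FALSE)
    }
    i
  }
  idx <- vapply(c("flow", "thoracic", "spo2"), pick, 0L)

  # de-interleave the requested signals
  rec_len <- sum(spr)
  starts <- cumsum(c(0L, spr))[seq_len(ns)]
  get_signal <- function(i) {
    take <- as.vector(outer(seq_len(spr[i]) + starts[i],
                            (seq_len(h$n_records) - 1L) * rec_len, `+`))
    d <- raw[take]
    scale <- (h$phys_max[i] - h$phys_min[i]) / (h$dig_max[i] - h$dig_min[i])
    vals <- h$phys_min[i] + (d - h$dig_min[i]) * scale
    series(vals, rate = spr[i] / h$record_duration, label = h$labels[i])
  }
  sleep_recording(flow = get_signal(idx[1]),
                  thoracic = get_signal(idx[2]),
                  spo2 = get_signal(idx[3]))
}
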