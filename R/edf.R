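# Minimal European Data Format (EDF) reader/writer for continuous telemetry.
# EDF stores a fixed ASCII header, one header block per signal, then data
# records of 16-bit little-endian integers; per-signal sampling rates may
# differ (here: EEG/EMG at 500 Hz, activity at 200 Hz, 1 s records).

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = width, flag = "-")
}

edf_num <- function(x, width = 8) {
  s <- formatC(x, width = width, format = "g", flag = "-")
  if (nchar(s) > width) s <- substr(s, 1, width)
  s
}

#' Write a recording to an EDF file
#'
#' One EDF signal per channel (EEG, EMG, ACT), 1 s data records, physical
#' ranges chosen symmetric around zero to cover the data. EDF quantizes to
#' 16 bits; amplitudes survive a round trip to within one quantization step
#' of the chosen physical range, while sample counts and rates are exact.
#'
#' @param recording a [signal_recording()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(recording, path) {
  stopifnot(inherits(recording, "signal_recording"))
  dur <- recording$duration_s
  if (abs(dur - round(dur)) > 1e-9)
    stop("EDF writer uses 1 s records; duration_s must be a whole number of seconds")
  nrec <- as.integer(round(dur))
  chans <- list(
    list(label = "EEG", dim = "uV", x = recording$eeg,
         rate = recording$eeg_rate_hz),
    list(label = "EMG", dim = "uV", x = recording$emg,
         rate = recording$eeg_rate_hz),
    list(label = "ACT", dim = "a.u.", x = recording$activity,
         rate = recording$activity_rate_hz)
  )
  ns <- length(chans)
  spr <- vapply(chans, function(ch) as.integer(round(ch$rate)), integer(1))
  for (i in seq_len(ns)) {
    need <- nrec * spr[i]
    x <- chans[[i]]$x
    if (length(x) < need) x <- c(x, numeric(need - length(x)))
    chans[[i]]$x <- x[seq_len(need)]
  }

  # physical range: symmetric, written to the header then re-parsed so the
  # quantization uses exactly what a reader will see
  pmax_str <- character(ns); pmin_str <- character(ns); pmax_val <- numeric(ns)
  for (i in seq_len(ns)) {
    m <- max(abs(chans[[i]]$x))
    m <- if (m == 0) 1 else m * 1.0001
    s <- edf_num(signif(m, 6))
    v <- abs(as.numeric(s))
    if (v < m) { s <- edf_num(signif(m * 1.01, 4)); v <- abs(as.numeric(s)) }
    pmax_str[i] <- s
    pmin_str[i] <- edf_num(-as.numeric(s))
    pmax_val[i] <- v
  }

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeChar(s, con, nchars = nchar(s), eos = NULL)
  wr(edf_pad("0", 8))
  wr(edf_pad(recording$subject_id, 80))
  wr(edf_pad(paste("group", recording$group_label), 80))
  wr(edf_pad("01.01.26", 8)); wr(edf_pad("00.00.00", 8))
  wr(edf_pad(256 * (ns + 1), 8))
  wr(edf_pad("", 44))
  wr(edf_pad(nrec, 8)); wr(edf_pad("1", 8)); wr(edf_pad(ns, 4))
  for (ch in chans) wr(edf_pad(ch$label, 16))
  for (ch in chans) wr(edf_pad("", 80))
  for (ch in chans) wr(edf_pad(ch$dim, 8))
  for (s in pmin_str) wr(edf_pad(s, 8))
  for (s in pmax_str) wr(edf_pad(s, 8))
  for (i in seq_len(ns)) wr(edf_pad("-32768", 8))
  for (i in seq_len(ns)) wr(edf_pad("32767", 8))
  for (ch in chans) wr(edf_pad("", 80))
  for (i in seq_len(ns)) wr(edf_pad(spr[i], 8))
  for (i in seq_len(ns)) wr(edf_pad("", 32))

  # digital conversion, then interleave into 1 s records
  tot <- sum(spr)
  dig <- integer(nrec * tot)
  off <- c(0L, cumsum(spr))
  for (i in seq_len(ns)) {
    g <- (2 * pmax_val[i]) / 65535
    d <- as.integer(pmin(32767, pmax(-32768,
      round((chans[[i]]$x + pmax_val[i]) / g) - 32768L)))
    idx <- rep(seq_len(nrec) - 1L, each = spr[i]) * tot + off[i] +
      rep(seq_len(spr[i]), times = nrec)
    dig[idx] <- d
  }
  writeBin(dig, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a recording from an EDF file
#'
#' Channels are located by case-insensitive prefix match on the signal label
#' ("EEG", "EMG", "ACT"). A missing ACT channel yields a zero activity trace
#' with `activity_missing = TRUE`; missing EEG or EMG is an error.
#'
#' @param path EDF file path.
#' @return A [signal_recording()].
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop("cannot read EDF file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) {
    raw <- readBin(con, "raw", n)
    trimws(rawToChar(raw))
  }
  rd(8)                                   # version
  subject_id <- rd(80)
  rec_field <- rd(80)
  rd(8); rd(8)                            # date, time
  rd(8); rd(44)                           # header bytes, reserved
  nrec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1) stop("not a valid EDF file: ", path)
  labels <- vapply(seq_len(ns), function(i) rd(16), character(1))
  for (i in seq_len(ns)) rd(80)           # transducer
  dims <- vapply(seq_len(ns), function(i) rd(8), character(1))
  pmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  pmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  for (i in seq_len(ns)) rd(80)           # prefiltering
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), character(1)))
  for (i in seq_len(ns)) rd(32)           # reserved

  tot <- sum(spr)
  dig <- readBin(con, "integer", n = nrec * tot, size = 2, signed = TRUE,
                 endian = "little")
  off <- c(0L, cumsum(spr))
  phys <- vector("list", ns)
  for (i in seq_len(ns)) {
    idx <- rep(seq_len(nrec) - 1L, each = spr[i]) * tot + off[i] +
      rep(seq_len(spr[i]), times = nrec)
    g <- (pmax[i] - pmin[i]) / (dmax[i] - dmin[i])
    phys[[i]] <- (dig[idx] - dmin[i]) * g + pmin[i]
  }

  find_ch <- function(prefix) {
    hit <- which(startsWith(toupper(labels), prefix))
    if (length(hit)) hit[1] else NA_integer_
  }
  i_eeg <- find_ch("EEG"); i_emg <- find_ch("EMG"); i_act <- find_ch("ACT")
  if (is.na(i_eeg)) stop("EEG channel not found in ", path)
  if (is.na(i_emg)) stop("EMG channel not found in ", path)
  dur <- nrec * rec_dur
  eeg_rate <- spr[i_eeg] / rec_dur
  if (is.na(i_act)) {
    act <- NULL; act_rate <- 200
  } else {
    act <- phys[[i_act]]; act_rate <- spr[i_act] / rec_dur
  }
  grp <- sub("^group ", "", rec_field)
  signal_recording(
    eeg = phys[[i_eeg]], emg = phys[[i_emg]], activity = act,
    eeg_rate_hz = eeg_rate, activity_rate_hz = act_rate, duration_s = dur,
    subject_id = subject_id, group_label = if (nzchar(grp)) grp else "WT",
    activity_missing = is.na(i_act)
  )
}
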