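# widest decimal representation of x fitting an n-byte ASCII header field
edf_num_ascii <- function(x, n) {
  s <- as.character(x)
  for (d in 7:1) {
    s <- formatC(x, format = "g", digits = d)
    if (nchar(s) <= n) break
  }
  s
}

#' Read a two-channel PSG recording from an EDF file
#'
#' Reads the named ECG and respiratory-effort channels from a European Data
#' Format (EDF, 16-bit) file. Only plain EDF is supported; EDF+ annotation
#' streams are ignored territory and not parsed.
#'
#' @param path Path to the EDF file.
#' @param ecg_label Channel label of the ECG signal (matched after trimming
#'   whitespace).
#' @param rip_label Channel label of the thoracic respiratory-effort (RIP)
#'   signal.
#' @param patient_id Optional patient identifier; defaults to the patient
#'   field of the EDF header.
#' @param ahi_reference Optional reference apnea-hypopnea index (events/hour),
#'   carried along for evaluation only.
#' @return A [recording] with both channels and their header sampling rates.
#' @export
read_edf <- function(path, ecg_label = "ECG", rip_label = "Thorax",
                     patient_id = NULL, ahi_reference = NA_real_) {
  cs_assert(file.exists(path), sprintf("EDF file not found: %s", path),
            "format_error")
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 256L, useBytes = TRUE)
  if (nchar(hdr, type = "bytes") < 256L)
    cs_error("truncated EDF header", "format_error")
  fld <- function(s, from, len) trimws(substr(s, from, from + len - 1L))
  patient <- fld(hdr, 9L, 80L)
  n_records <- suppressWarnings(as.integer(fld(hdr, 237L, 8L)))
  rec_dur <- suppressWarnings(as.numeric(fld(hdr, 245L, 8L)))
  ns <- suppressWarnings(as.integer(fld(hdr, 253L, 4L)))
  if (anyNA(c(n_records, rec_dur, ns)) || ns < 1L || rec_dur <= 0)
    cs_error("unreadable EDF header fields", "format_error")
  shdr <- readChar(con, ns * 256L, useBytes = TRUE)
  # offsets (bytes into the per-signal header block, each field ns-wide):
  # label 16, transducer 80, phys dim 8, phys min 8, phys max 8,
  # dig min 8, dig max 8, prefilter 80, samples/record 8, reserved 32
  field_at <- function(start, len) {
    vapply(seq_len(ns), function(i) {
      trimws(substr(shdr, start * ns + (i - 1L) * len + 1L,
                    start * ns + i * len))
    }, "")
  }
  # cumulative byte starts of each field block
  starts <- cumsum(c(0L, 16L, 80L, 8L, 8L, 8L, 8L, 8L, 80L, 8L))
  labels   <- field_at(starts[1], 16L)
  physdim  <- field_at(starts[3], 8L)
  phys_min <- as.numeric(field_at(starts[4], 8L))
  phys_max <- as.numeric(field_at(starts[5], 8L))
  dig_min  <- as.numeric(field_at(starts[6], 8L))
  dig_max  <- as.numeric(field_at(starts[7], 8L))
  spr      <- as.integer(field_at(starts[9], 8L))
  if (anyNA(phys_min) || anyNA(phys_max) || anyNA(dig_min) ||
      anyNA(dig_max) || anyNA(spr))
    cs_error("unreadable EDF signal header", "format_error")
  raw <- readBin(con, integer(), n = n_records * sum(spr), size = 2L,
                 endian = "little")
  if (length(raw) < n_records * sum(spr))
    cs_error("EDF data section shorter than header promises", "format_error")
  pick <- function(label) {
    i <- match(label, labels)
    if (is.na(i))
      cs_error(sprintf("channel '%s' not present (have: %s)", label,
                       paste(labels, collapse = ", ")),
               "missing_channel_error")
    # gather this signal's samples from each record
    offs <- cumsum(c(0L, spr))[i]
    idx <- as.vector(outer(seq_len(spr[i]) + offs,
                           (seq_len(n_records) - 1L) * sum(spr), "+"))
    d <- raw[idx]
    gain <- (phys_max[i] - phys_min[i]) / (dig_max[i] - dig_min[i])
    list(x = phys_min[i] + (d - dig_min[i]) * gain,
         rate = spr[i] / rec_dur)
  }
  ecg <- pick(ecg_label)
  rip <- pick(rip_label)
  recording(patient_id = if (is.null(patient_id)) patient else patient_id,
            ecg = ecg$x, ecg_rate = ecg$rate,
            rip = rip$x, rip_rate = rip$rate,
            ahi_reference = ahi_reference)
}

#' Write a recording to an EDF file
#'
#' Stores both channels as 16-bit EDF with 1-second data records; sample
#' rates must therefore be whole numbers. The trailing partial record is
#' dropped. Values are quantized to the 16-bit digital range over each
#' channel's physical range.
#'
#' @param rec A [recording].
#' @param path Output path.
#' @param ecg_label,rip_label Channel labels written to the header.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path, ecg_label = "ECG", rip_label = "Thorax") {
  stopifnot(inherits(rec, "psg_recording"))
  rates <- c(rec$ecg$rate, rec$rip$rate)
  cs_assert(all(rates == round(rates)),
            "EDF writer requires integer sample rates (1 s records)",
            "parameter_error")
  chans <- list(list(label = ecg_label, x = rec$ecg$x, rate = rec$ecg$rate),
                list(label = rip_label, x = rec$rip$x, rate = rec$rip$rate))
  n_records <- min(vapply(chans, function(ch)
    floor(length(ch$x) / ch$rate), 0))
  ns <- length(chans)
  pad <- function(s, n) formatC(s, width = n, flag = "-")
  num <- function(x, n) formatC(edf_num_ascii(x, n), width = n, flag = "-")
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(pad("0", 8L), pad("X", 80L), pad("cardiosleep", 80L),
                pad("01.01.20", 8L), pad("00.00.00", 8L),
                num(256L * (1L + ns), 8L), pad("", 44L),
                num(n_records, 8L), num(1, 8L), num(ns, 4L))
  writeChar(hdr, con, eos = NULL, useBytes = TRUE)
  pm <- lapply(chans, function(ch) {
    r <- range(ch$x[seq_len(n_records * ch$rate)])
    if (diff(r) == 0) r <- r + c(-1, 1)
    r
  })
  blk <- function(f) paste(vapply(seq_len(ns), f, ""), collapse = "")
  writeChar(paste0(
    blk(function(i) pad(chans[[i]]$label, 16L)),
    blk(function(i) pad("", 80L)),
    blk(function(i) pad("au", 8L)),
    blk(function(i) num(pm[[i]][1], 8L)),
    blk(function(i) num(pm[[i]][2], 8L)),
    blk(function(i) num(-32768L, 8L)),
    blk(function(i) num(32767L, 8L)),
    blk(function(i) pad("", 80L)),
    blk(function(i) num(chans[[i]]$rate, 8L)),
    blk(function(i) pad("", 32L))), con, eos = NULL, useBytes = TRUE)
  # re-read the ASCII physical ranges so quantization matches the file
  pm_file <- lapply(pm, function(r)
    vapply(r, function(x) as.numeric(edf_num_ascii(x, 8L)), 0))
  enc <- lapply(seq_len(ns), function(i) {
    r <- pm_file[[i]]
    x <- chans[[i]]$x[seq_len(n_records * chans[[i]]$rate)]
    as.integer(round((x - r[1]) / (r[2] - r[1]) * 65535 - 32768))
  })
  spr <- vapply(chans, function(ch) as.integer(ch$rate), 0L)
  out <- integer(n_records * sum(spr))
  at <- 0L
  for (rec_i in seq_len(n_records)) {
    for (i in seq_len(ns)) {
      out[at + seq_len(spr[i])] <- enc[[i]][(rec_i - 1L) * spr[i] +
                                              seq_len(spr[i])]
      at <- at + spr[i]
    }
  }
  writeBin(out, con, size = 2L, endian = "little")
  invisible(path)
}
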