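# Minimal EDF/EDF+ reader and writer. EDF is a fixed-layout format: an
# ASCII header (256 bytes + 256 per signal) followed by data records of
# little-endian int16 samples. No R reader ships with the runtime, so the
# subset needed here (uniform-rate signals plus an optional
# "EDF Annotations" channel with TAL-encoded events) is implemented
# directly.

edf_field <- function(con, n) {
  raw <- readChar(con, n, useBytes = TRUE)
  if (nchar(raw, type = "bytes") < n)
    stop_config("malformed EDF header: truncated at byte offset %d",
                seek(con))
  trimws(raw)
}

#' Normalize an EEG channel label to 10-10 form
#'
#' Strips trailing dots and whitespace (Physionet-style padding) and
#' canonicalizes case (`"Fc5."` to `"FC5"`, `"CZ"` to `"Cz"`). Labels
#' that do not look like 10-10 electrode names pass through verbatim with
#' a warning.
#'
#' @param label character vector of raw labels.
#' @return normalized labels.
#' @export
normalize_channel_label <- function(label) {
  vapply(label, function(l) {
    x <- gsub("\\.+$", "", trimws(l))
    if (grepl("^[A-Za-z]{1,3}[0-9]{0,2}[Zz]?$", x) && nchar(x) >= 2L) {
      x <- toupper(x)
      sub("Z$", "z", x)
    } else {
      warning(sprintf("unrecognized channel label '%s' passed through", l),
              call. = FALSE)
      x
    }
  }, "", USE.NAMES = FALSE)
}

# parse the time-stamped annotation lists of one EDF+ annotations record
parse_tal <- function(bytes) {
  txt <- rawToChar(bytes[bytes != as.raw(0)])
  tals <- strsplit(txt, "\x14\x14", fixed = TRUE)[[1]]
  out <- list()
  for (tal in tals) {
    parts <- strsplit(tal, "\x14", fixed = TRUE)[[1]]
    if (!length(parts)) next
    head <- strsplit(parts[1L], "\x15", fixed = TRUE)[[1]]
    onset <- suppressWarnings(as.numeric(head[1L]))
    if (!is.finite(onset)) next
    labels <- parts[-1L]
    labels <- labels[nzchar(labels)]
    for (lb in labels)
      out[[length(out) + 1L]] <- data.frame(onset_sec = onset, label = lb)
  }
  if (length(out)) do.call(rbind, out) else NULL
}

#' Read an EDF/EDF+ file
#'
#' Reads all ordinary signals (which must share one sampling rate) into a
#' `channel x sample` matrix in physical units, normalizes channel labels,
#' and parses EDF+ annotations into labeled events. Truncated files raise
#' a format error rather than returning a partial read.
#'
#' @param path EDF file path.
#' @return list with `signals` (channel x sample matrix), `meta`
#'   (`recording_meta`: `fs`, `n_channels`, `channel_names`, `n_samples`,
#'   `source_path`, `subject`), `events` (data frame `onset_sec`,
#'   `onset_sample`, `label`; zero rows if none).
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  edf_field(con, 8L)                      # version
  subject <- edf_field(con, 80L)
  edf_field(con, 80L)                     # recording id
  edf_field(con, 8L); edf_field(con, 8L)  # start date/time
  header_bytes <- as.integer(edf_field(con, 8L))
  edf_field(con, 44L)
  n_records <- as.integer(edf_field(con, 8L))
  record_dur <- as.numeric(edf_field(con, 8L))
  ns <- as.integer(edf_field(con, 4L))
  if (is.na(ns) || ns < 1L) stop_config("malformed EDF header: bad signal count")

  sig_field <- function(n) vapply(seq_len(ns), function(i) edf_field(con, n), "")
  labels_raw <- sig_field(16L)
  sig_field(80L)                          # transducer
  sig_field(8L)                           # physical dimension
  phys_min <- as.numeric(sig_field(8L))
  phys_max <- as.numeric(sig_field(8L))
  dig_min <- as.numeric(sig_field(8L))
  dig_max <- as.numeric(sig_field(8L))
  sig_field(80L)                          # prefilter
  spr <- as.integer(sig_field(8L))        # samples per record
  sig_field(32L)

  rec_bytes <- 2L * sum(spr)
  data_bytes <- file.size(path) - header_bytes
  if (n_records < 0L) n_records <- as.integer(data_bytes %/% rec_bytes)
  if (data_bytes < n_records * rec_bytes)
    stop_config("malformed EDF: expected %d data bytes, found %d",
                n_records * rec_bytes, data_bytes)

  is_annot <- labels_raw == "EDF Annotations"
  ord <- which(!is_annot)
  if (!length(ord)) stop_config("EDF file has no ordinary signals")
  if (length(unique(spr[ord])) != 1L)
    stop_config("signals with differing sampling rates are not supported")
  fs <- spr[ord][1L] / record_dur

  seek(con, header_bytes)
  sig <- matrix(0, length(ord), n_records * spr[ord][1L])
  annot_rows <- list()
  for (r in seq_len(n_records)) {
    for (s in seq_len(ns)) {
      if (is_annot[s]) {
        bytes <- readBin(con, "raw", 2L * spr[s])
        ev <- parse_tal(bytes)
        if (!is.null(ev)) annot_rows[[length(annot_rows) + 1L]] <- ev
      } else {
        dig <- readBin(con, "integer", spr[s], size = 2L, signed = TRUE,
                       endian = "little")
        if (length(dig) < spr[s])
          stop_config("malformed EDF: truncated data record %d", r)
        k <- match(s, ord)
        gain <- (phys_max[s] - phys_min[s]) / (dig_max[s] - dig_min[s])
        sig[k, ((r - 1L) * spr[s] + 1L):(r * spr[s])] <-
          phys_min[s] + (dig - dig_min[s]) * gain
      }
    }
  }
  events <- if (length(annot_rows)) {
    ev <- do.call(rbind, annot_rows)
    ev <- ev[order(ev$onset_sec), , drop = FALSE]
    ev$onset_sample <- as.integer(round(ev$onset_sec * fs))
    rownames(ev) <- NULL
    ev[, c("onset_sec", "onset_sample", "label")]
  } else {
    if (any(is_annot))
      warning("annotation track present but empty", call. = FALSE)
    else
      warning("no annotation track; returning empty events", call. = FALSE)
    data.frame(onset_sec = numeric(0), onset_sample = integer(0),
               label = character(0))
  }
  meta <- structure(list(subject = subject, fs = fs,
                         n_channels = length(ord),
                         channel_names = normalize_channel_label(labels_raw[ord]),
                         n_samples = ncol(sig), source_path = path),
                    class = "recording_meta")
  list(signals = sig, meta = meta, events = events)
}

pad_field <- function(x, n) formatC(as.character(x), width = -n)

#' Write a minimal EDF+ file
#'
#' Writer counterpart of [read_edf()], mainly for building synthetic
#' fixtures: one data record per second, int16 quantization over the
#' per-channel physical range, optional events encoded as an
#' "EDF Annotations" signal.
#'
#' @param path output file.
#' @param signals `channel x sample` matrix; the sample count must be a
#'   multiple of `fs`.
#' @param fs sampling rate (integer samples per second).
#' @param channel_names channel labels.
#' @param events optional data frame with `onset_sec` and `label`.
#' @param subject subject identifier stored in the header.
#' @return `path`, invisibly.
#' @export
write_edf <- function(path, signals, fs, channel_names,
                      events = NULL, subject = "X") {
  stopifnot(is.matrix(signals), nrow(signals) == length(channel_names))
  n_samp <- ncol(signals)
  if (n_samp %% fs != 0) stop_config("sample count must be a multiple of fs")
  n_records <- n_samp %/% fs
  n_ch <- nrow(signals)
  has_annot <- !is.null(events) && nrow(events) > 0
  annot_len <- 60L   # bytes per record for the annotation signal (30 int16)
  ns <- n_ch + has_annot

  phys_min <- apply(signals, 1L, min)
  phys_max <- apply(signals, 1L, max)
  span <- pmax(phys_max - phys_min, 1e-6)
  phys_max <- phys_min + span

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, n) writeChar(pad_field(x, n), con, eos = NULL)
  wr("0", 8L); wr(subject, 80L); wr("synthetic", 80L)
  wr("01.01.26", 8L); wr("00.00.00", 8L)
  wr(256L * (1L + ns), 8L)
  wr(if (has_annot) "EDF+C" else "", 44L)
  wr(n_records, 8L); wr("1", 8L); wr(ns, 4L)
  labels <- c(channel_names, if (has_annot) "EDF Annotations")
  for (l in labels) wr(l, 16L)
  for (i in seq_len(ns)) wr("", 80L)
  for (i in seq_len(ns)) wr("uV", 8L)
  for (v in c(phys_min, if (has_annot) -1)) wr(format(v, digits = 6), 8L)
  for (v in c(phys_max, if (has_annot) 1)) wr(format(v, digits = 6), 8L)
  for (i in seq_len(ns)) wr("-32768", 8L)
  for (i in seq_len(ns)) wr("32767", 8L)
  for (i in seq_len(ns)) wr("", 80L)
  for (v in c(rep(fs, n_ch), if (has_annot) annot_len %/% 2L)) wr(v, 8L)
  for (i in seq_len(ns)) wr("", 32L)

  gain <- 65535 / span
  for (r in seq_len(n_records)) {
    for (ch in seq_len(n_ch)) {
      x <- signals[ch, ((r - 1L) * fs + 1L):(r * fs)]
      dig <- as.integer(round((x - phys_min[ch]) * gain[ch]) - 32768)
      writeBin(pmin(pmax(dig, -32768L), 32767L), con, size = 2L,
               endian = "little")
    }
    if (has_annot) {
      tal <- sprintf("+%d\x14\x14", r - 1L)  # record-keeping TAL
      in_rec <- events[events$onset_sec >= r - 1L & events$onset_sec < r, ,
                       drop = FALSE]
      for (i in seq_len(nrow(in_rec)))
        tal <- paste0(tal, sprintf("+%g\x14%s\x14", in_rec$onset_sec[i],
                                   in_rec$label[i]))
      bytes <- charToRaw(tal)
      if (length(bytes) > annot_len)
        stop_config("too many events in one record for the fixed TAL buffer")
      writeBin(c(bytes, raw(annot_len - length(bytes))), con)
    }
  }
  invisible(path)
}
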