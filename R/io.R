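# Minimal readers/writers for the standard formats the pipeline touches:
# BrainVision (.vhdr/.vmrk/.eeg, IEEE float 32, multiplexed) for EEG, RIFF
# WAV (16-bit PCM or float 32, mono) for stimulus audio, and CSV/RDS for
# the internal containers.

#' Write a recording to BrainVision files
#'
#' Produces the .vhdr/.vmrk/.eeg triplet (multiplexed IEEE float 32,
#' microvolt resolution 1) with triggers as markers.
#'
#' @param rec a [continuous_recording()].
#' @param basename path without extension; the three files are written next
#'   to it.
#' @return the .vhdr path, invisibly.
#' @export
write_brainvision <- function(rec, basename) {
  stopifnot(inherits(rec, "continuous_recording"))
  vhdr <- paste0(basename, ".vhdr")
  vmrk <- paste0(basename, ".vmrk")
  eeg <- paste0(basename, ".eeg")
  nch <- nrow(rec$samples)
  hdr <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "", "[Common Infos]",
    paste0("DataFile=", basename(eeg)),
    paste0("MarkerFile=", basename(vmrk)),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", nch),
    paste0("SamplingInterval=", format(1e6 / rec$fs, scientific = FALSE)),
    "", "[Binary Infos]",
    "BinaryFormat=IEEE_FLOAT_32",
    "", "[Channel Infos]",
    sprintf("Ch%d=%s,,1,µV", seq_len(nch), rec$channel_labels)
  )
  writeLines(hdr, vhdr)
  mk <- c("Brain Vision Data Exchange Marker File, Version 1.0",
          "", "[Common Infos]",
          paste0("DataFile=", basename(eeg)),
          "", "[Marker Infos]",
          "Mk1=New Segment,,1,1,0")
  if (nrow(rec$triggers) > 0) {
    mk <- c(mk, sprintf("Mk%d=Stimulus,%s,%d,1,0",
                        seq_len(nrow(rec$triggers)) + 1L,
                        rec$triggers$code, rec$triggers$sample))
  }
  writeLines(mk, vmrk)
  con <- file(eeg, "wb")
  on.exit(close(con))
  writeBin(as.vector(rec$samples), con, size = 4, endian = "little")
  invisible(vhdr)
}

# Parse one key=value section body of an INI-style BrainVision header.
.bv_ini <- function(lines) {
  kv <- grep("=", lines, fixed = TRUE, value = TRUE)
  keys <- sub("=.*$", "", kv)
  vals <- sub("^[^=]*=", "", kv)
  stats::setNames(vals, keys)
}

#' Read a BrainVision recording
#'
#' Supports the subset this package writes: binary multiplexed or
#' vectorized IEEE float 32 / int 16 data with per-channel resolution, and
#' stimulus markers as triggers.
#'
#' @param vhdr_path path to the .vhdr header.
#' @return a [continuous_recording()].
#' @export
read_brainvision <- function(vhdr_path) {
  lines <- readLines(vhdr_path, warn = FALSE)
  ini <- .bv_ini(lines)
  dir <- dirname(vhdr_path)
  nch <- as.integer(ini[["NumberOfChannels"]])
  fs <- 1e6 / as.numeric(ini[["SamplingInterval"]])
  fmt <- ini[["BinaryFormat"]] %||% "IEEE_FLOAT_32"
  orient <- toupper(ini[["DataOrientation"]] %||% "MULTIPLEXED")
  ch_lines <- grep("^Ch[0-9]+=", lines, value = TRUE)
  ch_fields <- strsplit(sub("^Ch[0-9]+=", "", ch_lines), ",")
  labels <- vapply(ch_fields, `[`, character(1), 1)
  resol <- vapply(ch_fields, function(f) {
    r <- suppressWarnings(as.numeric(f[3]))
    if (is.na(r)) 1 else r
  }, numeric(1))
  eeg_path <- file.path(dir, ini[["DataFile"]])
  sz <- file.info(eeg_path)$size
  con <- file(eeg_path, "rb")
  on.exit(close(con))
  raw_vals <- if (fmt == "IEEE_FLOAT_32") {
    readBin(con, numeric(), n = sz / 4, size = 4, endian = "little")
  } else if (fmt == "INT_16") {
    readBin(con, integer(), n = sz / 2, size = 2, signed = TRUE,
            endian = "little")
  } else stop("unsupported BinaryFormat: ", fmt)
  nt <- length(raw_vals) %/% nch
  samples <- if (orient == "MULTIPLEXED") {
    matrix(raw_vals[seq_len(nch * nt)], nrow = nch)
  } else {
    t(matrix(raw_vals[seq_len(nch * nt)], nrow = nt))
  }
  samples <- samples * resol
  triggers <- data.frame(sample = integer(0), code = character(0))
  vmrk_path <- file.path(dir, ini[["MarkerFile"]] %||% "")
  if (nzchar(ini[["MarkerFile"]] %||% "") && file.exists(vmrk_path)) {
    mlines <- grep("^Mk[0-9]+=", readLines(vmrk_path, warn = FALSE),
                   value = TRUE)
    parts <- strsplit(sub("^Mk[0-9]+=", "", mlines), ",")
    stim <- vapply(parts, `[`, character(1), 1) == "Stimulus"
    if (any(stim)) {
      triggers <- data.frame(
        sample = as.integer(vapply(parts[stim], `[`, character(1), 3)),
        code = vapply(parts[stim], `[`, character(1), 2))
    }
  }
  continuous_recording(samples, fs, labels, triggers)
}

#' Write a mono WAV file
#'
#' @param x numeric vector in [-1, 1] (clipped otherwise).
#' @param fs sampling rate, Hz.
#' @param path output path.
#' @param bits 16 (PCM) or 32 (IEEE float).
#' @return `path`, invisibly.
#' @export
write_wav <- function(x, fs, path, bits = 16) {
  stopifnot(bits %in% c(16, 32))
  con <- file(path, "wb")
  on.exit(close(con))
  n <- length(x)
  bytes_per <- bits / 8
  data_size <- n * bytes_per
  fmt_code <- if (bits == 16) 1L else 3L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmt_code, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")          # mono
  writeBin(as.integer(fs), con, size = 4, endian = "little")
  writeBin(as.integer(fs * bytes_per), con, size = 4, endian = "little")
  writeBin(as.integer(bytes_per), con, size = 2, endian = "little")
  writeBin(as.integer(bits), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  if (bits == 16) {
    writeBin(as.integer(round(pmin(pmax(x, -1), 1) * 32767)), con,
             size = 2, endian = "little")
  } else {
    writeBin(as.numeric(x), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a mono WAV file
#'
#' Supports 16-bit PCM and 32-bit IEEE float, single channel (the stimulus
#' format used here). Multichannel files are reduced to their first channel
#' with a warning.
#'
#' @param path WAV file path.
#' @return list(`x` waveform in [-1, 1], `fs` sampling rate).
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  if (riff != "RIFF") stop("not a RIFF/WAV file")
  invisible(readBin(con, integer(), size = 4, endian = "little"))
  if (readChar(con, 4) != "WAVE") stop("not a WAV file")
  fmt_code <- NULL; nch <- 1L; fs <- NA_real_; bits <- NA_integer_
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) stop("no data chunk found")
    size <- readBin(con, integer(), size = 4, endian = "little")
    if (id == "fmt ") {
      fmt_code <- readBin(con, integer(), size = 2, endian = "little")
      nch <- readBin(con, integer(), size = 2, endian = "little")
      fs <- readBin(con, integer(), size = 4, endian = "little")
      invisible(readBin(con, integer(), size = 4, endian = "little"))
      invisible(readBin(con, integer(), size = 2, endian = "little"))
      bits <- readBin(con, integer(), size = 2, endian = "little")
      if (size > 16) invisible(readBin(con, raw(), n = size - 16))
    } else if (id == "data") {
      x <- if (fmt_code == 1L && bits == 16L) {
        readBin(con, integer(), n = size / 2, size = 2, signed = TRUE,
                endian = "little") / 32767
      } else if (fmt_code == 3L && bits == 32L) {
        readBin(con, numeric(), n = size / 4, size = 4, endian = "little")
      } else stop("unsupported WAV encoding")
      break
    } else {
      invisible(readBin(con, raw(), n = size))
    }
  }
  if (nch > 1L) {
    warning("multichannel WAV: using channel 1")
    x <- x[seq(1, length(x), by = nch)]
  }
  list(x = x, fs = fs)
}

#' Write a response waveform to CSV
#'
#' One row per lag: lag_ms then one column per channel.
#'
#' @param h a windowed [response_waveform()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_response_csv <- function(h, path) {
  stopifnot(inherits(h, "response_waveform"), !is.null(h$lags_ms))
  df <- data.frame(lag_ms = h$lags_ms, h$values)
  names(df) <- c("lag_ms", paste0("ch", seq_len(ncol(h$values))))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
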