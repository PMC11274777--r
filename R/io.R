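## EEG file readers and writers.
##
## Three dialects are supported: EDF (16-bit), BioSemi BDF (24-bit) and
## BrainVision (.vhdr/.vmrk/.eeg triplet, IEEE float32 multiplexed). All
## voltages are handled in microvolts. The EDF/BDF writers store the whole
## recording in a single data record, with the physical range fitted
## symmetrically to the data so that 16-bit quantization error stays below
## the format's resolution at the stated range.

pad_field <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = width, flag = "-")
}

num_field <- function(x, width) {
  # prefer plain decimal notation: EDF/BDF header fields are narrow and
  # must round trip large integer ranges (e.g. -8388608) exactly
  s <- if (x == round(x) && nchar(sprintf("%d", as.integer(x))) <= width &&
           abs(x) < 2^31) {
    sprintf("%d", as.integer(x))
  } else {
    format(x, scientific = FALSE, trim = TRUE, digits = width - 1)
  }
  s <- substr(s, 1, width)
  formatC(s, width = width, flag = "-")
}

write_int24 <- function(con, values) {
  v <- as.integer(round(values))
  v[v < 0] <- v[v < 0] + 16777216L  # two's complement, 24 bit
  b1 <- v %% 256L
  b2 <- (v %/% 256L) %% 256L
  b3 <- (v %/% 65536L) %% 256L
  raw <- as.raw(rbind(b1, b2, b3))
  writeBin(raw, con)
}

read_int24 <- function(con, n) {
  raw <- readBin(con, "raw", n = 3L * n)
  if (length(raw) < 3L * n) stop("unexpected end of file in 24-bit data")
  m <- matrix(as.integer(raw), nrow = 3L)
  v <- m[1, ] + 256L * m[2, ] + 65536L * m[3, ]
  v[v >= 8388608] <- v[v >= 8388608] - 16777216
  v
}

edf_like_write <- function(rec, path, bdf = FALSE) {
  nch <- n_channels(rec)
  ns <- n_samples(rec)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr_bytes <- 256L + 256L * nch
  # physical range fitted to the data, symmetric, never degenerate
  pmax <- max(abs(rec$data), 1e-6) * 1.0001
  dmax <- if (bdf) 8388607 else 32767
  version <- if (bdf) {
    c(as.raw(255), charToRaw(pad_field("BIOSEMI", 7)))
  } else {
    charToRaw(pad_field("0", 8))
  }
  writeBin(version, con)
  writeBin(charToRaw(paste0(
    pad_field("X X X X", 80),                    # patient id
    pad_field("Startdate X X X X", 80),          # recording id
    pad_field("01.01.00", 8), pad_field("00.00.00", 8),
    num_field(hdr_bytes, 8),
    pad_field(if (bdf) "24BIT" else "", 44),
    num_field(1, 8),                             # one data record
    num_field(ns / rec$fs, 8),                   # record duration, s
    num_field(nch, 4)
  )), con)
  fields <- c(
    vapply(rec$labels, pad_field, "", width = 16),
    rep(pad_field("AgAgCl electrode", 80), nch),
    rep(pad_field("uV", 8), nch),
    rep(num_field(-pmax, 8), nch),
    rep(num_field(pmax, 8), nch),
    rep(num_field(-dmax - if (bdf) 1 else 1, 8), nch),
    rep(num_field(dmax, 8), nch),
    rep(pad_field("", 80), nch),
    rep(num_field(ns, 8), nch),
    rep(pad_field("", 32), nch)
  )
  writeBin(charToRaw(paste(fields, collapse = "")), con)
  scale <- dmax / pmax
  dig <- round(rec$data * scale)
  for (ch in seq_len(nch)) {
    if (bdf) write_int24(con, dig[ch, ]) else {
      writeBin(as.integer(dig[ch, ]), con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

edf_like_read <- function(path, bdf = FALSE) {
  con <- file(path, "rb")
  on.exit(close(con))
  ver <- readBin(con, "raw", 8)
  if (bdf && ver[1] != as.raw(255)) stop("not a BDF file: ", path)
  readBin(con, "raw", 80 + 80 + 8 + 8)  # ids and date/time
  hdr_bytes <- as.integer(readChar(con, 8))
  readChar(con, 44)
  n_rec <- as.integer(readChar(con, 8))
  dur <- as.numeric(readChar(con, 8))
  nch <- as.integer(readChar(con, 4))
  if (is.na(nch) || nch < 1) stop("corrupt header: no channels in ", path)
  if (is.na(n_rec) || n_rec < 1) stop("corrupt header: no data records in ", path)
  rd <- function(w) vapply(seq_len(nch), function(i) readChar(con, w), "")
  labels <- trimws(rd(16)); rd(80); rd(8)
  pmin <- as.numeric(trimws(rd(8))); pmax <- as.numeric(trimws(rd(8)))
  dmin <- as.numeric(trimws(rd(8))); dmax <- as.numeric(trimws(rd(8)))
  rd(80)
  spr <- as.integer(trimws(rd(8)))
  rd(32)
  if (any(is.na(c(pmin, pmax, dmin, dmax, spr)))) {
    stop("corrupt header: unparsable signal fields in ", path)
  }
  seek(con, hdr_bytes)
  data <- matrix(0, nrow = nch, ncol = spr[1] * n_rec)
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(nch)) {
      dig <- if (bdf) read_int24(con, spr[ch]) else {
        readBin(con, "integer", n = spr[ch], size = 2, endian = "little")
      }
      if (length(dig) < spr[ch]) stop("truncated data record in ", path)
      phys <- pmin[ch] + (dig - dmin[ch]) * (pmax[ch] - pmin[ch]) / (dmax[ch] - dmin[ch])
      data[ch, ((r - 1) * spr[ch] + 1):(r * spr[ch])] <- phys
    }
  }
  fs <- spr[1] / (dur / 1)
  eeg_recording(data, labels, fs)
}

brainvision_write <- function(rec, path) {
  base <- sub("\\.vhdr$", "", path)
  vhdr <- paste0(base, ".vhdr")
  vmrk <- paste0(base, ".vmrk")
  eeg <- paste0(base, ".eeg")
  stem <- basename(base)
  ch_lines <- sprintf("Ch%d=%s,,1,µV", seq_along(rec$labels), rec$labels)
  writeLines(c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "", "[Common Infos]", "Codepage=UTF-8",
    paste0("DataFile=", stem, ".eeg"),
    paste0("MarkerFile=", stem, ".vmrk"),
    "DataFormat=BINARY", "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", n_channels(rec)),
    paste0("SamplingInterval=", format(1e6 / rec$fs, digits = 12)),
    "", "[Binary Infos]", "BinaryFormat=IEEE_FLOAT_32",
    "", "[Channel Infos]", ch_lines
  ), vhdr, useBytes = TRUE)
  writeLines(c(
    "Brain Vision Data Exchange Marker File, Version 1.0",
    "", "[Common Infos]", paste0("DataFile=", stem, ".eeg"),
    "", "[Marker Infos]",
    "Mk1=New Segment,,1,1,0,00000000000000000000"
  ), vmrk, useBytes = TRUE)
  con <- file(eeg, "wb")
  on.exit(close(con))
  # multiplexed: all channels of sample 1, then sample 2, ...
  writeBin(as.vector(rec$data), con, size = 4, endian = "little")
  invisible(vhdr)
}

parse_vhdr_value <- function(lines, key) {
  hit <- grep(paste0("^", key, "="), lines, value = TRUE)
  if (!length(hit)) stop("BrainVision header missing ", key)
  sub(paste0("^", key, "="), "", hit[1])
}

brainvision_read <- function(path) {
  if (!grepl("\\.vhdr$", path)) path <- paste0(path, ".vhdr")
  if (!file.exists(path)) stop("BrainVision header not found: ", path)
  lines <- readLines(path, warn = FALSE)
  datafile <- file.path(dirname(path), parse_vhdr_value(lines, "DataFile"))
  if (!file.exists(datafile)) {
    stop("BrainVision triplet incomplete: missing data file ", datafile)
  }
  fmt <- parse_vhdr_value(lines, "BinaryFormat")
  if (fmt != "IEEE_FLOAT_32") stop("unsupported BinaryFormat: ", fmt)
  orient <- parse_vhdr_value(lines, "DataOrientation")
  nch <- as.integer(parse_vhdr_value(lines, "NumberOfChannels"))
  if (is.na(nch) || nch < 1) stop("corrupt header: no channels in ", path)
  fs <- 1e6 / as.numeric(parse_vhdr_value(lines, "SamplingInterval"))
  ch_lines <- grep("^Ch[0-9]+=", lines, value = TRUE)
  labels <- vapply(strsplit(sub("^Ch[0-9]+=", "", ch_lines), ","),
                   `[`, "", 1)
  if (length(labels) != nch) stop("channel count mismatch in ", path)
  sz <- file.info(datafile)$size
  n <- as.integer(sz / 4)
  con <- file(datafile, "rb")
  on.exit(close(con))
  vals <- readBin(con, "numeric", n = n, size = 4, endian = "little")
  ns <- length(vals) %/% nch
  data <- matrix(vals[seq_len(nch * ns)], nrow = nch)
  if (orient == "VECTORIZED") {
    data <- matrix(vals[seq_len(nch * ns)], ncol = nch)
    data <- t(data)
  }
  eeg_recording(data, labels, fs)
}

guess_dialect <- function(path) {
  if (grepl("\\.vhdr$", path, ignore.case = TRUE)) return("brainvision")
  if (grepl("\\.bdf$", path, ignore.case = TRUE)) return("bdf")
  if (grepl("\\.edf$", path, ignore.case = TRUE)) return("edf")
  stop("cannot infer dialect from file name: ", path,
       " (pass `dialect` explicitly)")
}

#' Read an EEG recording from disk
#'
#' @param path path to an `.edf`, `.bdf` or BrainVision `.vhdr` file.
#' @param dialect file dialect; `"auto"` infers it from the extension.
#' @return an [eeg_recording()] in microvolts.
#' @export
read_recording <- function(path, dialect = c("auto", "edf", "bdf", "brainvision")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") dialect <- guess_dialect(path)
  if (dialect != "brainvision" && !file.exists(path)) {
    stop("file not found: ", path)
  }
  switch(dialect,
    edf = edf_like_read(path, bdf = FALSE),
    bdf = edf_like_read(path, bdf = TRUE),
    brainvision = brainvision_read(path)
  )
}

#' Write an EEG recording to disk
#'
#' @param rec an [eeg_recording()].
#' @param path output path; for BrainVision, the `.vhdr` path (the `.vmrk`
#'   and `.eeg` members are written alongside).
#' @param dialect output format.
#' @return the path written, invisibly.
#' @export
write_recording <- function(rec, path,
                            dialect = c("auto", "edf", "bdf", "brainvision")) {
  stopifnot(inherits(rec, "eeg_recording"))
  dialect <- match.arg(dialect)
  if (dialect == "auto") dialect <- guess_dialect(path)
  if (n_channels(rec) < 1) stop("cannot write a recording with 0 channels")
  switch(dialect,
    edf = edf_like_write(rec, path, bdf = FALSE),
    bdf = edf_like_write(rec, path, bdf = TRUE),
    brainvision = brainvision_write(rec, path)
  )
  invisible(path)
}
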