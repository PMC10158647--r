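# Minimal RIFF/WAVE I/O. No WAV reader ships with the declared dependencies,
# so the subset needed here (PCM 8/16/24-bit and IEEE float32, mono/stereo)
# is implemented directly against the RIFF chunk layout.

#' Read a WAV file
#'
#' Supports PCM (8/16/24-bit) and IEEE float (32-bit) encodings. Multichannel
#' files are averaged to mono unless `mono = FALSE`.
#'
#' @param path file path.
#' @param mono average channels to mono (default TRUE).
#' @return list with `samples` (numeric in `[-1, 1]`, or channel x sample
#'   matrix when `mono = FALSE`) and `sample_rate`.
#' @export
read_wav <- function(path, mono = TRUE) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- rawToChar(readBin(con, "raw", 4))
  if (riff != "RIFF") stopf("not a RIFF file: %s", path)
  readBin(con, "integer", 1, 4, endian = "little")
  wave <- rawToChar(readBin(con, "raw", 4))
  if (wave != "WAVE") stopf("not a WAVE file: %s", path)
  fmt <- NULL; dat <- NULL
  repeat {
    id <- readBin(con, "raw", 4)
    if (length(id) < 4) break
    id <- rawToChar(id)
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, "raw", sz)
    } else if (id == "data") {
      dat <- readBin(con, "raw", sz)
    } else {
      readBin(con, "raw", sz + sz %% 2)  # chunks are word-aligned
    }
    if (!is.null(fmt) && !is.null(dat)) break
  }
  if (is.null(fmt) || is.null(dat)) stopf("missing fmt/data chunk in %s", path)
  u16 <- function(r, off) sum(as.integer(r[off + 1:2]) * c(1, 256))
  u32 <- function(r, off) sum(as.numeric(r[off + 1:4]) * 256^(0:3))
  fmt_tag <- u16(fmt, 0)
  n_chan <- u16(fmt, 2)
  rate <- u32(fmt, 4)
  bits <- u16(fmt, 14)
  x <- decode_wav_samples(dat, fmt_tag, bits)
  if (n_chan > 1) {
    x <- matrix(x, nrow = n_chan)
    if (mono) x <- colMeans(x)
  }
  list(samples = x, sample_rate = rate)
}

decode_wav_samples <- function(dat, fmt_tag, bits) {
  if (fmt_tag == 3 && bits == 32) {
    return(readBin(dat, "double", length(dat) / 4, size = 4, endian = "little"))
  }
  if (fmt_tag != 1) stopf("unsupported WAV format tag %d", fmt_tag)
  if (bits == 16) {
    readBin(dat, "integer", length(dat) / 2, size = 2,
            signed = TRUE, endian = "little") / 32768
  } else if (bits == 8) {
    (as.integer(dat) - 128) / 128
  } else if (bits == 24) {
    b <- as.integer(dat)
    n <- length(b) / 3
    v <- b[seq(1, by = 3, length.out = n)] +
      256 * b[seq(2, by = 3, length.out = n)] +
      65536 * b[seq(3, by = 3, length.out = n)]
    v <- ifelse(v >= 2^23, v - 2^24, v)
    v / 2^23
  } else stopf("unsupported PCM bit depth %d", bits)
}

#' Write a mono 16-bit PCM WAV file
#'
#' @param samples numeric vector in `[-1, 1]` (clipped otherwise).
#' @param sample_rate rate in Hz.
#' @param path output path.
#' @export
write_wav <- function(samples, sample_rate, path) {
  x <- as.integer(round(pmax(-1, pmin(1, samples)) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  data_sz <- 2L * length(x)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_sz), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")   # PCM format tag
  writeBin(1L, con, size = 2, endian = "little")   # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * 2), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(data_sz, con, size = 4, endian = "little")
  writeBin(x, con, size = 2, endian = "little")
  invisible(path)
}
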