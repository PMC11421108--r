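#' Write a mono waveform to a WAV file
#'
#' Minimal RIFF/WAVE writer supporting 16-bit PCM and 32-bit IEEE float,
#' single channel. Amplitudes are in arbitrary linear units; for PCM output
#' the signal is scaled by the `pcm_scale` factor and clipped to the 16-bit
#' range, for float output samples are written as-is.
#'
#' @param waveform numeric vector of samples.
#' @param path output file path.
#' @param fs sample rate in Hz.
#' @param format `"float32"` (default, lossless for synthetic audio) or
#'   `"pcm16"`.
#' @param pcm_scale multiplier applied before quantization when
#'   `format = "pcm16"`.
#' @return `path`, invisibly.
#' @seealso [read_wav()]
#' @export
write_wav <- function(waveform, path, fs = 16000, format = c("float32", "pcm16"),
                      pcm_scale = 1) {
  format <- match.arg(format)
  .assert(is.numeric(waveform) && length(waveform) > 0, "waveform must be a non-empty numeric vector")
  n <- length(waveform)
  bits <- if (format == "pcm16") 16L else 32L
  audio_fmt <- if (format == "pcm16") 1L else 3L
  bytes_per_sample <- bits %/% 8L
  data_size <- n * bytes_per_sample

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(audio_fmt, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")            # mono
  writeBin(as.integer(fs), con, size = 4, endian = "little")
  writeBin(as.integer(fs * bytes_per_sample), con, size = 4, endian = "little")
  writeBin(as.integer(bytes_per_sample), con, size = 2, endian = "little")
  writeBin(bits, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  if (format == "pcm16") {
    x <- round(waveform * pcm_scale)
    x <- pmin(pmax(x, -32768), 32767)
    writeBin(as.integer(x), con, size = 2, endian = "little")
  } else {
    writeBin(as.numeric(waveform), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a mono WAV file
#'
#' Counterpart of [write_wav()]; reads single-channel 16-bit PCM or 32-bit
#' float RIFF/WAVE files. PCM samples are returned divided by the scale
#' factor used at write time.
#'
#' @param path WAV file path.
#' @param pcm_scale scale factor to undo for PCM input.
#' @return list with `waveform` (numeric) and `fs` (Hz).
#' @export
read_wav <- function(path, pcm_scale = 1) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  .assert(identical(riff, "RIFF"), "not a RIFF file")
  readBin(con, "integer", 1, size = 4, endian = "little")
  wave <- readChar(con, 4, useBytes = TRUE)
  .assert(identical(wave, "WAVE"), "not a WAVE file")

  fs <- NULL; bits <- NULL; audio_fmt <- NULL; waveform <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      audio_fmt <- readBin(con, "integer", 1, size = 2, endian = "little")
      n_chan <- readBin(con, "integer", 1, size = 2, endian = "little")
      .assert(n_chan == 1L, "only mono WAV supported")
      fs <- readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 2, endian = "little")
      bits <- readBin(con, "integer", 1, size = 2, endian = "little")
      if (size > 16) readBin(con, "raw", size - 16)
    } else if (identical(id, "data")) {
      if (bits == 16L) {
        waveform <- readBin(con, "integer", size %/% 2L, size = 2,
                            endian = "little", signed = TRUE) / pcm_scale
      } else if (bits == 32L && audio_fmt == 3L) {
        waveform <- readBin(con, "numeric", size %/% 4L, size = 4,
                            endian = "little")
      } else {
        stop("unsupported WAV encoding (", bits, " bit, format ", audio_fmt, ")",
             call. = FALSE)
      }
      break
    } else {
      readBin(con, "raw", size)
    }
  }
  .assert(!is.null(waveform), "no data chunk found")
  list(waveform = waveform, fs = fs)
}
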