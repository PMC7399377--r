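# Minimal RIFF/WAVE reader and writer (PCM 16/24/32-bit and IEEE float32).
# Kept in-package because no audio I/O library is available as a dependency.

#' Read a WAV file as a mono AudioRecording
#'
#' Supports PCM 16/24/32-bit and 32-bit IEEE float WAV. Multi-channel input
#' is averaged to mono; samples are scaled to `[-1, 1]`.
#'
#' @param path path to a readable `.wav` file.
#' @param sourceId identifier for the recording; defaults to the file name
#'   without extension.
#' @return An [AudioRecording-class].
#' @export
readWav <- function(path, sourceId = NULL) {
  if (!file.exists(path)) stopIO(sprintf("WAV file not found: %s", path))
  con <- file(path, "rb")
  on.exit(close(con))

  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stopIO(sprintf("not a RIFF file: %s", path))
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stopIO(sprintf("not a WAVE file: %s", path))

  fmt <- NULL
  dataRaw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", size)
      fmt <- list(
        audioFormat = .leInt(body[1:2]),
        channels = .leInt(body[3:4]),
        sampleRate = .leInt(body[5:8]),
        bitsPerSample = .leInt(body[15:16])
      )
      # WAVE_FORMAT_EXTENSIBLE: actual format lives in the sub-format GUID
      if (fmt$audioFormat == 65534L && size >= 40L)
        fmt$audioFormat <- .leInt(body[25:26])
    } else if (identical(id, "data")) {
      dataRaw <- readBin(con, "raw", size)
    } else {
      invisible(readBin(con, "raw", size + size %% 2L))
    }
    if (!is.null(fmt) && !is.null(dataRaw)) break
  }
  if (is.null(fmt) || is.null(dataRaw))
    stopIO(sprintf("malformed WAV (missing fmt/data chunk): %s", path))

  bytesPer <- fmt$bitsPerSample %/% 8L
  n <- length(dataRaw) %/% bytesPer
  if (n == 0L) stopValidation(sprintf("zero-length audio: %s", path))

  x <- switch(as.character(fmt$audioFormat),
    "1" = .decodePcm(dataRaw, fmt$bitsPerSample, n),
    "3" = readBin(dataRaw, "double", n, size = 4, endian = "little"),
    stopIO(sprintf("unsupported WAV format code %d", fmt$audioFormat))
  )

  if (fmt$channels > 1L) {
    n <- (n %/% fmt$channels) * fmt$channels
    x <- rowMeans(matrix(x[seq_len(n)], ncol = fmt$channels, byrow = TRUE))
  }
  if (is.null(sourceId)) sourceId <- sub("\\.[^.]*$", "", basename(path))
  audioRecording(pmin(1, pmax(-1, x)), fmt$sampleRate, sourceId)
}

.leInt <- function(bytes) {
  sum(as.integer(bytes) * 256^(seq_along(bytes) - 1))
}

.decodePcm <- function(raw, bits, n) {
  if (bits == 16L) {
    readBin(raw, "integer", n, size = 2, signed = TRUE, endian = "little") / 32768
  } else if (bits == 32L) {
    readBin(raw, "integer", n, size = 4, endian = "little") / 2147483648
  } else if (bits == 24L) {
    b <- matrix(as.integer(raw[seq_len(3L * n)]), nrow = 3)
    v <- b[1, ] + 256 * b[2, ] + 65536 * b[3, ]
    v <- ifelse(v >= 8388608, v - 16777216, v)
    v / 8388608
  } else {
    stopIO(sprintf("unsupported PCM bit depth: %d", bits))
  }
}

#' Write an AudioRecording to a WAV file
#'
#' @param rec an [AudioRecording-class].
#' @param path output path.
#' @param bits bit depth: 16 (default) or 32 (PCM).
#' @return `path`, invisibly.
#' @export
writeWav <- function(rec, path, bits = 16L) {
  assertThat(is(rec, "AudioRecording"), "rec must be an AudioRecording")
  assertThat(bits %in% c(16L, 32L), "bits must be 16 or 32")
  x <- pmin(1, pmax(-1, samples(rec)))
  # scale by 2^(bits-1) (matching the reader) and clamp the +1.0 edge
  scale <- if (bits == 16L) 32768 else 2147483648
  pcm <- as.integer(pmin(scale - 1, round(x * scale)))
  bytesPer <- bits %/% 8L
  dataSize <- length(pcm) * bytesPer

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + dataSize), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")          # PCM
  writeBin(1L, con, size = 2, endian = "little")          # mono
  writeBin(as.integer(sampleRate(rec)), con, size = 4, endian = "little")
  writeBin(as.integer(sampleRate(rec)) * bytesPer, con, size = 4, endian = "little")
  writeBin(bytesPer, con, size = 2, endian = "little")    # block align
  writeBin(as.integer(bits), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(dataSize, con, size = 4, endian = "little")
  writeBin(pcm, con, size = bytesPer, endian = "little")
  invisible(path)
}
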