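#' Construct an audio clip
#'
#' An `audio_clip` holds a mono waveform as full-scale amplitudes in
#' \[-1, 1\] together with its sample rate. It is the substrate every
#' spectral measurement in the package operates on.
#'
#' @param samples Numeric vector of amplitudes in \[-1, 1\] (dimensionless,
#'   full scale). All values must be finite.
#' @param sample_rate Sample rate in Hz (positive integer, >= 8000).
#' @return An object of class `audio_clip` with elements `samples` and
#'   `sample_rate`.
#' @examples
#' clip <- audio_clip(sin(2 * pi * 550 * seq(0, 1, length.out = 44100)),
#'                    44100)
#' clip_duration(clip)
#' @export
audio_clip <- function(samples, sample_rate) {
  if (!is.numeric(samples) || length(samples) == 0L)
    stop("'samples' must be a non-empty numeric vector")
  if (anyNA(samples) || any(!is.finite(samples)))
    stop("'samples' must be finite (no NA/NaN/Inf)")
  sample_rate <- as.integer(round(sample_rate))
  if (length(sample_rate) != 1L || is.na(sample_rate) || sample_rate < 8000L)
    stop("'sample_rate' must be a single integer >= 8000 Hz")
  mx <- max(abs(samples))
  if (mx > 1 + 1e-6)
    stop(sprintf("samples exceed full scale (max |x| = %.4g > 1)", mx))
  structure(list(samples = as.numeric(samples), sample_rate = sample_rate),
            class = "audio_clip")
}

#' Duration of an audio clip in seconds
#' @param clip An `audio_clip`.
#' @return Duration in seconds (`length(samples) / sample_rate`).
#' @export
clip_duration <- function(clip) {
  stopifnot(inherits(clip, "audio_clip"))
  length(clip$samples) / clip$sample_rate
}

#' @export
print.audio_clip <- function(x, ...) {
  cat(sprintf("<audio_clip> %.3f s @ %d Hz (%d samples, peak %.3f)\n",
              clip_duration(x), x$sample_rate, length(x$samples),
              max(abs(x$samples))))
  invisible(x)
}

#' Extract a time slice of a clip
#' @param clip An `audio_clip`.
#' @param from,to Slice boundaries in seconds (half-open, clamped to the
#'   clip).
#' @return An `audio_clip` covering `[from, to)`.
#' @export
clip_slice <- function(clip, from, to) {
  stopifnot(inherits(clip, "audio_clip"), from < to)
  sr <- clip$sample_rate
  i0 <- max(1L, floor(from * sr) + 1L)
  i1 <- min(length(clip$samples), ceiling(to * sr))
  if (i1 < i0) stop("empty slice")
  audio_clip(clip$samples[i0:i1], sr)
}

# ---- WAV (RIFF) I/O -------------------------------------------------------
# No pre-installed R package in this stack reads WAV, so the RIFF container
# is parsed directly. Supported: PCM 16/24-bit and IEEE float32; mono
# preferred, multichannel downmixed by averaging.

#' Read a WAV file as a mono audio clip
#'
#' Reads RIFF/WAVE files containing PCM 16-bit, PCM 24-bit or IEEE float32
#' samples. Multichannel audio is downmixed to mono by averaging channels.
#'
#' @param path Path to a `.wav` file.
#' @return An [audio_clip()].
#' @export
read_wav <- function(path) {
  if (!file.exists(path) || file.info(path)$size < 44)
    stop("unreadable or empty WAV file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1L, size = 4L, endian = "little"))
  wave <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", sz + sz %% 2L)
      u16 <- function(off) sum(as.integer(body[off + 1:2]) * c(1L, 256L))
      u32 <- function(off) sum(as.numeric(body[off + 1:4]) * 256^(0:3))
      fmt <- list(code = u16(0L), channels = u16(2L),
                  sample_rate = u32(4L), bits = u16(14L))
      # WAVE_FORMAT_EXTENSIBLE: actual code in the first two bytes of GUID
      if (fmt$code == 65534L && sz >= 26L) fmt$code <- u16(24L)
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
      if (sz %% 2L) invisible(readBin(con, "raw", 1L))
    } else {
      invisible(readBin(con, "raw", sz + sz %% 2L))
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt)) stop("WAV file has no fmt chunk: ", path)
  if (is.null(data_raw) || length(data_raw) == 0L)
    stop("WAV file has no data: ", path)

  bytes_per <- fmt$bits / 8L
  n_total <- length(data_raw) %/% bytes_per
  x <- switch(as.character(fmt$code),
    "1" = {
      if (fmt$bits == 16L) {
        readBin(data_raw, "integer", n_total, size = 2L, signed = TRUE,
                endian = "little") / 32768
      } else if (fmt$bits == 24L) {
        b <- as.integer(data_raw)
        i <- seq(1L, 3L * n_total, by = 3L)
        v <- b[i] + 256L * b[i + 1L] + 65536L * b[i + 2L]
        v <- ifelse(v >= 8388608, v - 16777216, v)
        v / 8388608
      } else stop("unsupported PCM bit depth: ", fmt$bits)
    },
    "3" = readBin(data_raw, "numeric", n_total, size = 4L,
                  endian = "little"),
    stop("unsupported WAV format code: ", fmt$code)
  )
  if (fmt$channels > 1L) {
    n_frames <- n_total %/% fmt$channels
    x <- x[seq_len(n_frames * fmt$channels)]
    x <- rowMeans(matrix(x, ncol = fmt$channels, byrow = TRUE))
  }
  x[x > 1] <- 1
  x[x < -1] <- -1
  audio_clip(x, fmt$sample_rate)
}

#' Write an audio clip to a WAV file
#'
#' @param clip An [audio_clip()]. Samples outside \[-1, 1\] are an error at
#'   construction; NaN samples are a validation error here.
#' @param path Output path.
#' @param bit_depth One of `"16"` (PCM 16-bit), `"24"` (PCM 24-bit) or
#'   `"float32"` (IEEE float).
#' @return `path`, invisibly.
#' @export
write_wav <- function(clip, path, bit_depth = c("16", "float32", "24")) {
  stopifnot(inherits(clip, "audio_clip"))
  bit_depth <- match.arg(bit_depth)
  x <- clip$samples
  if (anyNA(x) || any(!is.finite(x))) stop("cannot write non-finite samples")
  sr <- clip$sample_rate
  n <- length(x)

  con <- file(path, "wb")
  on.exit(close(con))
  w16 <- function(v) writeBin(as.integer(v), con, size = 2L,
                              endian = "little")
  w32 <- function(v) writeBin(as.integer(v), con, size = 4L,
                              endian = "little")

  if (bit_depth == "float32") {
    fmt_code <- 3L; bits <- 32L
  } else {
    fmt_code <- 1L; bits <- if (bit_depth == "16") 16L else 24L
  }
  block <- bits / 8L
  data_bytes <- n * block
  fact_bytes <- if (fmt_code == 3L) 12L else 0L

  writeChar("RIFF", con, eos = NULL)
  w32(4L + 24L + fact_bytes + 8L + data_bytes)
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  w32(16L); w16(fmt_code); w16(1L); w32(sr)
  w32(sr * block); w16(block); w16(bits)
  if (fmt_code == 3L) {          # fact chunk expected for non-PCM
    writeChar("fact", con, eos = NULL); w32(4L); w32(n)
  }
  writeChar("data", con, eos = NULL)
  w32(data_bytes)

  if (bit_depth == "16") {
    v <- as.integer(pmax(pmin(round(x * 32768), 32767), -32768))
    writeBin(v, con, size = 2L, endian = "little")
  } else if (bit_depth == "24") {
    v <- pmax(pmin(round(x * 8388608), 8388607), -8388608)
    v <- ifelse(v < 0, v + 16777216, v)
    b <- matrix(0L, nrow = 3L, ncol = n)
    b[1L, ] <- v %% 256
    b[2L, ] <- (v %/% 256) %% 256
    b[3L, ] <- (v %/% 65536) %% 256
    writeBin(as.raw(as.vector(b)), con)
  } else {
    writeBin(x, con, size = 4L, endian = "little")
  }
  invisible(path)
}
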