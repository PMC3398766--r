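#' Mono audio waveform
#'
#' Lightweight container for sampled mono audio: a numeric vector of
#' dimensionless amplitudes plus a sample rate in samples/second. All
#' analysis and synthesis functions in the package consume and return
#' `waveform` objects.
#'
#' @param samples Numeric vector of sample amplitudes. Must be finite and
#'   non-empty.
#' @param rate Sample rate in samples per second (> 0).
#' @return An object of class `waveform` with elements `samples` and `rate`.
#' @examples
#' w <- waveform(sin(2 * pi * 440 * seq(0, 1, by = 1 / 8000)), 8000)
#' duration(w)
#' @export
waveform <- function(samples, rate) {
  samples <- as.numeric(samples)
  if (length(samples) == 0L) stop("waveform must contain at least one sample")
  if (!all(is.finite(samples))) stop("waveform samples must be finite")
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0)
    stop("sample rate must be a single positive number")
  structure(list(samples = samples, rate = as.numeric(rate)),
            class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform: %d samples @ %g Hz (%.3f s), RMS %.4g>\n",
              length(x$samples), x$rate, duration(x), rms(x)))
  invisible(x)
}

#' Duration of a waveform in seconds
#' @param wave A `waveform`.
#' @return Duration in seconds.
#' @export
duration <- function(wave) {
  stopifnot(inherits(wave, "waveform"))
  length(wave$samples) / wave$rate
}

#' Root-mean-square amplitude
#' @param wave A `waveform`.
#' @return RMS amplitude (dimensionless).
#' @export
rms <- function(wave) {
  stopifnot(inherits(wave, "waveform"))
  sqrt(mean(wave$samples^2))
}

#' Scale a waveform to a target RMS
#'
#' @param wave A `waveform`.
#' @param target Target RMS amplitude.
#' @return Rescaled `waveform`; silence (RMS 0) is returned unchanged.
#' @export
match_rms <- function(wave, target) {
  r <- rms(wave)
  if (r == 0) return(wave)
  waveform(wave$samples * (target / r), wave$rate)
}

#' Resample a waveform
#'
#' FFT brick-wall anti-alias filtering (when down-sampling) followed by
#' linear interpolation onto the new sample grid. Adequate for test
#' fixtures and stimulus preparation; not a polyphase resampler.
#'
#' @param wave A `waveform`.
#' @param rate Target sample rate (samples/second).
#' @return A `waveform` at the requested rate.
#' @export
resample_wave <- function(wave, rate) {
  stopifnot(inherits(wave, "waveform"))
  if (rate == wave$rate) return(wave)
  x <- wave$samples
  if (rate < wave$rate) {
    # remove content above the new Nyquist before interpolating
    n <- length(x)
    X <- stats::fft(x)
    f <- c(seq(0, ceiling(n / 2) - 1), seq(-floor(n / 2), -1)) * wave$rate / n
    X[abs(f) > rate / 2] <- 0
    x <- Re(stats::fft(X, inverse = TRUE)) / n
  }
  t_old <- (seq_along(x) - 1) / wave$rate
  n_new <- max(1L, round(length(x) * rate / wave$rate))
  t_new <- (seq_len(n_new) - 1) / rate
  waveform(stats::approx(t_old, x, xout = pmin(t_new, max(t_old)))$y, rate)
}

#' Read a mono WAV file
#'
#' Minimal RIFF/WAVE reader for uncompressed mono audio: 16-bit PCM
#' (format tag 1) and 32-bit IEEE float (format tag 3).
#'
#' @param path Path to a `.wav` file.
#' @param rate Optional analysis rate; if given and different from the
#'   file's rate the waveform is resampled on read.
#' @return A `waveform`.
#' @export
read_wav <- function(path, rate = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  readBin(con, "integer", 1, size = 4, endian = "little")
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)
  fmt <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4) stop("no data chunk found in ", path)
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      raw <- readBin(con, "raw", sz)
      fmt <- list(
        tag      = readBin(raw[1:2], "integer", 1, size = 2, endian = "little"),
        channels = readBin(raw[3:4], "integer", 1, size = 2, endian = "little"),
        rate     = readBin(raw[5:8], "integer", 1, size = 4, endian = "little"),
        bits     = readBin(raw[15:16], "integer", 1, size = 2, endian = "little"))
    } else if (identical(id, "data")) {
      if (is.null(fmt)) stop("data chunk before fmt chunk in ", path)
      if (fmt$channels != 1L) stop("only mono WAV files are supported")
      if (fmt$tag == 1L && fmt$bits == 16L) {
        x <- readBin(con, "integer", sz / 2, size = 2, signed = TRUE,
                     endian = "little") / 32768
      } else if (fmt$tag == 3L && fmt$bits == 32L) {
        x <- readBin(con, "numeric", sz / 4, size = 4, endian = "little")
      } else {
        stop("unsupported WAV encoding (need PCM16 or float32)")
      }
      w <- waveform(x, fmt$rate)
      if (!is.null(rate)) w <- resample_wave(w, rate)
      return(w)
    } else {
      readBin(con, "raw", sz + sz %% 2)  # skip unknown chunk (word aligned)
    }
  }
}

#' Write a mono WAV file
#'
#' @param wave A `waveform`.
#' @param path Output path.
#' @param encoding `"pcm16"` (values clipped to \[-1, 1\]) or `"float32"`.
#' @return `path`, invisibly.
#' @export
write_wav <- function(wave, path, encoding = c("pcm16", "float32")) {
  stopifnot(inherits(wave, "waveform"))
  encoding <- match.arg(encoding)
  n <- length(wave$samples)
  bytes_per <- if (encoding == "pcm16") 2L else 4L
  data_sz <- n * bytes_per
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_sz), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(if (encoding == "pcm16") 1L else 3L, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")                 # mono
  writeBin(as.integer(round(wave$rate)), con, size = 4, endian = "little")
  writeBin(as.integer(round(wave$rate) * bytes_per), con, size = 4,
           endian = "little")                                    # byte rate
  writeBin(bytes_per, con, size = 2, endian = "little")          # block align
  writeBin(8L * bytes_per, con, size = 2, endian = "little")     # bits
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_sz), con, size = 4, endian = "little")
  if (encoding == "pcm16") {
    x <- pmax(-1, pmin(1, wave$samples))
    writeBin(as.integer(round(x * 32767)), con, size = 2, endian = "little")
  } else {
    writeBin(wave$samples, con, size = 4, endian = "little")
  }
  invisible(path)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}
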