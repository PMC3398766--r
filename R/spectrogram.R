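#' Spectrogram analysis parameters
#'
#' Parameters for the Gaussian-window short-time Fourier transform that
#' underlies the modulation-filtering pipeline.
#'
#' @param window_sd Standard deviation of the Gaussian analysis window, in
#'   seconds. The window is truncated at +/- 3 SD.
#' @param hop Frame step in seconds. Must not exceed `window_sd * 6`
#'   (i.e. one full window length), which guarantees overlap for inversion.
#' @param fft_pad_factor Positive integer zero-padding factor applied to the
#'   FFT length (next power of two of the window length, times this factor).
#' @param floor_db Dynamic-range floor in dB below the spectrogram maximum;
#'   log amplitudes are clamped this far below the peak.
#' @return An object of class `spectrogram_params`.
#' @export
spectrogram_params <- function(window_sd = 0.002, hop = 0.001,
                               fft_pad_factor = 2L, floor_db = 80) {
  stopifnot(window_sd > 0, hop > 0, floor_db > 0,
            fft_pad_factor >= 1, fft_pad_factor == round(fft_pad_factor))
  if (hop > window_sd * 6)
    stop("hop must not exceed 6 * window_sd (one window length)")
  structure(list(window_sd = window_sd, hop = hop,
                 fft_pad_factor = as.integer(fft_pad_factor),
                 floor_db = floor_db),
            class = "spectrogram_params")
}

# Window / framing geometry shared by analysis and synthesis.
stft_geometry <- function(n, rate, params) {
  sd_n <- params$window_sd * rate
  half <- as.integer(ceiling(3 * sd_n))
  win_len <- 2L * half + 1L
  if (win_len > n) stop("analysis window is longer than the signal")
  hop_n <- max(1L, as.integer(round(params$hop * rate)))
  win <- exp(-0.5 * (((-half):half) / sd_n)^2)
  nfft <- params$fft_pad_factor * 2^ceiling(log2(win_len))
  centers <- seq(1L, n, by = hop_n)  # window centres, in samples (1-based)
  list(half = half, win_len = win_len, hop_n = hop_n, win = win,
       nfft = as.integer(nfft), centers = centers,
       nbins = as.integer(nfft / 2 + 1))
}

# One-sided complex STFT (nbins x nframes). Frames are centred on
# `centers`; the signal is zero-padded by half a window at each end.
stft_complex <- function(samples, rate, params) {
  n <- length(samples)
  g <- stft_geometry(n, rate, params)
  xpad <- c(numeric(g$half), samples, numeric(g$half + g$win_len))
  idx <- outer(seq_len(g$win_len) - 1L, g$centers, "+")  # start at xpad[center]
  frames <- matrix(xpad[idx], nrow = g$win_len) * g$win
  fr <- rbind(frames, matrix(0, g$nfft - g$win_len, ncol(frames)))
  S <- stats::mvfft(fr)[seq_len(g$nbins), , drop = FALSE]
  list(S = S, geom = g,
       freq = (seq_len(g$nbins) - 1) * rate / g$nfft,
       time = (g$centers - 1) / rate)
}

# Overlap-add synthesis from one-sided complex STFT; returns n_out samples.
istft_complex <- function(S, geom, n_out) {
  nb <- geom$nbins
  # rebuild the full Hermitian spectrum for a real inverse FFT
  body <- S[seq(nb - 1, 2), , drop = FALSE]
  Sfull <- rbind(S, Conj(body))
  Sfull[1, ] <- Re(Sfull[1, ])
  Sfull[nb, ] <- Re(Sfull[nb, ])
  fr <- Re(stats::mvfft(Sfull, inverse = TRUE)) / geom$nfft
  fr <- fr[seq_len(geom$win_len), , drop = FALSE]
  ylen <- geom$half + n_out + geom$half + geom$win_len
  y <- numeric(ylen)
  wsum <- numeric(ylen)
  starts <- geom$centers  # frame r = 1 lands at xpad index `center`
  contrib <- fr * geom$win
  w2 <- geom$win^2
  for (r in seq_len(geom$win_len)) {
    pos <- starts + r - 1L
    y[pos] <- y[pos] + contrib[r, ]
    wsum[pos] <- wsum[pos] + w2[r]
  }
  keep <- wsum > max(wsum) * 1e-10
  y[keep] <- y[keep] / wsum[keep]
  y[(geom$half + 1):(geom$half + n_out)]
}

#' Gaussian-window log-spectrogram
#'
#' Computes the magnitude short-time Fourier transform of a waveform with a
#' Gaussian window, converts to natural-log amplitude, and clamps the result
#' at a dynamic-range floor `floor_db` below the maximum. This is the
#' time-frequency representation over which modulation filtering operates.
#'
#' @param wave A [waveform()].
#' @param params A [spectrogram_params()] object.
#' @return An object of class `log_spectrogram`: a matrix `values`
#'   (rows = frequency bins, columns = frames) of natural-log amplitudes,
#'   with `freq` (Hz) and `time` (s) axis calibrations, the originating
#'   `params`, sample `rate`, `floor_value` (log units) and `n_samples`.
#' @details All-zero input yields a spectrogram uniformly at the floor.
#'   Natural logs are used internally; decibels appear only at interfaces
#'   (`floor_db`).
#' @export
stft_log_spectrogram <- function(wave, params = spectrogram_params()) {
  stopifnot(inherits(wave, "waveform"))
  st <- stft_complex(wave$samples, wave$rate, params)
  A <- Mod(st$S)
  ref <- max(A)
  if (ref <= 0) {
    floor_value <- log(.Machine$double.eps)
    L <- matrix(floor_value, nrow(A), ncol(A))
  } else {
    floor_value <- log(ref) - params$floor_db * log(10) / 20
    L <- pmax(log(pmax(A, exp(floor_value))), floor_value)
  }
  structure(list(values = L, freq = st$freq, time = st$time,
                 params = params, rate = wave$rate,
                 floor_value = floor_value,
                 n_samples = length(wave$samples)),
            class = "log_spectrogram")
}

#' @export
print.log_spectrogram <- function(x, ...) {
  cat(sprintf(paste0("<log_spectrogram: %d freq bins x %d frames, ",
                     "%.0f Hz rate, floor %.2f>\n"),
              nrow(x$values), ncol(x$values), x$rate, x$floor_value))
  invisible(x)
}

#' Invert a log-spectrogram to audio by alternating projections
#'
#' Recursive spectrogram inversion (Griffin-Lim style): starting from an
#' initial phase estimate, alternately synthesises a waveform by
#' overlap-add and replaces the magnitude of its STFT with the target
#' magnitude, keeping the phase. Iterates until the relative Frobenius
#' error between achieved and target magnitude falls below `tol` or
#' `max_iter` is reached.
#'
#' @param spec A `log_spectrogram`.
#' @param init_phase Either `"random"` (seeded uniform phases) or a phase
#'   matrix in radians with the dimensions of `spec$values`.
#' @param max_iter Maximum number of projection iterations (>= 1).
#' @param tol Relative magnitude error at which to stop (> 0).
#' @param seed Integer seed used when `init_phase = "random"`.
#' @return A list with elements `wave` (the reconstructed [waveform()]),
#'   `achieved_error` (final relative error) and `error_trace` (per
#'   iteration; non-increasing).
#' @export
invert_log_spectrogram <- function(spec, init_phase = "random",
                                   max_iter = 50L, tol = 1e-3, seed = 1L) {
  stopifnot(inherits(spec, "log_spectrogram"))
  if (!all(is.finite(spec$values))) stop("spectrogram values must be finite")
  if (max_iter < 1) stop("max_iter must be >= 1")
  if (tol <= 0) stop("tol must be positive")
  A <- exp(spec$values)
  geom <- stft_geometry(spec$n_samples, spec$rate, spec$params)
  if (nrow(A) != geom$nbins || ncol(A) != length(geom$centers))
    stop("spectrogram dimensions inconsistent with its parameters")
  if (is.matrix(init_phase)) {
    if (!identical(dim(init_phase), dim(A)))
      stop("init_phase dimensions must match the spectrogram")
    phase <- init_phase
  } else {
    phase <- with_seed(seed,
      matrix(stats::runif(length(A), -pi, pi), nrow(A), ncol(A)))
  }
  normA <- sqrt(sum(A^2))
  S <- A * exp(1i * phase)
  err_trace <- numeric(0)
  x <- NULL
  for (it in seq_len(max_iter)) {
    x <- istft_complex(S, geom, spec$n_samples)
    st <- stft_complex(x, spec$rate, spec$params)
    M <- Mod(st$S)
    err <- sqrt(sum((M - A)^2)) / normA
    err_trace <- c(err_trace, err)
    if (err < tol) break
    # keep the consistent phase, restore the target magnitude
    U <- st$S
    nz <- M > 0
    U[nz] <- U[nz] / M[nz]
    U[!nz] <- exp(1i * phase[!nz])
    S <- A * U
  }
  list(wave = waveform(x, spec$rate),
       achieved_error = err_trace[length(err_trace)],
       error_trace = err_trace)
}

#' Control filtering: spectrogram analysis plus inversion, no modulation filter
#'
#' Round-trips a sound through the log-spectrogram representation and the
#' recursive inversion with no modulation filtering in between. Applied to
#' raw sounds, this matches any signal loss incurred by spectrographic
#' inversion in the modulation-filtered condition, so that filtered and
#' unfiltered stimuli differ only in their modulation content.
#'
#' @inheritParams invert_log_spectrogram
#' @param wave A [waveform()].
#' @param params A [spectrogram_params()].
#' @param preserve_rms Rescale the output to the input RMS (default TRUE).
#' @return A [waveform()] of exactly the input length.
#' @export
control_filter <- function(wave, params = spectrogram_params(),
                           max_iter = 50L, tol = 1e-3, seed = 1L,
                           preserve_rms = TRUE) {
  spec <- stft_log_spectrogram(wave, params)
  inv <- invert_log_spectrogram(spec, max_iter = max_iter, tol = tol,
                                seed = seed)
  out <- inv$wave
  if (preserve_rms) out <- match_rms(out, rms(wave))
  out
}
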