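# Acoustic measurement helpers used to quantify what modulation filtering
# preserves and removes.

#' Temporal envelope of a waveform
#'
#' Full-wave rectification followed by an FFT brick-wall low-pass.
#'
#' @param wave A [waveform()].
#' @param lowpass_hz Envelope bandwidth in Hz (default 30).
#' @return Numeric vector, one envelope value per sample.
#' @export
temporal_envelope <- function(wave, lowpass_hz = 30) {
  stopifnot(inherits(wave, "waveform"))
  e <- abs(wave$samples)
  n <- length(e)
  E <- stats::fft(e)
  f <- c(seq(0, ceiling(n / 2) - 1), seq(-floor(n / 2), -1)) * wave$rate / n
  E[abs(f) > lowpass_hz] <- 0
  Re(stats::fft(E, inverse = TRUE)) / n
}

#' Envelope modulation depth at a target rate
#'
#' Fourier amplitude of the temporal envelope at `rate_hz`, normalised by
#' the envelope mean (DC), times two -- so a fully sinusoidally modulated
#' envelope has depth near 1 and an unmodulated one near 0.
#'
#' @param wave A [waveform()].
#' @param rate_hz Modulation rate to probe, in Hz.
#' @param lowpass_hz Envelope bandwidth (see [temporal_envelope()]).
#' @return Modulation depth (dimensionless, >= 0).
#' @export
envelope_modulation_depth <- function(wave, rate_hz, lowpass_hz = 30) {
  env <- temporal_envelope(wave, lowpass_hz)
  n <- length(env)
  E <- stats::fft(env)
  k <- round(rate_hz * n / wave$rate) + 1L
  if (k < 2L || k > n) stop("rate_hz outside the resolvable range")
  dc <- Mod(E[1L])
  if (dc == 0) return(0)
  2 * Mod(E[k]) / dc
}

#' Mean log-amplitude spectral profile
#'
#' Long-term spectral shape: the log-spectrogram averaged over frames.
#'
#' @param wave A [waveform()].
#' @param params A [spectrogram_params()].
#' @return A data frame with columns `freq` (Hz) and `log_amp`.
#' @export
spectral_profile <- function(wave, params = spectrogram_params()) {
  spec <- stft_log_spectrogram(wave, params)
  data.frame(freq = spec$freq, log_amp = rowMeans(spec$values))
}

#' Mean log-amplitude temporal profile
#'
#' Temporal (dB-style) envelope as seen by the spectrogram: the
#' log-spectrogram averaged over frequency bins, frame by frame. This is
#' the temporal marginal that spectral low-pass modulation filtering
#' preserves exactly (the wt axis is untouched), making it the natural
#' envelope measure for filtering-preservation checks; linear-amplitude
#' envelopes are additionally perturbed by how spectral smoothing
#' redistributes linear power across bins.
#'
#' @inheritParams spectral_profile
#' @return A data frame with columns `time` (s) and `log_amp`.
#' @export
temporal_profile <- function(wave, params = spectrogram_params()) {
  spec <- stft_log_spectrogram(wave, params)
  data.frame(time = spec$time, log_amp = colMeans(spec$values))
}

#' Harmonic peak-to-valley spectral contrast
#'
#' Difference (in natural-log amplitude units) between the mean spectral
#' profile at the harmonic frequencies of `f0` and at the midpoints
#' between them. Large for resolved harmonic stacks; near zero after the
#' harmonic ripple has been filtered out.
#'
#' @param wave A [waveform()].
#' @param f0 Fundamental frequency in Hz.
#' @param params A [spectrogram_params()].
#' @param n_harm Number of harmonics to probe (clipped to Nyquist).
#' @return Contrast in log-amplitude units.
#' @export
harmonic_contrast <- function(wave, f0, params = spectrogram_params(),
                              n_harm = 6L) {
  prof <- spectral_profile(wave, params)
  nyq <- wave$rate / 2
  h <- seq_len(n_harm)
  h <- h[h * f0 < nyq * 0.9]
  if (length(h) < 2) stop("too few resolvable harmonics below Nyquist")
  nearest <- function(f) vapply(f, function(fi)
    which.min(abs(prof$freq - fi)), integer(1))
  peaks <- nearest(h * f0)
  valleys <- nearest((h + 0.5) * f0)
  mean(prof$log_amp[peaks]) - mean(prof$log_amp[valleys])
}
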