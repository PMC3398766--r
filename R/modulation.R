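# Centred DFT frequency axes and the permutation that centres them.
fft_axis <- function(n, d) {
  c(seq(0, ceiling(n / 2) - 1), seq(-floor(n / 2), -1)) / (n * d)
}
shift_order <- function(n) {
  if (n %% 2 == 0) c((n / 2 + 1):n, 1:(n / 2))
  else c(((n + 3) / 2):n, 1:((n + 1) / 2))
}

#' Modulation power spectrum of a log-spectrogram
#'
#' The centred two-dimensional discrete Fourier transform of the
#' log-spectrogram, decomposed into amplitude and phase. The column axis is
#' temporal modulation in Hz (spanning +/- 1 / (2 hop)); the row axis is
#' spectral modulation in cycles/kHz (ripple density across the frequency
#' axis, derived from the frequency-bin spacing). Harmonic stacks with
#' fundamental f0 concentrate spectral-modulation energy near 1000 / f0
#' cycles/kHz.
#'
#' @param spec A `log_spectrogram` (see [stft_log_spectrogram()]).
#' @return An object of class `modulation_spectrum` with non-negative
#'   `amplitude` and radian `phase` matrices (rows indexed by `wf`, the
#'   spectral-modulation axis in cycles/kHz; columns by `wt`, the temporal
#'   modulation axis in Hz), plus the provenance needed to invert back to a
#'   calibrated spectrogram.
#' @export
compute_mps <- function(spec) {
  stopifnot(inherits(spec, "log_spectrogram"))
  V <- spec$values
  if (nrow(V) < 2 || ncol(V) < 2)
    stop("spectrogram must have at least 2 rows and 2 columns")
  nf <- nrow(V); nt <- ncol(V)
  Fm <- stats::fft(V)
  rord <- shift_order(nf); cord <- shift_order(nt)
  Fm <- Fm[rord, cord, drop = FALSE]
  df <- spec$freq[2] - spec$freq[1]       # Hz per frequency bin
  dt <- spec$time[2] - spec$time[1]       # s per frame (= hop)
  wf <- fft_axis(nf, df)[rord] * 1000     # cycles/Hz -> cycles/kHz
  wt <- fft_axis(nt, dt)[cord]            # Hz
  structure(list(amplitude = Mod(Fm), phase = Arg(Fm), wt = wt, wf = wf,
                 provenance = list(params = spec$params, rate = spec$rate,
                                   freq = spec$freq, time = spec$time,
                                   floor_value = spec$floor_value,
                                   n_samples = spec$n_samples)),
            class = "modulation_spectrum")
}

#' @export
print.modulation_spectrum <- function(x, ...) {
  cat(sprintf(paste0("<modulation_spectrum: %d x %d; wt %.1f..%.1f Hz, ",
                     "wf %.2f..%.2f cyc/kHz>\n"),
              nrow(x$amplitude), ncol(x$amplitude),
              min(x$wt), max(x$wt), min(x$wf), max(x$wf)))
  invisible(x)
}

#' Low-pass modulation filter specification
#'
#' @param mode One of `"lowpass_spectral"` (keep ripple densities with
#'   |wf| <= cutoff, in cycles/kHz), `"lowpass_temporal"` (keep envelope
#'   rates with |wt| <= cutoff, in Hz) or `"none"`.
#' @param cutoff Cutoff in cycles/kHz (spectral) or Hz (temporal); required
#'   unless `mode = "none"`.
#' @return An object of class `filter_spec`.
#' @seealso [animal_preset()], [tool_preset()]
#' @export
filter_spec <- function(mode = c("lowpass_spectral", "lowpass_temporal",
                                 "none"), cutoff = NULL) {
  mode <- match.arg(mode)
  if (mode != "none") {
    if (is.null(cutoff) || !is.finite(cutoff) || cutoff <= 0)
      stop("cutoff must be a positive number for mode ", mode)
  }
  structure(list(mode = mode, cutoff = cutoff), class = "filter_spec")
}

#' Preset: spectral low-pass at 0.5 cycles/kHz
#'
#' The cutoff used to render vocalisation-type ("animal") sounds
#' unrecognisable: spectral modulations above 0.5 cycles/kHz -- including
#' harmonic ripple -- are removed, while the temporal envelope is preserved.
#' @return A `filter_spec`.
#' @export
animal_preset <- function() filter_spec("lowpass_spectral", 0.5)

#' Preset: temporal low-pass at 4 Hz
#'
#' The cutoff used to render action-type ("tool") sounds unrecognisable:
#' temporal modulations above 4 Hz are removed, while the overall power
#' spectrum is preserved.
#' @return A `filter_spec`.
#' @export
tool_preset <- function() filter_spec("lowpass_temporal", 4)

#' Binary modulation-domain mask for a filter specification
#'
#' Builds the keep/zero matrix over the (wf, wt) modulation plane. Masks
#' depend only on |wt| and |wf| so they are Hermitian-symmetric, and the
#' DC cell is always kept so the overall level survives filtering.
#'
#' @param filter A [filter_spec()].
#' @param wt Temporal-modulation axis (Hz), symmetric about zero.
#' @param wf Spectral-modulation axis (cycles/kHz), symmetric about zero.
#' @return An object of class `modulation_mask` holding a binary `keep`
#'   matrix aligned to `(wf, wt)`.
#' @export
make_mask <- function(filter, wt, wf) {
  stopifnot(inherits(filter, "filter_spec"))
  keep <- matrix(1, length(wf), length(wt))
  if (filter$mode == "lowpass_spectral") {
    if (filter$cutoff >= max(abs(wf))) {
      warning("spectral cutoff exceeds the modulation axis range; ",
              "mask keeps everything")
    } else {
      keep[abs(wf) > filter$cutoff, ] <- 0
    }
  } else if (filter$mode == "lowpass_temporal") {
    if (filter$cutoff >= max(abs(wt))) {
      warning("temporal cutoff exceeds the modulation axis range; ",
              "mask keeps everything")
    } else {
      keep[, abs(wt) > filter$cutoff] <- 0
    }
  }
  keep[which.min(abs(wf)), which.min(abs(wt))] <- 1  # DC always retained
  structure(list(keep = keep, wt = wt, wf = wf), class = "modulation_mask")
}

#' Apply a modulation mask
#'
#' Zeroes the amplitudes of the masked modulation components; phase is
#' preserved where kept and zeroed where removed. A binary projection:
#' idempotent and non-expansive in total squared amplitude.
#'
#' @param mps A `modulation_spectrum`.
#' @param mask A `modulation_mask` with matching dimensions.
#' @return The filtered `modulation_spectrum`.
#' @export
apply_mask <- function(mps, mask) {
  stopifnot(inherits(mps, "modulation_spectrum"),
            inherits(mask, "modulation_mask"))
  if (!identical(dim(mps$amplitude), dim(mask$keep)))
    stop("mask dimensions do not match the modulation spectrum")
  out <- mps
  out$amplitude <- mps$amplitude * mask$keep
  out$phase <- mps$phase * mask$keep
  out
}

#' Invert a modulation spectrum to a log-spectrogram
#'
#' Inverse centred 2-D DFT of `amplitude * exp(i phase)`. The input must be
#' Hermitian-symmetric (as any modulation spectrum of a real spectrogram
#' is, and as mask application preserves); the small imaginary residual is
#' checked against `tol` and discarded. The output inherits the source
#' spectrogram's axis calibrations and is clamped at its floor.
#'
#' @param mps A `modulation_spectrum`.
#' @param tol Maximum tolerated relative imaginary residual (default 1e-8).
#' @return A `log_spectrogram`.
#' @export
invert_mps <- function(mps, tol = 1e-8) {
  stopifnot(inherits(mps, "modulation_spectrum"))
  Fm <- mps$amplitude * exp(1i * mps$phase)
  nf <- nrow(Fm); nt <- ncol(Fm)
  runshift <- order(shift_order(nf)); cunshift <- order(shift_order(nt))
  Fm <- Fm[runshift, cunshift, drop = FALSE]
  V <- stats::fft(Fm, inverse = TRUE) / (nf * nt)
  scale <- max(abs(V))
  if (scale > 0 && max(abs(Im(V))) / scale > tol)
    stop("modulation spectrum is not Hermitian-symmetric: ",
         "inverse transform would be complex")
  p <- mps$provenance
  structure(list(values = pmax(Re(V), p$floor_value),
                 freq = p$freq, time = p$time, params = p$params,
                 rate = p$rate, floor_value = p$floor_value,
                 n_samples = p$n_samples),
            class = "log_spectrogram")
}

#' Modulation-filter a sound end to end
#'
#' The full five-step pipeline that removes sound-identity cues while
#' preserving spectrotemporal complexity: (i) Gaussian-window
#' log-spectrogram; (ii) 2-D Fourier transform to the modulation amplitude
#' and phase spectrum; (iii) zeroing of amplitudes outside the low-pass
#' region; (iv) inverse 2-D transform to the filtered spectrogram; and
#' (v) recursive spectrogram inversion back to audio.
#'
#' @param wave A [waveform()].
#' @param filter A [filter_spec()]; use [animal_preset()] (spectral
#'   low-pass, 0.5 cycles/kHz) for harmonic vocalisation-type sounds or
#'   [tool_preset()] (temporal low-pass, 4 Hz) for action-type sounds.
#' @param params A [spectrogram_params()].
#' @param max_iter,tol,seed Spectrogram-inversion settings, see
#'   [invert_log_spectrogram()].
#' @param preserve_rms Rescale output RMS to the input RMS (default TRUE).
#' @return A [waveform()] of exactly the input length.
#' @export
mps_filter_sound <- function(wave, filter, params = spectrogram_params(),
                             max_iter = 50L, tol = 1e-3, seed = 1L,
                             preserve_rms = TRUE) {
  spec <- stft_log_spectrogram(wave, params)
  mps <- compute_mps(spec)
  mask <- make_mask(filter, mps$wt, mps$wf)
  spec2 <- invert_mps(apply_mask(mps, mask))
  inv <- invert_log_spectrogram(spec2, max_iter = max_iter, tol = tol,
                                seed = seed)
  out <- inv$wave
  if (preserve_rms) out <- match_rms(out, rms(wave))
  out
}

#' Modulation marginals
#'
#' Sums MPS amplitude across one modulation axis, for locating planted or
#' empirical modulation peaks.
#'
#' @param mps A `modulation_spectrum`.
#' @param along `"spectral"` (marginal over wf, summed across wt) or
#'   `"temporal"` (marginal over wt, summed across wf).
#' @return A data frame with columns `axis` and `amplitude`.
#' @export
mps_marginal <- function(mps, along = c("spectral", "temporal")) {
  along <- match.arg(along)
  if (along == "spectral")
    data.frame(axis = mps$wf, amplitude = rowSums(mps$amplitude))
  else
    data.frame(axis = mps$wt, amplitude = colSums(mps$amplitude))
}
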