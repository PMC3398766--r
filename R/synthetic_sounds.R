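#' Synthesise a test sound with known modulation content
#'
#' Fixture generator for exercising the modulation-filtering pipeline
#' without recorded audio. `harmonic_voc` emulates a vocalisation: a
#' harmonic stack on `f0` with slow vibrato and a slow amplitude contour,
#' so spectral-modulation energy concentrates near `1000 / f0` cycles/kHz
#' and fast envelope modulation is absent. `am_noise` emulates an
#' action/movement sound: Gaussian noise under a sinusoidal envelope at
#' `am_rate` Hz (temporal modulation at `am_rate`, no harmonic ripple).
#' `click_train` is a periodic broadband transient train at `am_rate` Hz.
#'
#' @param kind One of `"harmonic_voc"`, `"am_noise"`, `"click_train"`,
#'   `"tone"`, `"silence"`.
#' @param f0 Fundamental frequency in Hz (harmonic_voc, tone).
#' @param am_rate Envelope/click rate in Hz (am_noise, click_train).
#' @param duration Duration in seconds (> 0).
#' @param rate Sample rate in samples/second.
#' @param seed Integer seed; synthesis is deterministic per seed.
#' @return A [waveform()], RMS-normalised to 0.1 (except silence).
#' @export
synth_sound <- function(kind = c("harmonic_voc", "am_noise", "click_train",
                                 "tone", "silence"),
                        f0 = 500, am_rate = 8, duration = 2,
                        rate = 44100, seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(duration > 0, rate > 0, f0 >= 0, am_rate >= 0)
  n <- round(duration * rate)
  t <- (seq_len(n) - 1) / rate
  if (kind == "silence") return(waveform(numeric(n), rate))
  if (kind %in% c("harmonic_voc", "tone") && f0 >= rate / 2)
    stop("f0 must be below the Nyquist frequency")
  x <- with_seed(seed, switch(kind,
    tone = sin(2 * pi * f0 * t),
    harmonic_voc = {
      # slow vibrato (4 Hz, 1% depth) keeps modulation content gentle
      vib_rate <- 4; vib_depth <- 0.01
      phi0 <- 2 * pi * (f0 * t - f0 * vib_depth / (2 * pi * vib_rate) *
                          cos(2 * pi * vib_rate * t))
      n_harm <- max(1L, floor((rate / 2 * 0.9) / f0))
      s <- numeric(n)
      for (h in seq_len(n_harm))
        s <- s + (1 / h) * sin(h * phi0 + stats::runif(1, 0, 2 * pi))
      # slow syllabic envelope (2.5 Hz, depth 0.5): characterful but well
      # below the 4 Hz temporal cutoff, so spectral filtering keeps it
      s * (1 + 0.5 * sin(2 * pi * 2.5 * t + stats::runif(1, 0, 2 * pi)))
    },
    am_noise = stats::rnorm(n) * 0.5 * (1 + sin(2 * pi * am_rate * t - pi / 2)),
    click_train = {
      s <- numeric(n)
      period <- max(1L, round(rate / max(am_rate, 1e-9)))
      starts <- seq(1L, n, by = period)
      click_len <- max(2L, round(0.001 * rate))
      burst <- stats::rnorm(click_len) *
        exp(-seq(0, 4, length.out = click_len))
      for (s0 in starts) {
        ii <- s0:min(n, s0 + click_len - 1L)
        s[ii] <- s[ii] + burst[seq_along(ii)]
      }
      s
    }))
  x <- apply_ramps(x, rate, 0.01)
  w <- waveform(x, rate)
  match_rms(w, 0.1)
}

# Raised-cosine onset/offset ramps of `ramp` seconds.
apply_ramps <- function(x, rate, ramp = 0.01) {
  nr <- min(round(ramp * rate), floor(length(x) / 2))
  if (nr < 1) return(x)
  env <- 0.5 * (1 - cos(pi * (seq_len(nr) - 0.5) / nr))
  x[seq_len(nr)] <- x[seq_len(nr)] * env
  x[seq(length(x), by = -1, length.out = nr)] <-
    x[seq(length(x), by = -1, length.out = nr)] * env
  x
}

#' Synthetic sound inventory
#'
#' Builds a labelled inventory of synthetic sounds for trial construction:
#' `n_per_category` harmonic vocalisations (category `"animal"`) and
#' `n_per_category` amplitude-modulated noises alternating with click
#' trains (category `"tool"`), with per-entry parameter jitter drawn under
#' `seed`. Vocalisation fixtures avoid fast envelopes and action fixtures
#' avoid harmonic structure, so the two categories are separable in the
#' modulation plane.
#'
#' @param n_per_category Sounds per category; must be divisible by 4 so the
#'   inventory partitions into four-sound trials.
#' @param rate Sample rate for all entries.
#' @param duration Duration of each entry in seconds.
#' @param seed Integer seed; the inventory is deterministic per seed.
#' @param render If FALSE, entries carry their synthesis parameters but no
#'   waveform (cheap design-only inventories).
#' @return An object of class `sound_inventory`: a list of entries, each
#'   with `source_id`, `category`, `synth` (parameters) and `wave`.
#' @export
make_inventory <- function(n_per_category, rate = 44100, duration = 2,
                           seed = 1L, render = TRUE) {
  if (n_per_category %% 4 != 0)
    stop("n_per_category must be divisible by 4")
  specs <- with_seed(seed, {
    animal <- lapply(seq_len(n_per_category), function(i) {
      list(source_id = sprintf("animal_%02d", i), category = "animal",
           kind = "harmonic_voc",
           f0 = stats::runif(1, 300, 800), am_rate = 0,
           seed = sample.int(1e6, 1))
    })
    tool <- lapply(seq_len(n_per_category), function(i) {
      kind <- if (i %% 2 == 1) "am_noise" else "click_train"
      list(source_id = sprintf("tool_%02d", i), category = "tool",
           kind = kind, f0 = 0,
           am_rate = stats::runif(1, if (kind == "am_noise") 5 else 6,
                                  if (kind == "am_noise") 12 else 14),
           seed = sample.int(1e6, 1))
    })
    c(animal, tool)
  })
  entries <- lapply(specs, function(s) {
    s$wave <- if (render)
      synth_sound(s$kind, f0 = s$f0, am_rate = s$am_rate,
                  duration = duration, rate = rate, seed = s$seed)
    else NULL
    s
  })
  structure(list(entries = entries, rate = rate, duration = duration,
                 seed = seed),
            class = "sound_inventory")
}

#' @export
print.sound_inventory <- function(x, ...) {
  cats <- table(vapply(x$entries, `[[`, "", "category"))
  cat(sprintf("<sound_inventory: %s @ %g Hz, %g s each>\n",
              paste(sprintf("%d %s", cats, names(cats)), collapse = " + "),
              x$rate, x$duration))
  invisible(x)
}

#' Read a sound inventory from a manifest CSV
#'
#' The manifest has columns `source_id`, `category` (animal/tool) and
#' `path` (WAV file, resolved relative to the manifest unless absolute).
#'
#' @param manifest Path to the CSV manifest.
#' @param rate Analysis rate; files are resampled on read.
#' @return A `sound_inventory`.
#' @export
read_sound_inventory <- function(manifest, rate = 44100) {
  df <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  need <- c("source_id", "category", "path")
  if (!all(need %in% names(df)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$source_id)) stop("source_id values must be unique")
  base <- dirname(normalizePath(manifest))
  entries <- lapply(seq_len(nrow(df)), function(i) {
    p <- df$path[i]
    if (!file.exists(p)) p <- file.path(base, p)
    list(source_id = df$source_id[i], category = df$category[i],
         wave = read_wav(p, rate = rate))
  })
  structure(list(entries = entries, rate = rate,
                 duration = NA_real_, seed = NA_integer_),
            class = "sound_inventory")
}
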