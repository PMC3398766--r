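# Shared fixtures, computed lazily and cached for the whole test run.
# Fixture sounds run at 8-16 kHz with a 4 ms window / 2 ms hop: coarse
# enough to keep the suite fast, fine enough to resolve the 4 Hz and
# 0.5 cycles/kHz cutoffs under test.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache, inherits = FALSE))
    assign(name, expr, envir = .fixture_cache)
  get(name, envir = .fixture_cache, inherits = FALSE)
}

fx_params <- function() spectrogram_params(window_sd = 0.004, hop = 0.002)

fx_am <- function() fixture("am",
  synth_sound("am_noise", am_rate = 8, duration = 2, rate = 8000, seed = 4))

fx_am_filtered <- function() fixture("am_filtered",
  mps_filter_sound(fx_am(), tool_preset(), fx_params(),
                   max_iter = 30, seed = 7))

fx_harm <- function() fixture("harm",
  synth_sound("harmonic_voc", f0 = 500, duration = 2, rate = 16000,
              seed = 3))

fx_harm_filtered <- function() fixture("harm_filtered",
  mps_filter_sound(fx_harm(), animal_preset(), fx_params(),
                   max_iter = 30, seed = 7))

fx_control_filtered <- function() fixture("control_filtered",
  control_filter(fx_harm(), fx_params(), max_iter = 30, seed = 7))

# Construct a calibrated log-spectrogram directly from a value matrix,
# for modulation-domain unit tests that need exact analytic content.
make_test_spec <- function(values, df = 10, dt = 0.002, rate = 8000) {
  structure(list(values = values,
                 freq = (seq_len(nrow(values)) - 1) * df,
                 time = (seq_len(ncol(values)) - 1) * dt,
                 params = spectrogram_params(window_sd = 0.004, hop = dt),
                 rate = rate,
                 floor_value = min(values) - 1,
                 n_samples = round(ncol(values) * dt * rate)),
            class = "log_spectrogram")
}

# Brute-force centred 2-D DFT: the independent oracle for compute_mps.
brute_force_mps <- function(V, df, dt) {
  nf <- nrow(V); nt <- ncol(V)
  Fm <- matrix(0 + 0i, nf, nt)
  for (a in 0:(nf - 1)) for (b in 0:(nt - 1)) {
    s <- 0 + 0i
    for (r in 0:(nf - 1)) for (c in 0:(nt - 1))
      s <- s + V[r + 1, c + 1] *
        exp(-2i * pi * (a * r / nf + b * c / nt))
    Fm[a + 1, b + 1] <- s
  }
  ford <- function(n) if (n %% 2 == 0) c((n / 2 + 1):n, 1:(n / 2))
    else c(((n + 3) / 2):n, 1:((n + 1) / 2))
  list(Fm = Fm[ford(nf), ford(nt)],
       wf = (c(seq(0, ceiling(nf / 2) - 1),
               seq(-floor(nf / 2), -1)) / (nf * df))[ford(nf)] * 1000,
       wt = (c(seq(0, ceiling(nt / 2) - 1),
               seq(-floor(nt / 2), -1)) / (nt * dt))[ford(nt)])
}
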