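---
title: "Modulation-spectrum filtering and auditory experiment statistics with modfilt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modulation-spectrum filtering and auditory experiment statistics with modfilt}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(modfilt)
```

## The problem modfilt addresses

Experiments that compare *recognisable* environmental sounds (a cow
lowing, a handsaw cutting) with acoustically matched but *unrecognisable*
controls need a way to destroy sound identity without destroying
spectrotemporal complexity. modfilt implements the modulation power
spectrum (MPS) approach to this problem, together with the surrounding
experimental machinery: assembling filtered and unfiltered excerpts into
factorial trial sequences for passive-listening fMRI, scoring
forced-choice recognition behaviour against exact binomial chance, and
comparing groups of 3-D effect maps voxel-wise.

## The modulation power spectrum and its filtering pipeline

A sound's spectrogram describes energy at time *t* and frequency *f*.
The MPS describes how that energy *fluctuates*: it is the amplitude of
the 2-D Fourier transform of the log-spectrogram, with a temporal
modulation axis $\omega_t$ (Hz -- how fast the envelope changes) and a
spectral modulation axis $\omega_f$ (cycles/kHz -- how finely energy
ripples across frequency). A harmonic stack with fundamental $f_0$
produces spectral modulation near $1000/f_0$ cycles/kHz; rhythmic
clatter produces temporal modulation at its event rate.

`mps_filter_sound()` chains five steps:

1. `stft_log_spectrogram()` -- Gaussian-window STFT, natural-log
   amplitude, clamped at a dynamic-range floor;
2. `compute_mps()` -- centred 2-D DFT, split into amplitude and phase;
3. `make_mask()` / `apply_mask()` -- hard (binary) zeroing of amplitudes
   beyond a low-pass cutoff;
4. `invert_mps()` -- inverse 2-D DFT back to a log-spectrogram;
5. `invert_log_spectrogram()` -- recursive spectrogram inversion
   (alternating projections, Griffin--Lim style) back to a waveform,
   since the filtered magnitude spectrogram no longer has a consistent
   phase.

Two presets encode the category-specific cutoffs: `animal_preset()`
low-passes *spectral* modulation at 0.5 cycles/kHz (vocalisation
identity rides on harmonic ripple), and `tool_preset()` low-passes
*temporal* modulation at 4 Hz (action identity rides on event timing).
`control_filter()` runs steps 1 and 5 only, so that unfiltered stimuli
incur the same inversion losses as filtered ones.

```{r filter-example, eval = FALSE}
p <- spectrogram_params(window_sd = 0.004, hop = 0.002)
voc <- synth_sound("harmonic_voc", f0 = 500, duration = 2, rate = 16000)
voc_meaningless <- mps_filter_sound(voc, animal_preset(), p, seed = 17)
```

## Tunable parameters

* `window_sd` (s, default 0.002) and `hop` (s, default 0.001): the
  Gaussian analysis window and frame step. The window trades temporal
  against spectral resolution of the spectrogram and therefore bounds
  which modulations are even representable; the defaults resolve both a
  4 Hz temporal cutoff and harmonic ripple for speech-band sounds. The
  hop bounds the temporal-modulation axis at $\pm 1/(2\,\mathrm{hop})$.
* `fft_pad_factor` (default 2) refines the frequency grid; the
  spectral-modulation *resolution* is fixed at roughly
  $2/\mathrm{rate}$ cycles/Hz regardless, so low analysis rates make the
  0.5 cycles/kHz cutoff coarse (at 8 kHz it spans only two bins).
* `floor_db` (default 80): log amplitudes are clamped this far below
  the maximum. The floor value is carried with the spectrogram so
  exponentiation is exact at the floor and silence round-trips to
  silence.
* Inversion: `max_iter` (default 50) and `tol` (default 1e-3, relative
  Frobenius error between achieved and target magnitude). The error
  trace is returned and is non-increasing; phase is initialised from a
  seeded uniform draw so the whole pipeline is deterministic per seed.
* `preserve_rms` (default on): filtered output is rescaled to the input
  RMS, since level itself is not an identity cue.

Masks are hard-edged because the filtering operation is defined as
setting amplitudes to zero; the DC cell is always retained so overall
level survives. Mask application is a binary projection (idempotent,
non-expansive), preserves Hermitian symmetry, and therefore always
inverts to a real spectrogram.

## Trial and session construction

`excerpt()` cuts each source to 2 s by maximal short-term energy -- a
mechanical proxy for an experimenter choosing the most characteristic
segment -- and applies 10 ms raised-cosine ramps. `build_trial()`
concatenates four *different* sources of one category into an 8 s trial
(butt-joined; the per-excerpt ramps prevent clicks, and the duration is
exactly the sum of the excerpts). `build_trial_sets()` uses every
inventory sound exactly once across the meaningful set and produces a
source-matched meaningless trial for each meaningful one, filtered with
the category's preset. `build_session()` arranges each run as all 64
sound trials plus 8 silence baseline trials in a seeded order fixed
across subjects: 72 trials per run, 144 in total.

For design-level work `build_trial_sets(..., render_audio = FALSE)`
performs all bookkeeping without synthesising or filtering audio; the
audio path is identical, just skipped.

## Behavioural statistics

The recognition test is a six-alternative forced choice (24 animal and
24 tool items), so chance is 1/6. `binomial_above_chance()` computes
the exact one-tailed upper-tail probability
$P(X \ge k \mid n, 1/6)$ -- at $\alpha = 0.05$ a patient needs at least
13/48 pooled (or 8/24 within a category) to count as above chance.
`paired_mean_difference_ci()` gives the paired t interval for the
animal--tool score difference, and `group_summary()` the per-group
means/SDs/minima. The package ships the nine-patient score table
(`sd_patient_scores()`) and the published control summary
(`control_score_summary()`; raw control scores are not available, so
control inferential statistics are not recomputed).

## Map statistics

`contrast_vector()` returns the seven factorial contrasts over the fixed
condition order (mful_a, mful_t, mless_a, mless_t, silence);
`expand_contrast()` duplicates them across runs with zeros for motion
regressors. `welch_group_t_map()` compares groups voxel-wise without
pooling variances (Welch--Satterthwaite df per voxel), appropriate when
a patient group is more heterogeneous than controls.
`form_clusters()` labels connected supra-threshold components
(connectivity 6/18/26; default 18, a common volumetric convention --
the choice only matters for diagonally touching voxels).
`categorise_interaction_voxels()` implements the forward/reverse
disambiguation: an interaction voxel (patients > controls) is coloured
by the *sign of the control group's forward effect* -- cyan where
controls also activate forward (so patients over-activate), magenta
where controls activate the reverse contrast. We use the signed control
effect rather than a thresholded statistic as the most literal reading
of "direction of activation"; exact zeros are labelled indeterminate
rather than silently coloured. `sample_foci()` samples per-subject
effects at named mm coordinates supplied via configuration
(`read_focus_set()`), using nearest-voxel lookup through the affine.

Random-field-theory FWE cluster correction is out of scope;
`cluster_extent_null()` offers a permutation-based maximum-extent null
for synthetic experiments instead.

## What the synthetic generators emulate -- and what they do not

`synth_sound()` plants known modulation content: `harmonic_voc` (stack
on $f_0$ with 1% vibrato at 4 Hz and a 2.5 Hz, depth-0.5 syllabic
envelope) stands in for animal vocalisations; `am_noise` (sinusoidally
gated noise) and `click_train` stand in for tool/action sounds. The
categories mirror the stimulus-selection rule that vocalisations carry
salient harmonic content while action sounds carry salient temporal
patterning, and deliberately avoid the confusable middle ground (noisy
vocalisations). `simulate_group_maps()` produces Gaussian-noise effect
maps with spherical planted effects.

These fixtures make every filtering and map-statistics claim testable,
but they are idealisations: natural recordings have broadband noise
floors, overlapping modulation content, nonstationary pitch and room
acoustics, and real effect maps have spatial autocorrelation from
smoothing. Passing tests demonstrate that the operations do what they
claim on signals with known ground truth -- not that any particular
natural recording becomes unrecognisable, which is ultimately a
perceptual question.

## Numerical choices

* Natural logs internally; dB only at interfaces.
* The spectrogram floor is a clamp, not a deletion, and the floor value
  travels with the object.
* Hermitian-symmetry tolerance for `invert_mps()` is 1e-8 (relative
  imaginary residual) -- numerical, not scientific.
* `invert_mps()` clamps its output at the source floor so the
  log-spectrogram invariant survives masking.
* Welch t at zero pooled variance is defined as 0 (identical constant
  groups), with df falling back to $n_A + n_B - 2$.
* Excerpt/energy ties break to the earliest window; cluster peak ties
  to the first maximal voxel in array order.
* Envelope preservation is measured on the *log-amplitude* temporal
  profile (`temporal_profile()`, the frame-wise mean log amplitude):
  this is the marginal the spectral low-pass preserves by construction,
  and it is robust across fixture seeds (r above 0.99), whereas
  linear-amplitude envelope correlation varies with the random harmonic
  phases of the fixture (roughly 0.82--0.97) because spectral smoothing
  redistributes linear power across bins. The matching spectral measure
  (`spectral_profile()`) is used for the power-spectrum-preservation
  check.

## Problem sizes used in the test suite

Fixture sounds are 2 s at 8 kHz (temporal-modulation checks) or 16 kHz
(spectral-modulation checks, where the ripple grid is finer), analysed
with a 4 ms window and 2 ms hop, inverted with 30 iterations; map
simulations use 10 subjects per group on grids of about $10^4$ voxels.
These sizes were chosen so each property is measured well inside its
tolerance while the whole suite stays quick to run; the same code
handles 44.1 kHz audio and full-size maps unchanged.

## Known limitations

* The recursive inversion converges to a consistent spectrogram, not to
  the original phase: round-trip *waveforms* differ from inputs even
  when round-trip spectrograms correlate above 0.95.
* WAV I/O is deliberately minimal (mono PCM16/float32); resampling is
  FFT-antialiased linear interpolation, adequate for stimuli but not a
  mastering-grade resampler.
* The exact spectrogram parameters, inversion iteration counts and
  randomisation orders used to build any particular published stimulus
  set are not recoverable; defaults here are the package's own, and
  orders are reproducible only per seed.
* Only low-pass modulation filtering is exposed; band-pass and notch
  masks are not.
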