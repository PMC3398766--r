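# Trial and session construction: a 2 x 2 factorial (meaningful/meaningless
# x animal/tool) plus a silence baseline, presented over two runs.

TRIAL_CONDITIONS <- c("mful_a", "mful_t", "mless_a", "mless_t", "silence")

#' Excerpt a fixed-duration segment from a waveform
#'
#' Selects the contiguous window of the requested duration with maximal
#' energy (a proxy for "retains characteristic acoustic features"), then
#' applies 10 ms raised-cosine onset/offset ramps.
#'
#' @param wave A [waveform()] at least `dur` seconds long.
#' @param dur Excerpt duration in seconds (default 2).
#' @param ramp Ramp duration in seconds (default 0.01).
#' @return A [waveform()] of exactly `round(dur * rate)` samples.
#' @export
excerpt <- function(wave, dur = 2, ramp = 0.01) {
  stopifnot(inherits(wave, "waveform"))
  L <- round(dur * wave$rate)
  n <- length(wave$samples)
  if (n < L) stop("input shorter than the requested excerpt duration")
  if (n == L) {
    start <- 1L
  } else {
    cs <- cumsum(c(0, wave$samples^2))
    starts <- seq_len(n - L + 1L)
    energy <- cs[starts + L] - cs[starts]
    start <- starts[which.max(energy)]
  }
  x <- wave$samples[start:(start + L - 1L)]
  waveform(apply_ramps(x, wave$rate, ramp), wave$rate)
}

#' Build an experimental trial from four excerpts
#'
#' Concatenates four different 2 s sound sources of the same category into
#' one 8 s trial. Joins are butt-joins; clicks are avoided by the 10 ms
#' raised-cosine ramps already present on each excerpt, so the trial
#' duration is exactly the sum of the excerpt durations.
#'
#' @param sounds List of four [waveform()]s with equal sample rates.
#' @param source_ids Character vector of four distinct source identifiers.
#' @param category `"animal"` or `"tool"`; either a single value or one
#'   per sound (which must then all agree -- mixed-category trials are an
#'   error).
#' @param condition One of `mful_a`, `mful_t`, `mless_a`, `mless_t`.
#' @return An object of class `trial` with fields `condition`, `category`,
#'   `source_ids` and `wave`.
#' @export
build_trial <- function(sounds, source_ids, category, condition) {
  if (!is.list(sounds) || length(sounds) != 4L)
    stop("a trial requires exactly 4 sounds")
  if (length(source_ids) != 4L || anyDuplicated(source_ids))
    stop("a trial requires 4 distinct source_ids")
  category <- unique(category)
  if (length(category) != 1L || !category %in% c("animal", "tool"))
    stop("all sounds in a trial must share one category (animal or tool)")
  if (!condition %in% setdiff(TRIAL_CONDITIONS, "silence"))
    stop("unknown trial condition: ", condition)
  rates <- vapply(sounds, function(w) w$rate, numeric(1))
  if (length(unique(rates)) != 1L) stop("all sounds must share a sample rate")
  x <- unlist(lapply(sounds, `[[`, "samples"))
  structure(list(condition = condition, category = category,
                 source_ids = source_ids,
                 wave = waveform(x, rates[1])),
            class = "trial")
}

silence_trial <- function() {
  structure(list(condition = "silence", category = NA_character_,
                 source_ids = character(0), wave = NULL),
            class = "trial")
}

#' @export
print.trial <- function(x, ...) {
  if (x$condition == "silence") cat("<trial: silence>\n")
  else cat(sprintf("<trial %s (%s): %s>\n", x$condition, x$category,
                   paste(x$source_ids, collapse = ", ")))
  invisible(x)
}

#' Build matched meaningful and meaningless trial sets
#'
#' Partitions the inventory into four-source groups per category and
#' builds, for each group, one "meaningful" trial from the raw excerpts
#' and one matched "meaningless" trial from modulation-filtered versions
#' of exactly the same sources (spectral low-pass for animal sounds,
#' temporal low-pass for tool sounds). Every inventory entry is used
#' exactly once in the meaningful set; a full 64 + 64 inventory yields
#' 16 animal + 16 tool meaningful trials and 32 matched meaningless trials.
#'
#' @param inventory A `sound_inventory` whose per-category sizes are
#'   divisible by 4.
#' @param animal_filter,tool_filter [filter_spec()]s for the two
#'   categories; defaults are the study presets ([animal_preset()],
#'   [tool_preset()]).
#' @param params Spectrogram parameters for filtering.
#' @param max_iter,tol,seed Inversion settings (see
#'   [invert_log_spectrogram()]); `seed` also shuffles the grouping of
#'   sources into trials when not `NULL` (default: manifest order).
#' @param excerpt_dur Excerpt duration in seconds (default 2).
#' @param render_audio If FALSE, skip synthesis/filtering and emit
#'   trials carrying only conditions and source assignments.
#' @return A list with `meaningful` and `meaningless` lists of `trial`s,
#'   matched element-wise by source set.
#' @export
build_trial_sets <- function(inventory,
                             animal_filter = animal_preset(),
                             tool_filter = tool_preset(),
                             params = spectrogram_params(),
                             max_iter = 50L, tol = 1e-3, seed = NULL,
                             excerpt_dur = 2, render_audio = TRUE) {
  stopifnot(inherits(inventory, "sound_inventory"))
  cats <- vapply(inventory$entries, `[[`, "", "category")
  meaningful <- list(); meaningless <- list()
  for (cat_name in c("animal", "tool")) {
    idx <- which(cats == cat_name)
    if (length(idx) == 0L) next
    if (length(idx) %% 4 != 0)
      stop("inventory has ", length(idx), " ", cat_name,
           " sounds; must be divisible by 4")
    if (!is.null(seed))
      idx <- with_seed(seed + match(cat_name, c("animal", "tool")),
                       sample(idx))
    groups <- split(idx, ceiling(seq_along(idx) / 4))
    filt <- if (cat_name == "animal") animal_filter else tool_filter
    cond_m <- if (cat_name == "animal") "mful_a" else "mful_t"
    cond_l <- if (cat_name == "animal") "mless_a" else "mless_t"
    for (g in groups) {
      ids <- vapply(inventory$entries[g], `[[`, "", "source_id")
      if (render_audio) {
        exc <- lapply(inventory$entries[g], function(e)
          excerpt(e$wave, dur = excerpt_dur))
        filtered <- lapply(exc, function(w)
          mps_filter_sound(w, filt, params = params, max_iter = max_iter,
                           tol = tol,
                           seed = if (is.null(seed)) 1L else seed))
        meaningful[[length(meaningful) + 1L]] <-
          build_trial(exc, ids, cat_name, cond_m)
        meaningless[[length(meaningless) + 1L]] <-
          build_trial(filtered, ids, cat_name, cond_l)
      } else {
        meaningful[[length(meaningful) + 1L]] <-
          structure(list(condition = cond_m, category = cat_name,
                         source_ids = ids, wave = NULL), class = "trial")
        meaningless[[length(meaningless) + 1L]] <-
          structure(list(condition = cond_l, category = cat_name,
                         source_ids = ids, wave = NULL), class = "trial")
      }
    }
  }
  list(meaningful = meaningful, meaningless = meaningless)
}

#' Assemble the two-run scanning session
#'
#' Pools the meaningful and meaningless trial sets (four sound conditions
#' of 16 trials each for the full design) and adds `n_silence_per_run`
#' silence baseline trials to each run. Each run presents every sound
#' trial once, in a seeded random order that is fixed across subjects;
#' with the full design this yields 72 trials per run and 144 in total.
#'
#' @param trial_sets Result of [build_trial_sets()].
#' @param n_silence_per_run Number of silence trials per run (default 8).
#' @param seed Integer seed driving the (fixed) presentation orders.
#' @return An object of class `session_design` with `runs` (two ordered
#'   trial lists) and `seed`.
#' @export
build_session <- function(trial_sets, n_silence_per_run = 8, seed = 1L) {
  sound_trials <- c(trial_sets$meaningful, trial_sets$meaningless)
  if (length(sound_trials) == 0L) stop("trial sets are empty")
  runs <- with_seed(seed, lapply(1:2, function(run) {
    trials <- c(sound_trials,
                replicate(n_silence_per_run, silence_trial(),
                          simplify = FALSE))
    trials[sample(length(trials))]
  }))
  structure(list(runs = runs, seed = as.integer(seed)),
            class = "session_design")
}

#' Per-run condition counts of a session design
#'
#' @param design A `session_design`.
#' @return Integer matrix, runs x conditions (`mful_a`, `mful_t`,
#'   `mless_a`, `mless_t`, `silence`).
#' @export
session_condition_counts <- function(design) {
  stopifnot(inherits(design, "session_design"))
  t(vapply(design$runs, function(run) {
    conds <- vapply(run, `[[`, "", "condition")
    vapply(TRIAL_CONDITIONS, function(cc) sum(conds == cc), integer(1))
  }, integer(length(TRIAL_CONDITIONS))))
}

#' @export
print.session_design <- function(x, ...) {
  counts <- session_condition_counts(x)
  cat(sprintf("<session_design: %d runs of %s trials (seed %d)>\n",
              length(x$runs),
              paste(rowSums(counts), collapse = " + "), x$seed))
  invisible(x)
}

#' Write a session design description to JSON
#'
#' Records, per run, the ordered conditions and source assignments (not
#' the audio itself).
#'
#' @param design A `session_design`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_session_design <- function(design, path) {
  stopifnot(inherits(design, "session_design"))
  out <- list(
    seed = design$seed,
    runs = lapply(design$runs, function(run)
      lapply(run, function(tr)
        list(condition = tr$condition,
             category = if (is.na(tr$category)) NULL else tr$category,
             source_ids = tr$source_ids))))
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
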