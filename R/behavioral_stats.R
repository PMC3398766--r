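# Scoring and statistics for the six-alternative forced-choice
# sound-picture matching task (24 animal + 24 tool items, chance 1/6).

#' Patient sound-picture matching scores
#'
#' The nine semantic-dementia patients' scores on the post-scan
#' sound-picture matching task: number of items correct out of 24 per
#' category, matching each heard sound to its picture in a six-photograph
#' array (chance = 1/6). Also shipped as
#' `inst/extdata/sd_sound_picture_scores.csv`.
#'
#' @return A data frame with columns `subject_id`, `group`,
#'   `animal_correct`, `tool_correct`.
#' @export
sd_patient_scores <- function() {
  data.frame(
    subject_id = paste0("case_", 1:9),
    group = "SD",
    animal_correct = c(9L, 12L, 14L, 23L, 12L, 10L, 4L, 7L, 0L),
    tool_correct   = c(10L, 17L, 14L, 20L, 8L, 10L, 6L, 3L, 0L),
    stringsAsFactors = FALSE)
}

#' Published control-group score summary
#'
#' Healthy-control summary statistics for the same task (raw per-subject
#' control scores are not available): per-category mean, standard
#' deviation and minimum over 22 controls.
#'
#' @return A list with elements `animal` and `tool`, each
#'   `(mean, sd, min)`, plus `n`.
#' @export
control_score_summary <- function() {
  list(animal = c(mean = 21.7, sd = 1.9, min = 15),
       tool   = c(mean = 19.9, sd = 2.1, min = 16),
       n = 22L)
}

#' Read a score table from CSV
#'
#' @param path CSV with columns `subject_id`, `group`, `animal_correct`,
#'   `tool_correct`; counts must lie in \[0, 24\].
#' @return A validated data frame.
#' @export
read_score_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "animal_correct", "tool_correct")
  if (!all(need %in% names(df)))
    stop("score table must have columns: ", paste(need, collapse = ", "))
  counts <- c(df$animal_correct, df$tool_correct)
  if (any(counts < 0 | counts > 24)) stop("scores must lie in [0, 24]")
  df
}

#' Exact binomial above-chance test
#'
#' One-tailed exact binomial upper-tail probability of scoring at least
#' `correct` out of `n_trials` under a guessing rate `p_chance`
#' (1/6 for a six-alternative forced choice). Vectorised over `correct`.
#'
#' @param correct Number(s) correct, `0 <= correct <= n_trials`.
#' @param n_trials Number of trials.
#' @param p_chance Chance success probability (default 1/6).
#' @param alpha Significance level (default 0.05).
#' @return A data frame with columns `correct`, `p_value`
#'   (`P(X >= correct)`) and `significant` (`p_value < alpha`).
#' @export
binomial_above_chance <- function(correct, n_trials, p_chance = 1 / 6,
                                  alpha = 0.05) {
  if (any(correct < 0 | correct > n_trials) || any(correct != round(correct)))
    stop("correct must be integer counts in [0, n_trials]")
  p <- stats::pbinom(correct - 1, n_trials, p_chance, lower.tail = FALSE)
  data.frame(correct = correct, p_value = p, significant = p < alpha)
}

#' Paired mean difference with Student-t confidence interval
#'
#' Mean of paired differences `a - b` with a t-based confidence interval
#' on `n - 1` degrees of freedom.
#'
#' @param a,b Paired score vectors of equal length (>= 2).
#' @param level Confidence level (default 0.95).
#' @return A list with `mean_diff`, `ci_low`, `ci_high`, `t`, `df`,
#'   `p_value`.
#' @export
paired_mean_difference_ci <- function(a, b, level = 0.95) {
  if (length(a) != length(b)) stop("a and b must have equal length")
  if (length(a) < 2) stop("need at least 2 pairs")
  d <- a - b
  if (stats::sd(d) == 0) {
    # constant differences: the interval degenerates to a point
    return(list(mean_diff = mean(d), ci_low = mean(d), ci_high = mean(d),
                t = NA_real_, df = length(d) - 1, p_value = NA_real_))
  }
  tt <- stats::t.test(a, b, paired = TRUE, conf.level = level)
  list(mean_diff = unname(tt$estimate), ci_low = tt$conf.int[1],
       ci_high = tt$conf.int[2], t = unname(tt$statistic),
       df = unname(tt$parameter), p_value = tt$p.value)
}

#' Per-group score summary
#'
#' Group means, standard deviations and minima per category, plus the
#' animal minus tool mean gap, following the reporting conventions of the
#' score table (1 dp at presentation; values here are unrounded). A group
#' of one subject yields `sd = NA`.
#'
#' @param table A score table (see [read_score_table()]).
#' @return A data frame with one row per group and columns `group`, `n`,
#'   `animal_mean`, `animal_sd`, `animal_min`, `tool_mean`, `tool_sd`,
#'   `tool_min`, `animal_tool_gap`.
#' @export
group_summary <- function(table) {
  if (nrow(table) == 0L) stop("score table is empty")
  groups <- unique(table$group)
  do.call(rbind, lapply(groups, function(g) {
    sub <- table[table$group == g, , drop = FALSE]
    a <- sub$animal_correct; t_ <- sub$tool_correct
    data.frame(group = g, n = nrow(sub),
               animal_mean = mean(a),
               animal_sd = if (nrow(sub) > 1) stats::sd(a) else NA_real_,
               animal_min = min(a),
               tool_mean = mean(t_),
               tool_sd = if (nrow(sub) > 1) stats::sd(t_) else NA_real_,
               tool_min = min(t_),
               animal_tool_gap = mean(a) - mean(t_),
               stringsAsFactors = FALSE)
  }))
}

#' Above-chance classification of every subject
#'
#' Applies the exact binomial above-chance rule both per category
#' (24 trials each) and to the pooled score (48 trials).
#'
#' @param table A score table.
#' @inheritParams binomial_above_chance
#' @return `table` with logical columns `animal_above_chance`,
#'   `tool_above_chance`, `combined_above_chance` and the associated
#'   p-value columns.
#' @export
classify_above_chance <- function(table, p_chance = 1 / 6, alpha = 0.05) {
  a <- binomial_above_chance(table$animal_correct, 24, p_chance, alpha)
  t_ <- binomial_above_chance(table$tool_correct, 24, p_chance, alpha)
  comb <- binomial_above_chance(table$animal_correct + table$tool_correct,
                                48, p_chance, alpha)
  cbind(table,
        animal_p = a$p_value, animal_above_chance = a$significant,
        tool_p = t_$p_value, tool_above_chance = t_$significant,
        combined_p = comb$p_value,
        combined_above_chance = comb$significant)
}
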