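test_that("excerpts have exactly the requested duration", {
  w <- synth_sound("am_noise", am_rate = 5, duration = 5, rate = 8000,
                   seed = 1)
  e <- excerpt(w, dur = 2)
  expect_identical(length(e$samples), 16000L)
  # an input of exactly the target duration is returned whole (ramped)
  w2 <- synth_sound("tone", f0 = 300, duration = 2, rate = 8000)
  expect_identical(length(excerpt(w2, 2)$samples), length(w2$samples))
  expect_error(excerpt(waveform(rnorm(100), 8000), 2), "shorter")
})

test_that("excerpt selection finds the maximal-energy window", {
  # energy only in the middle second of a 5 s input
  rate <- 4000
  x <- numeric(5 * rate)
  x[(2 * rate):(3 * rate)] <- rnorm(rate + 1)
  w <- waveform(x, rate)
  e <- excerpt(w, dur = 2, ramp = 0)
  # oracle: brute force over a coarse grid of candidate windows
  L <- 2 * rate
  cand_energy <- vapply(seq(1, length(x) - L + 1, by = 50), function(s)
    sum(x[s:(s + L - 1)]^2), numeric(1))
  expect_gte(sum(e$samples^2), max(cand_energy) * 0.999)
  # the selected window must overlap the energetic second
  expect_gt(sum(e$samples^2), 0.5 * sum(x^2))
})

test_that("trials are validated concatenations of four sources", {
  rate <- 8000
  sounds <- lapply(1:4, function(i)
    synth_sound("tone", f0 = 200 * i, duration = 2, rate = rate, seed = i))
  tr <- build_trial(sounds, paste0("animal_", 1:4), "animal", "mful_a")
  expect_identical(length(tr$wave$samples), 64000L)  # 4 x 2 s x 8 kHz
  expect_error(
    build_trial(sounds, c("a", "a", "b", "c"), "animal", "mful_a"),
    "distinct")
  expect_error(
    build_trial(sounds[1:3], paste0("s", 1:3), "animal", "mful_a"),
    "exactly 4")
  expect_error(
    build_trial(sounds, paste0("s", 1:4),
                c("animal", "animal", "tool", "animal"), "mful_a"),
    "share one category")
})

test_that("a toy inventory yields matched trial sets end to end", {
  inv <- make_inventory(4, rate = 8000, duration = 2.2, seed = 6)
  sets <- build_trial_sets(inv, params = fx_params(), max_iter = 5)
  expect_length(sets$meaningful, 2)   # 1 animal + 1 tool
  expect_length(sets$meaningless, 2)
  for (i in seq_along(sets$meaningful)) {
    expect_identical(sort(sets$meaningful[[i]]$source_ids),
                     sort(sets$meaningless[[i]]$source_ids))
    expect_identical(sets$meaningful[[i]]$category,
                     sets$meaningless[[i]]$category)
    # 8 s at the inventory rate
    expect_identical(length(sets$meaningless[[i]]$wave$samples),
                     8L * 8000L)
  }
  conds <- vapply(sets$meaningless, `[[`, "", "condition")
  expect_setequal(conds, c("mless_a", "mless_t"))
})

test_that("the full design uses all 128 sounds once across 32 trials", {
  inv <- make_inventory(64, rate = 8000, render = FALSE)
  sets <- build_trial_sets(inv, render_audio = FALSE)
  expect_length(sets$meaningful, 32)
  conds <- vapply(sets$meaningful, `[[`, "", "condition")
  expect_equal(sum(conds == "mful_a"), 16)
  expect_equal(sum(conds == "mful_t"), 16)
  used <- unlist(lapply(sets$meaningful, `[[`, "source_ids"))
  expect_identical(sort(used),
                   sort(vapply(inv$entries, `[[`, "", "source_id")))
  # meaningless set is source-matched trial by trial
  used_less <- unlist(lapply(sets$meaningless, `[[`, "source_ids"))
  expect_identical(sort(used), sort(used_less))
  expect_error(build_trial_sets(make_inventory(64, render = FALSE,
                                               seed = 3)$entries[[1]]))
})

test_that("sessions have two fixed-order runs of 72 trials", {
  inv <- make_inventory(64, rate = 8000, render = FALSE)
  sets <- build_trial_sets(inv, render_audio = FALSE)
  des <- build_session(sets, seed = 11)
  counts <- session_condition_counts(des)
  expect_identical(unname(counts),
                   matrix(rep(c(16L, 16L, 16L, 16L, 8L), each = 2), 2))
  expect_equal(sum(counts), 144)
  # the order is a pure function of the seed
  des2 <- build_session(sets, seed = 11)
  ord <- function(d) lapply(d$runs, function(r)
    vapply(r, `[[`, "", "condition"))
  expect_identical(ord(des), ord(des2))
  des3 <- build_session(sets, seed = 12)
  expect_false(identical(ord(des), ord(des3)))
  # design serialisation round-trips through JSON
  f <- tempfile(fileext = ".json")
  write_session_design(des, f)
  js <- jsonlite::read_json(f)
  expect_length(js$runs, 2)
  expect_length(js$runs[[1]], 72)
})
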