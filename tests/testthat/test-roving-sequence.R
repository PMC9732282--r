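test_that("a default run has 1152 events, ~20% deviants and valid structure", {
  cfg <- sequence_config(n_runs = 1, seed = 11)
  sq <- generate_sequence(cfg)
  expect_equal(nrow(sq), 1152)
  # independent scan over emitted role labels
  expect_equal(sum(sq$role == "deviant"), round(0.2 * 1152))
  # deviant = first event of each train, re-derived from pitch changes
  derived <- c(TRUE, sq$pitch[-1] != sq$pitch[-nrow(sq)])
  derived[1] <- TRUE
  expect_identical(ifelse(derived, "deviant", "standard"), sq$role)
  expect_true(validate_sequence(sq))
  # pitch-wise deviant counts differ by at most 1
  devs <- table(sq$pitch[sq$role == "deviant"])
  expect_lte(abs(devs[["high"]] - devs[["low"]]), 1)
  # mean train length ~ 1 / deviant fraction
  tl <- rle(sq$train_id)$lengths
  expect_true(all(tl >= 2))
  expect_equal(mean(tl), 1152 / round(0.2 * 1152), tolerance = 1e-12)
  # onsets advance by the ISI
  expect_equal(unique(round(diff(sq$onset_s), 9)), cfg$isi)
})

test_that("a single-train configuration yields deviant-then-standards", {
  sq <- generate_sequence(sequence_config(n_events_per_run = 5, n_runs = 1,
                                          train_length_support = 5,
                                          seed = 1))
  expect_equal(sq$role, c("deviant", rep("standard", 4)))
  expect_equal(length(unique(sq$train_id)), 1L)
})

test_that("infeasible train-length configurations raise a configuration error", {
  expect_error(generate_sequence(sequence_config(n_events_per_run = 9,
                                                 n_runs = 1,
                                                 train_length_support = 5)),
               "infeasible")
  expect_error(sequence_config(deviant_fraction = 1.2), "deviant_fraction")
  expect_error(sequence_config(train_length_support = c(1, 4)), ">= 2")
})

test_that("generation is bit-identical under a fixed seed and varies across seeds", {
  a <- generate_sequence(sequence_config(n_events_per_run = 240, n_runs = 2,
                                         seed = 5))
  b <- generate_sequence(sequence_config(n_events_per_run = 240, n_runs = 2,
                                         seed = 5))
  c <- generate_sequence(sequence_config(n_events_per_run = 240, n_runs = 2,
                                         seed = 6))
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_false(identical(as.data.frame(a), as.data.frame(c)))
})

test_that("n_trains override fixes the number of deviants independently of the 20% rule", {
  sq <- generate_sequence(sequence_config(n_events_per_run = 1040,
                                          n_runs = 1, n_trains = 208,
                                          seed = 2))
  expect_equal(sum(sq$role == "deviant"), 208)
  expect_equal(length(last_standard_indices(sq)), 207)
})

test_that("last_standard_indices picks the event before each non-initial deviant", {
  sq <- toy_sequence("HHHLL")
  ls <- last_standard_indices(sq)
  expect_equal(which(sq$role == "deviant"), c(1L, 4L))
  expect_equal(as.integer(ls), 3L)
  # single train: no preceding train, empty set
  expect_length(last_standard_indices(toy_sequence("HHHH")), 0L)
  # run boundaries reset the bookkeeping
  two_runs <- toy_sequence("HHHLLHHLL", run = rep(1:2, c(5, 4)))
  ls2 <- last_standard_indices(two_runs)
  expect_equal(as.integer(ls2), c(3L, 7L))
  # generated run: |result| = trains - 1, by independent train counting
  gen <- generate_sequence(sequence_config(n_events_per_run = 300,
                                           n_runs = 1, seed = 3))
  n_trains <- length(rle(gen$train_id)$lengths)
  expect_length(last_standard_indices(gen), n_trains - 1L)
  # out-of-order events are a structural error
  bad <- toy_sequence("HHLL")
  bad$index <- c(1L, 3L, 2L, 4L)
  expect_error(last_standard_indices(bad), "out of order")
})

test_that("balance_report balances counts and mean surprise across pitches", {
  sq <- generate_sequence(sequence_config(n_runs = 1, seed = 11))
  s <- surprise_series(sq)
  br <- balance_report(sq, s)
  expect_lte(br$max_abs_surprise_gap, 0.05)
  expect_lte(abs(br$n_events_per_pitch[["high"]] -
                   br$n_events_per_pitch[["low"]]),
             max(attr(sq, "config")$train_length_support))
  # means agree with an independent per-event accumulation
  for (p in c("high", "low")) {
    acc <- 0; cnt <- 0
    for (i in seq_len(nrow(sq)))
      if (sq$pitch[i] == p) { acc <- acc + s[i]; cnt <- cnt + 1 }
    expect_equal(br$mean_surprise_per_pitch[[p]], acc / cnt,
                 tolerance = 1e-12)
  }
  # relabeling symmetry: swapping pitches exchanges the per-pitch counts
  swapped <- sq
  swapped$pitch <- ifelse(sq$pitch == "high", "low", "high")
  br2 <- balance_report(swapped, s)
  expect_equal(unname(br2$n_events_per_pitch[c("low", "high")]),
               unname(br$n_events_per_pitch[c("high", "low")]))
  expect_error(balance_report(sq, s[-1]), "does not match")
})

test_that("the validator rejects corrupted sequences", {
  sq <- generate_sequence(sequence_config(n_events_per_run = 60, n_runs = 1,
                                          seed = 4))
  bad_role <- sq; bad_role$role[2] <- "deviant"
  expect_error(validate_sequence(bad_role), "roles inconsistent")
  bad_onset <- sq; bad_onset$onset_s[10] <- bad_onset$onset_s[10] + 0.5
  expect_error(validate_sequence(bad_onset), "constant-ISI")
})
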