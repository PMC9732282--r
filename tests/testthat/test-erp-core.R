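test_that("condition_average is the pointwise mean and honours selectors", {
  set.seed(1)
  data <- array(rnorm(3 * 10 * 12), c(3, 10, 12))
  e <- toy_epochs(data)
  # identical trials: the mean is any single trial
  same <- toy_epochs(array(rep(data[, , 1], 12), c(3, 10, 12)))
  expect_equal(condition_average(same, 1:12)$data, data[, , 1],
               ignore_attr = TRUE)
  # naive per-trial accumulation oracle
  idx <- c(2, 5, 9)
  acc <- matrix(0, 3, 10)
  for (k in idx) acc <- acc + data[, , k]
  w <- condition_average(e, idx)
  expect_equal(w$data, acc / 3, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(w$n_trials, 3L)
  # predicate selectors work on the trial metadata
  e$trials$role <- rep(c("deviant", "standard"), 6)
  wd <- condition_average(e, function(tr) tr$role == "deviant")
  expect_equal(wd$n_trials, 6L)
  # empty selections name the selector
  expect_error(condition_average(e, function(tr) tr$role == "x"),
               "matched no trials")
  # linearity in the data
  e2 <- toy_epochs(3 * data)
  expect_equal(condition_average(e2, idx)$data, 3 * w$data,
               tolerance = 1e-12)
})

test_that("selector role=deviant selects exactly the sequence's deviant count", {
  st <- small_study(n_subjects = 2, n_events = 60, seed = 5,
                    conditions = c(solo = 300), n_channels = 4)
  e <- st$epochs[[1]]$solo
  w <- condition_average(e, function(tr) tr$role == "deviant")
  expect_equal(w$n_trials, sum(st$seq$role == "deviant"))
})

test_that("mmn_differential uses only the last standard of each train", {
  st <- small_study(n_subjects = 2, n_events = 60, seed = 6,
                    conditions = c(solo = 300), n_channels = 4)
  e <- st$epochs[[1]]$solo
  sq <- st$seq
  ls <- last_standard_indices(sq)
  dv <- attr(ls, "deviant_indices")
  w <- mmn_differential(e, sq)
  # two-pass oracle: average the two sets, then subtract
  avg <- function(idx) {
    acc <- matrix(0, dim(e$data)[1], dim(e$data)[2])
    for (k in idx) acc <- acc + e$data[, , k]
    acc / length(idx)
  }
  expect_equal(w$data, avg(dv) - avg(as.integer(ls)), tolerance = 1e-10,
               ignore_attr = TRUE)
  # corrupting non-last standards leaves the result unchanged
  corrupt <- e
  other_std <- setdiff(which(sq$role == "standard"), as.integer(ls))
  corrupt$data[, , other_std] <- 1e6
  expect_equal(mmn_differential(corrupt, sq)$data, w$data)
  # deviants identical to their last standards: all-zero waveform
  selfsub <- e
  selfsub$data[, , dv] <- selfsub$data[, , as.integer(ls)]
  expect_equal(max(abs(mmn_differential(selfsub, sq)$data)), 0)
  # a single-train sequence cannot form a differential
  sq1 <- toy_sequence("HHHH")
  e1 <- toy_epochs(array(rnorm(2 * 5 * 4), c(2, 5, 4)))
  expect_error(mmn_differential(e1, sq1), "no deviant with a preceding")
})

test_that("the synthetic default differential is negative at Fz without noise", {
  sq <- generate_sequence(sequence_config(n_events_per_run = 60, n_runs = 1,
                                          seed = 2))
  s <- surprise_series(sq)
  sim <- simulation_config(n_subjects = 3, noise_sd = 0, subject_sd = 0,
                           seed = 1)
  eps <- simulate_epochs(sq, s, sim, conditions = "solo")
  tt <- epoch_times(sim)
  win <- tt >= 0.19 & tt <= 0.23
  for (e in eps) {
    w <- mmn_differential(e$solo, sq)
    expect_true(all(w$data["Fz", win] < 0))
  }
})

test_that("negative_peak finds the windowed minimum with earliest-sample ties", {
  tt <- seq(0, 0.5, by = 0.002)
  y <- -exp(-((tt - 0.210)^2) / (2 * 0.02^2))
  wave <- erp_wave(rbind(y, 0 * y), tt, c("Fz", "Cz"), 1)
  pk <- negative_peak(wave, "Fz", c(100, 300))
  expect_equal(pk$latency_ms, 210)
  expect_equal(pk$amplitude_uv, -1)
  expect_false(pk$degenerate)
  # sign symmetry via the positive-peak counterpart
  flipped <- erp_wave(rbind(-y, 0 * y), tt, c("Fz", "Cz"), 1)
  pp <- positive_peak(flipped, "Fz", c(100, 300))
  expect_equal(pp$latency_ms, pk$latency_ms)
  expect_equal(pp$amplitude_uv, -pk$amplitude_uv)
  # exhaustive argmin oracle on a rough waveform
  set.seed(8)
  z <- rnorm(length(tt))
  wz <- erp_wave(rbind(z, z), tt, c("Fz", "Cz"), 1)
  pkz <- negative_peak(wz, "Fz", c(50, 450))
  in_win <- tt * 1000 >= 50 & tt * 1000 <= 450
  expect_equal(pkz$amplitude_uv, min(z[in_win]))
  expect_equal(pkz$latency_ms, tt[in_win][which.min(z[in_win])] * 1000)
  # flat windows are flagged degenerate, with ties to the earliest sample
  flat <- erp_wave(matrix(1, 1, length(tt)), tt, "Fz", 1)
  expect_warning(pf <- negative_peak(flat, "Fz", c(100, 300)), "degenerate")
  expect_true(pf$degenerate)
  expect_equal(pf$latency_ms, 100)
  expect_error(negative_peak(wave, "XX"), "not in the montage")
})

test_that("baseline correction removes the pre-onset mean per channel", {
  tt <- seq(-0.1, 0.3, by = 0.01)
  m <- matrix(rnorm(2 * length(tt)), 2)
  bc <- baseline_correct(m, tt)
  expect_equal(rowMeans(bc[, tt < 0]), c(0, 0), tolerance = 1e-12)
  expect_error(baseline_correct(m, tt + 1), "no pre-onset")
})

test_that("grand_average averages subjects pointwise", {
  tt <- seq(0, 0.1, by = 0.01)
  waves <- lapply(1:3, function(i)
    erp_wave(matrix(i, 2, length(tt)), tt, c("a", "b"), 1))
  ga <- grand_average(waves)
  expect_equal(unique(as.vector(ga$data)), 2)
  expect_equal(ga$n_trials, 3L)
})
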