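# Population onset detection: LN readout, naive baselines, scoring

test_that("onset LN fit matches the multi-cell closed-form least-squares oracle", {
  rec <- subset_cells(fix_population(), fix_population()$cell_ids[1:3])
  halves <- split_recording(rec)
  dec <- fit_onset_ln(halves$train, filter_length = 125)
  b <- bin_response(halves$train, 25, 0.5)
  s <- indicator_from_stimulus(halves$train$stimulus, b, "binary")
  X <- rgcdecode:::lagged_design(b$counts, 125, b$stride)
  oracle <- ls_oracle(X, s[seq_len(nrow(X))])
  expect_lt(max(abs(as.numeric(t(dec$filters)) - oracle$w)), 1e-6)
  expect_lt(abs(dec$constant - oracle$C), 1e-6)
})

test_that("a noiseless pulse cell yields a zero-error detector on its training data", {
  stim <- generate_stimulus(40, seed = 3)
  # one deterministic spike 50 ms after every onset, no baseline
  train <- stim$flashes$onset + 50
  rec <- as_population_recording(list(c1 = train), stim)
  dec <- fit_onset_ln(rec, filter_length = 125)
  est <- detect_onsets(dec, rec)
  rep <- score_detection(est, stim)
  expect_equal(rep$false_negative_rate, 0)
  expect_equal(rep$false_positive_rate, 0)
})

test_that("recordings without flashes are rejected with a no-events error", {
  stim <- generate_stimulus(0)
  stim$total_duration <- 5000
  rec <- as_population_recording(list(c1 = c(100, 900, 2000)), stim)
  expect_error(fit_onset_ln(rec), "no events")
  expect_error(fit_onset_ln(fix_population(), cell_subset = character(0)),
               "empty cell subset")
})

test_that("detection emits one event per supra-threshold excursion at its first window", {
  dec <- structure(list(threshold = 1), class = "onset_ln_decoder")
  fake <- function(s_hat) list(s_hat = s_hat, times = seq_along(s_hat) * 12.5)
  with_mocked_bindings(
    onset_linear_output = function(decoder, recording) fake(c(0, 0.5, 1.2, 1.4, 0.3, 2, 0)),
    {
      est <- detect_onsets(dec, NULL)
      expect_equal(est, c(3, 6) * 12.5)   # rising edges only
    },
    .package = "rgcdecode")
  with_mocked_bindings(
    onset_linear_output = function(decoder, recording) fake(rep(0.5, 10)),
    expect_equal(length(detect_onsets(dec, NULL)), 0),
    .package = "rgcdecode")
})

test_that("greedy matching reproduces hand-enumerated FN/FP rates", {
  fl <- data.frame(onset = c(1000, 3000, 5000, 7000),
                   colour = c("red", "green", "red", "green"),
                   intensity = rep(0.3, 4))
  stim <- rgcdecode:::new_stimulus_sequence(fl, 66, 10000)
  # 3 detections: two within 125 ms, one far off
  rep <- score_detection(c(1050, 3100, 4300), stim)
  expect_equal(rep$false_negative_rate, 2 / 4)
  expect_equal(rep$false_positive_rate, 1 / 3)
  # exact detections: no errors
  rep0 <- score_detection(fl$onset, stim)
  expect_equal(rep0$false_negative_rate, 0)
  expect_equal(rep0$false_positive_rate, 0)
  # everything shifted beyond tolerance: both rates 1
  rep1 <- score_detection(fl$onset + 200, stim)
  expect_equal(rep1$false_negative_rate, 1)
  expect_equal(rep1$false_positive_rate, 1)
})

test_that("matching bounds every matched timing error by the tolerance", {
  set.seed(5)
  fl <- data.frame(onset = seq(1000, 40000, by = 1300),
                   colour = sample(c("red", "green"), 31, replace = TRUE),
                   intensity = rep(0.3, 31))
  stim <- rgcdecode:::new_stimulus_sequence(fl, 66, 45000)
  est <- sort(c(fl$onset + rnorm(31, 0, 150), runif(5, 0, 45000)))
  rep <- score_detection(est, stim, tolerance = 125)
  expect_true(all(abs(rep$matches$error) <= 125))
})

test_that("timing report: rms and red-green bias definitions", {
  m <- data.frame(error = c(10, -10, 10, -10),
                  colour = c("red", "red", "green", "green"))
  t1 <- timing_errors(m)
  expect_equal(t1$rms_error, 10)
  expect_equal(t1$bias, 0)
  m2 <- data.frame(error = c(10, 10, 0, 0),
                   colour = c("red", "red", "green", "green"))
  expect_equal(timing_errors(m2)$bias, 10)
  empty <- timing_errors(data.frame(error = numeric(0),
                                    colour = character(0)))
  expect_true(empty$empty)
  expect_true(is.na(empty$rms_error))
})

test_that("weighted naive readout with equal forced weights reduces to the unweighted one", {
  rec <- fix_population()
  halves <- split_recording(rec)
  unw <- naive_rate_detector(halves$train, weighted = FALSE)
  forced <- unw
  forced$weights[] <- 1          # already 1, make the reduction explicit
  forced$constant <- 0
  o1 <- rgcdecode:::naive_linear_output(unw, halves$test)
  o2 <- rgcdecode:::naive_linear_output(forced, halves$test)
  expect_equal(o1$s_hat, o2$s_hat)
  expect_equal(detect_onsets(unw, halves$test), detect_onsets(forced, halves$test))
})

test_that("weighted naive readout beats the unweighted one when most cells are noise", {
  # few informative cells among many purely spontaneous ones: the
  # unweighted population count is swamped by noise, per-cell weights
  # recover the informative minority
  stim <- generate_stimulus(150, seed = 81)
  resp <- cell_params("r", baseline_rate = 2,
                      gain = c(red = 4, green = 4),
                      latency = c(red = 80, green = 80),
                      suppression = 0.5)
  trains <- c(
    lapply(1:4, function(k) simulate_cell(resp, stim, seed = 400 + k)),
    lapply(1:26, function(k) {
      p <- cell_params(paste0("n", k), baseline_rate = 10,
                       gain = c(red = 0, green = 0))
      simulate_cell(p, stim, seed = 500 + k)
    }))
  names(trains) <- sprintf("c%02d", seq_along(trains))
  rec <- as_population_recording(trains, stim)
  halves <- split_recording(rec)
  err <- function(det) {
    ev <- evaluate_detector(det, halves$test)
    ev$detection$false_negative_rate + ev$detection$false_positive_rate
  }
  e_unw <- err(naive_rate_detector(halves$train, weighted = FALSE))
  e_w <- err(naive_rate_detector(halves$train, weighted = TRUE))
  expect_lt(e_w, e_unw)
})

test_that("LN detector outperforms the naive readout on the same population", {
  rec <- fix_population()
  halves <- split_recording(rec)
  ln <- evaluate_detector(fit_onset_ln(halves$train, filter_length = 250),
                          halves$test)
  nv <- evaluate_detector(naive_rate_detector(halves$train, weighted = FALSE),
                          halves$test)
  e_ln <- ln$detection$false_negative_rate + ln$detection$false_positive_rate
  e_nv <- nv$detection$false_negative_rate + nv$detection$false_positive_rate
  expect_lte(e_ln, e_nv)
})

test_that("population-size sweep: error decreases with size; full size matches a single fit", {
  rec <- fix_population()
  sw <- population_size_sweep(rec, sizes = c(3, 12, 40), n_subgroups = 3,
                              filter_length = 125, seed = 2)
  tot <- sw$false_negative_rate + sw$false_positive_rate
  expect_true(all(diff(tot) < 0.05))       # non-increasing within MC error
  expect_lt(tot[3], tot[1])
  # size = full population: subgroup sampling is degenerate
  halves <- split_recording(rec)
  single <- evaluate_detector(fit_onset_ln(halves$train, filter_length = 125),
                              halves$test)
  expect_equal(sw$false_negative_rate[3],
               single$detection$false_negative_rate)
  expect_equal(sw$rms_error[3], single$timing$rms_error)
  expect_error(population_size_sweep(rec, sizes = 100), "exceeds")
})

test_that("no single cell detects onsets with both error rates at or below 5%", {
  rec <- fix_population()
  halves <- split_recording(rec)
  worst <- vapply(rec$cell_ids[seq(1, 40, by = 4)], function(id) {
    dec <- fit_onset_ln(halves$train, cell_subset = id, filter_length = 250)
    ev <- evaluate_detector(dec, halves$test)
    max(ev$detection$false_negative_rate, ev$detection$false_positive_rate)
  }, 0)
  expect_true(all(worst > 0.05))
})
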