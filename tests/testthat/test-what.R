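# Single-cell colour readouts: LN and first-spike latency

test_that("LN fit matches the closed-form least-squares oracle", {
  set.seed(21)
  for (rep in 1:3) {
    X <- matrix(rnorm(150 * 12, sd = 2), 150, 12)
    y <- sample(1:2, 150, replace = TRUE)
    trials <- structure(list(X = X, colour = y,
                             intensity = runif(150, 0.07, 0.7),
                             onset_used = seq_len(150), window_length = 25,
                             overlap = 0.5, filter_length = 150),
                        class = "colour_trials")
    dec <- fit_colour_ln(trials)
    oracle <- ls_oracle(X, y)
    expect_lt(max(abs(dec$filter - oracle$w)), 1e-8)
    expect_lt(abs(dec$constant - oracle$C), 1e-8)
  }
})

test_that("deterministic separable templates are fitted with zero training error", {
  trials <- fix_templates()
  dec <- fit_colour_ln(trials)
  expect_equal(dec$train_errors, 0)
  expect_equal(predict_colour(dec, trials), trials$colour)
})

test_that("threshold prediction rule: green at or above, red below", {
  dec <- structure(list(filter = 1, constant = 0, threshold = 1.5,
                        filter_length = 12.5, window_length = 25,
                        overlap = 0.5),
                   class = "colour_ln_decoder")
  mk <- function(x) structure(list(X = matrix(x, ncol = 1),
                                   colour = rep(1L, length(x)),
                                   intensity = rep(0.3, length(x)),
                                   onset_used = seq_along(x),
                                   window_length = 25, overlap = 0.5,
                                   filter_length = 12.5),
                              class = "colour_trials")
  expect_equal(predict_colour(dec, mk(c(1.2, 1.8, 1.5))), c(1L, 2L, 2L))
  expect_error(colour_linear_output(dec, fix_templates()), "match")
})

test_that("tuned cell decodes colour with held-out error below 10%", {
  acc <- colour_accuracy(fix_tuned()$train, fix_stimulus(), "ln")
  expect_gt(acc$accuracy, 0.90)
})

test_that("untuned cells sit at chance within binomial noise", {
  stim <- fix_stimulus()
  accs <- vapply(1:3, function(k) {
    p <- withr::with_seed(100 + k, sample_cell_params("untuned", "u"))
    tr <- simulate_cell(p, stim, seed = 200 + k)
    colour_accuracy(tr, stim, "ln")$accuracy
  }, 0)
  n_test <- 150
  expect_true(all(abs(accs - 0.5) < 4 * sqrt(0.25 / n_test)))
})

test_that("accuracy does not decrease as the colour latency separation grows", {
  stim <- generate_stimulus(250, seed = 31)
  acc_at <- function(sep) {
    p <- cell_params("c", baseline_rate = 8, gain = c(red = 3, green = 4.5),
                     latency = c(red = 60 + sep, green = 60),
                     kernel_width = 18, suppression = 0.9,
                     selectivity_class = "tuned")
    mean(vapply(1:2, function(k)
      colour_accuracy(simulate_cell(p, stim, seed = 40 + k), stim,
                      "ln")$accuracy, 0))
  }
  accs <- vapply(c(0, 35, 70), acc_at, 0)
  mc_slack <- 0.06
  expect_true(all(diff(accs) > -mc_slack))
  expect_gt(accs[3], accs[1])
})

test_that("first-spike decoder separates cleanly split latencies and matches brute force", {
  lat <- c(runif(30, 60, 160), runif(30, 180, 300))
  col <- rep(c(2L, 1L), each = 30)   # green early, red late
  dec <- fit_first_spike(lat, col)
  expect_equal(predict_colour_first_spike(dec, lat), col)
  # conditionals are normalised distributions
  expect_equal(unname(colSums(dec$conditional)), c(1, 1))
  # ML decision equals brute-force argmax for every bin midpoint
  mids <- head(dec$edges, -1) + dec$latency_bin / 2
  brute <- ifelse(dec$conditional[seq_along(mids), 2] >=
                  dec$conditional[seq_along(mids), 1], 2L, 1L)
  expect_equal(predict_colour_first_spike(dec, mids), unname(brute))
})

test_that("degenerate first-spike inputs: one trial per colour, no-spike fallback", {
  dec <- fit_first_spike(c(50, 250), c(2L, 1L))
  expect_equal(unname(colSums(dec$conditional)), c(1, 1))
  expect_equal(predict_colour_first_spike(dec, NA), 1L)
  dec2 <- fit_first_spike(c(50, 250), c(2L, 1L), no_spike_rule = 2L)
  expect_equal(predict_colour_first_spike(dec2, NA), 2L)
})

test_that("first-spike accuracy tracks the LN readout on tuned cells", {
  stim <- fix_stimulus()
  gaps <- vapply(1:3, function(k) {
    p <- withr::with_seed(300 + k, sample_cell_params("tuned", "t"))
    tr <- simulate_cell(p, stim, seed = 310 + k)
    colour_accuracy(tr, stim, "ln")$accuracy -
      colour_accuracy(tr, stim, "first_spike")$accuracy
  }, 0)
  expect_lt(abs(mean(gaps)), 0.05)
})

test_that("error contributions by intensity window behave as distributions", {
  expect_true(all(error_by_intensity(rep(TRUE, 10), runif(10, 0.1, 0.6),
                                     rep(1:2, 5)) == 0))
  one <- error_by_intensity(c(FALSE, TRUE), c(0.1, 0.6), c(1L, 1L),
                            n_windows = 4, intensity_range = c(0.07, 0.7))
  expect_equal(sum(one[, "red"]), 1)
  expect_equal(unname(one[1, "red"]), 1)   # the error sits in the lowest bin
  # intensity-independent errors spread uniformly within multinomial noise
  set.seed(77)
  n <- 4000
  contrib <- error_by_intensity(runif(n) > 0.5, runif(n, 0.07, 0.7),
                                rep(1L, n), n_windows = 5,
                                intensity_range = c(0.07, 0.7))[, "red"]
  expect_true(all(abs(contrib - 0.2) < 4 * sqrt(0.2 * 0.8 / (n / 2))))
})

test_that("train and test halves are disjoint and accuracy is test-half only", {
  stim <- fix_stimulus()
  acc <- colour_accuracy(fix_tuned()$train, stim, "ln")
  n <- nrow(stim$flashes)
  expect_equal(acc$test_idx, (floor(n / 2) + 1):n)
  expect_equal(length(acc$predicted), n - floor(n / 2))
})
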