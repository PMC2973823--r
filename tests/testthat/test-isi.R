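# Interspike-interval Bayesian stimulus classification

test_that("ISIs are assigned to stimulus conditions by their second spike", {
  fl <- data.frame(onset = c(1000, 3000), colour = c("red", "green"),
                   intensity = c(0.3, 0.3))
  stim <- rgcdecode:::new_stimulus_sequence(fl, 66, 10000)
  # second spikes at 1100 (within 216 of red onset), 3100 (green), 3500 (black)
  train <- c(900, 1100, 3100, 3500)
  dist <- build_isi_joint(train, stim)
  expect_equal(sum(dist$joint), 1)
  expect_equal(unname(dist$prior[c("red", "green", "black")]),
               c(1, 1, 1) / 3)
  # conditionals normalised where defined
  expect_true(all(abs(colSums(dist$conditional)[dist$prior > 0] - 1) < 1e-12))
  expect_error(build_isi_joint(c(5), stim), "2 spikes")
})

test_that("ML classification equals brute-force per-bin argmax with the fixed tie-break", {
  stim <- fix_stimulus()
  train <- fix_tuned()$train
  dist <- build_isi_joint(train, stim)
  mids <- head(dist$edges, -1) + dist$isi_bin / 2
  got <- ml_classify(dist, mids)
  brute <- vapply(seq_along(mids), function(k) {
    p <- dist$conditional[k, c("black", "green", "red")]
    names(p)[which.max(p)]          # scan order = tie-break black>green>red
  }, "")
  expect_equal(got, brute)
})

test_that("MAP equals ML under a uniform prior and collapses to black under a rare-flash prior", {
  stim <- fix_stimulus()
  dist <- build_isi_joint(fix_tuned()$train, stim)
  mids <- head(dist$edges, -1) + dist$isi_bin / 2
  expect_equal(map_classify(dist, mids, prior = c(1, 1, 1) / 3),
               ml_classify(dist, mids))
  # flashes occupy ~66/1600 of the time: stimulus presence is rare
  rare <- c(red = 0.02, green = 0.02, black = 0.96)
  maps <- map_classify(dist, mids, prior = rare)
  expect_gte(mean(maps == "black"), 0.95)
  # ML, by contrast, classifies a nontrivial share of bins as coloured
  expect_gt(mean(ml_classify(dist, mids) != "black"), 0.1)
})

test_that("posterior equals the Bayes-rule computation from joint and prior", {
  stim <- fix_stimulus()
  dist <- build_isi_joint(fix_tuned()$train, stim)
  post <- isi_posterior(dist)
  direct <- dist$joint / rowSums(dist$joint)
  ok <- rowSums(dist$joint) > 0
  expect_equal(post[ok, ], direct[ok, ], tolerance = 1e-12)
  rs <- rowSums(post[ok, ])
  expect_true(all(abs(rs - 1) < 1e-12))
})

test_that("false-alarm interval closed form and edge cases", {
  expect_equal(false_alarm_interval(6, 0.5), 1000 / 3)
  expect_equal(false_alarm_interval(6, 0.1), 5000 / 3)
  expect_equal(false_alarm_interval(10, 0), Inf)
  expect_error(false_alarm_interval(0, 0.5), "> 0")
})

test_that("empirical ML false-alarm interval on a baseline train matches the analytic value", {
  # 6 Hz Poisson, no stimulus; a synthetic distribution classifies ISIs in
  # [100, 400) ms as coloured. Analytic confusable fraction of Exp(6 Hz):
  p_conf <- exp(-0.006 * 100) - exp(-0.006 * 400)
  stim <- generate_stimulus(0)
  stim$total_duration <- 400000     # 400 s of black screen
  p <- cell_params("c", baseline_rate = 6, gain = c(red = 0, green = 0))
  train <- simulate_cell(p, stim, seed = 17)
  edges <- seq(0, 1000, 25)
  nb <- length(edges) - 1
  cond <- matrix(0, nb, 3, dimnames = list(NULL, c("red", "green", "black")))
  conf <- edges[-length(edges)] >= 100 & edges[-length(edges)] < 400
  cond[conf, "red"] <- 1 / sum(conf)
  cond[!conf, "black"] <- 1 / sum(!conf)
  dist <- structure(list(joint = cond / 3, conditional = cond,
                         prior = c(red = 1, green = 1, black = 1) / 3,
                         edges = edges, isi_bin = 25, assign_window = 216),
                    class = "isi_joint_distribution")
  lab <- suppressWarnings(ml_classify(dist, diff(train)))
  n_fa <- sum(lab != "black")
  interval <- stim$total_duration / n_fa
  analytic <- false_alarm_interval(6, p_conf)
  expect_lt(abs(interval - analytic) / analytic, 4 / sqrt(n_fa))
})

test_that("classification is insensitive to the assignment window once it covers the response", {
  # windows shorter than the red response latency necessarily relabel the
  # red-evoked ISI mass, so robustness is expected (and tested) for
  # assignment windows spanning the full evoked burst (~250 ms and beyond
  # for the simulated tuned cells)
  stim <- fix_stimulus()
  train <- fix_tuned()$train
  isis <- pmin(diff(train), 999)
  rates <- vapply(c(250, 300, 350), function(w) {
    d <- build_isi_joint(train, stim, assign_window = w)
    mean(ml_classify(d, isis) != "black")
  }, 0)
  expect_lt(max(rates) - min(rates), 0.05)
})

test_that("out-of-range ISIs are clamped with a warning", {
  stim <- fix_stimulus()
  dist <- build_isi_joint(fix_tuned()$train, stim)
  expect_warning(ml_classify(dist, 5000), "clamped")
})
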