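#' Fit the population linear-nonlinear onset detector
#'
#' The linear stage reconstructs the binary stimulus indicator (1 = flash,
#' 0 = black screen) on the overlapping-window grid from the joint lagged
#' spike counts of all cells:
#' `s_hat(t) = sum_i sum_tau h_i(tau) x_i(t + tau) + C`.
#' The estimator at window `t` is anticausal in the response: it reads the
#' counts from time `t` to `t + T` (filter length `T`, default 250 ms), so a
#' detection at time `t` uses spikes up to `t + T`. Filters and constant
#' minimise the squared indicator error; the threshold minimises the count
#' of misclassified windows on the training data, treating false hits and
#' false detections equally.
#'
#' @param recording A `population_recording` (the training segment).
#' @param cell_subset Optional character vector of cell ids to use.
#' @param filter_length Filter length `T` in ms (default 250; the combined
#'   causal readout uses 125).
#' @param window_length,overlap Window grid (default 25 ms, 50% overlap).
#' @param lambda Ridge penalty (default 1e-6).
#' @return An `onset_ln_decoder`: `filters` (cells x lags), `constant`,
#'   `threshold`, `cell_ids`, grid parameters.
#' @export
fit_onset_ln <- function(recording, cell_subset = NULL, filter_length = 250,
                         window_length = 25, overlap = 0.5, lambda = 1e-6) {
  stopifnot(inherits(recording, "population_recording"))
  if (!is.null(cell_subset)) {
    if (length(cell_subset) == 0) stop("empty cell subset")
    recording <- subset_cells(recording, cell_subset)
  }
  if (nrow(recording$stimulus$flashes) == 0)
    stop("no events: recording contains no flashes to learn from")
  binned <- bin_response(recording, window_length, overlap)
  s <- indicator_from_stimulus(recording$stimulus, binned, "binary")
  X <- lagged_design(binned$counts, filter_length, binned$stride)
  tt <- seq_len(nrow(X))
  fit <- ls_ridge_fit(X, s[tt], lambda)
  th <- threshold_search(fit$fitted, s[tt] == 1)
  L <- ncol(X) / nrow(binned$counts)
  structure(list(filters = matrix(fit$w, nrow = nrow(binned$counts),
                                  ncol = L, byrow = TRUE,
                                  dimnames = list(binned$cell_ids, NULL)),
                 constant = fit$C, threshold = th$theta,
                 cell_ids = binned$cell_ids, filter_length = filter_length,
                 window_length = window_length, overlap = overlap,
                 train_errors = th$train_errors),
            class = "onset_ln_decoder")
}

# Anticausal lagged design: row t holds, for every cell, the counts at
# windows t .. t+L-1 (cell-major column order). L = filter_length / stride.
lagged_design <- function(counts, filter_length, stride) {
  L <- round(filter_length / stride)
  W <- ncol(counts)
  if (W < L) stop("recording too short for the filter length")
  n_t <- W - L + 1
  N <- nrow(counts)
  X <- matrix(0, n_t, N * L)
  for (i in seq_len(N)) {
    ci <- counts[i, ]
    for (tau in seq_len(L)) {
      X[, (i - 1) * L + tau] <- ci[tau:(tau + n_t - 1)]
    }
  }
  X
}

#' Linear output of the onset detector over a recording
#'
#' @param decoder An `onset_ln_decoder`.
#' @param recording A `population_recording` (must contain the decoder's
#'   cells).
#' @return List with `s_hat` (linear estimate per window) and `times`
#'   (window start times, ms).
#' @export
onset_linear_output <- function(decoder, recording) {
  stopifnot(inherits(decoder, "onset_ln_decoder"))
  recording <- subset_cells(recording, decoder$cell_ids)
  binned <- bin_response(recording, decoder$window_length, decoder$overlap)
  X <- lagged_design(binned$counts, decoder$filter_length, binned$stride)
  s_hat <- as.numeric(X %*% as.numeric(t(decoder$filters)) + decoder$constant)
  list(s_hat = s_hat, times = binned$window_starts[seq_along(s_hat)])
}

#' Detect stimulus onsets with a fitted detector
#'
#' The estimated onset time is the time `t` at which the linear output
#' first crosses the threshold (rising edge). While the output stays at or
#' above the threshold no further event is emitted; the detector re-arms
#' when the output falls below the threshold (one event per supra-threshold
#' excursion).
#'
#' @param decoder An `onset_ln_decoder` or `naive_detector`.
#' @param recording A `population_recording`.
#' @return Numeric vector of estimated onset times (ms), strictly
#'   increasing.
#' @export
detect_onsets <- function(decoder, recording) {
  out <- if (inherits(decoder, "onset_ln_decoder"))
    onset_linear_output(decoder, recording)
  else if (inherits(decoder, "naive_detector"))
    naive_linear_output(decoder, recording)
  else stop("unknown decoder class")
  above <- out$s_hat >= decoder$threshold
  rising <- above & !c(FALSE, above[-length(above)])
  out$times[rising]
}

#' Score detections against the true flash times
#'
#' Greedy nearest-neighbour matching within the tolerance: candidate
#' (detection, flash) pairs closer than `tolerance` are matched in order of
#' increasing distance, each detection and each flash used at most once.
#' A false positive is a detection more than `tolerance` ms from any
#' (unclaimed) true flash, normalised by the number of detected events; a
#' false negative is a true flash with no detection within `tolerance`,
#' normalised by the number of true events. The matching rule bounds every
#' matched timing error at `tolerance`.
#'
#' @param estimates Numeric vector of detected onset times (ms).
#' @param stimulus A `stimulus_sequence`.
#' @param tolerance Matching tolerance in ms (default 125).
#' @return A `detection_report`: `false_negative_rate`,
#'   `false_positive_rate`, `n_true`, `n_detected`, `tolerance`, and
#'   `matches` (data.frame `estimate`, `true_onset`, `colour`, `error`).
#' @export
score_detection <- function(estimates, stimulus, tolerance = 125) {
  stopifnot(inherits(stimulus, "stimulus_sequence"), tolerance > 0)
  onsets <- stimulus$flashes$onset
  n_true <- length(onsets)
  n_det <- length(estimates)
  pairs <- NULL
  if (n_det > 0 && n_true > 0) {
    # candidate pairs within tolerance (flashes are >= 1.1 s apart, so each
    # detection has at most one candidate flash, but stay general)
    cand <- do.call(rbind, lapply(seq_len(n_det), function(e) {
      d <- abs(onsets - estimates[e])
      j <- which(d <= tolerance)
      if (length(j)) cbind(e = e, f = j, d = d[j]) else NULL
    }))
    if (!is.null(cand)) {
      cand <- cand[order(cand[, "d"]), , drop = FALSE]
      used_e <- logical(n_det); used_f <- logical(n_true)
      keep <- logical(nrow(cand))
      for (r in seq_len(nrow(cand))) {
        e <- cand[r, "e"]; f <- cand[r, "f"]
        if (!used_e[e] && !used_f[f]) {
          used_e[e] <- used_f[f] <- keep[r] <- TRUE
        }
      }
      cand <- cand[keep, , drop = FALSE]
      if (nrow(cand))
        pairs <- data.frame(
          estimate = estimates[cand[, "e"]],
          true_onset = onsets[cand[, "f"]],
          colour = stimulus$flashes$colour[cand[, "f"]],
          error = estimates[cand[, "e"]] - onsets[cand[, "f"]])
    }
  }
  if (is.null(pairs))
    pairs <- data.frame(estimate = numeric(0), true_onset = numeric(0),
                        colour = character(0), error = numeric(0))
  n_match <- nrow(pairs)
  structure(list(
    false_negative_rate = if (n_true > 0) (n_true - n_match) / n_true else 0,
    false_positive_rate = if (n_det > 0) (n_det - n_match) / n_det else 0,
    n_true = n_true, n_detected = n_det, tolerance = tolerance,
    matches = pairs), class = "detection_report")
}

#' @export
print.detection_report <- function(x, ...) {
  cat(sprintf("Detection: FN %.1f%% (of %d true), FP %.1f%% (of %d detected), +/-%g ms\n",
              100 * x$false_negative_rate, x$n_true,
              100 * x$false_positive_rate, x$n_detected, x$tolerance))
  invisible(x)
}

#' Timing error of matched detections
#'
#' Over matched (detection, flash) pairs: `rms_error` is the
#' root-mean-square of the signed timing errors; `bias` is the mean
#' estimation error on red flashes minus the mean on green flashes — a
#' systematic colour-dependent offset that no uniform delay line could
#' remove (cells respond later to red, so the detector tends to place red
#' onsets late).
#'
#' @param matches Data frame with columns `error` (ms) and `colour`, as
#'   produced by [score_detection()].
#' @return A `timing_report`: `rms_error`, `bias`, `n_matched`, `empty`.
#' @export
timing_errors <- function(matches) {
  if (inherits(matches, "detection_report")) matches <- matches$matches
  n <- nrow(matches)
  if (n == 0)
    return(structure(list(rms_error = NA_real_, bias = NA_real_,
                          n_matched = 0L, empty = TRUE),
                     class = "timing_report"))
  rms <- sqrt(mean(matches$error^2))
  red <- matches$colour == "red"
  bias <- if (any(red) && any(!red))
    mean(matches$error[red]) - mean(matches$error[!red]) else NA_real_
  structure(list(rms_error = rms, bias = bias, n_matched = n, empty = FALSE),
            class = "timing_report")
}

#' @export
print.timing_report <- function(x, ...) {
  if (x$empty) cat("Timing: no matched detections\n")
  else cat(sprintf("Timing: RMS %.1f ms, red-green bias %.1f ms (n=%d)\n",
                   x$rms_error, x$bias, x$n_matched))
  invisible(x)
}

#' Fit a naive rate-code onset detector
#'
#' Rate-code baselines for the LN detector. Both read the population spike
#' count in a single sliding window of `window` ms (default 250, anticausal
#' like the LN estimator) with no temporal structure within the window:
#' unweighted sums counts over all cells; weighted fits one least-squares
#' weight per cell (noisy cells get smaller weights). In both cases the
#' threshold minimises misclassified windows on the training data.
#'
#' @param recording A `population_recording` (training segment).
#' @param window Count window in ms (default 250).
#' @param weighted Use per-cell least-squares weights? Default `FALSE`.
#' @param stride Grid stride in ms (default 12.5, matching the LN grid).
#' @param lambda Ridge penalty for the weighted fit.
#' @return A `naive_detector` with `weights`, `constant`, `threshold`.
#' @export
naive_rate_detector <- function(recording, window = 250, weighted = FALSE,
                                stride = 12.5, lambda = 1e-6) {
  stopifnot(inherits(recording, "population_recording"), window > 0)
  if (nrow(recording$stimulus$flashes) == 0)
    stop("no events: recording contains no flashes to learn from")
  b <- bin_response(recording, window_length = window,
                    overlap = 1 - stride / window)
  s <- flash_at_window_start(recording$stimulus, b)
  if (weighted) {
    fit <- ls_ridge_fit(t(b$counts), s, lambda)
    w <- fit$w; C <- fit$C; s_hat <- fit$fitted
  } else {
    w <- rep(1, nrow(b$counts)); C <- 0
    s_hat <- as.numeric(colSums(b$counts))
  }
  th <- threshold_search(s_hat, s == 1)
  structure(list(weights = stats::setNames(w, b$cell_ids), constant = C,
                 threshold = th$theta, window = window, stride = stride,
                 weighted = weighted, cell_ids = b$cell_ids),
            class = "naive_detector")
}

# Binary target for the naive detectors: 1 iff a flash overlaps the 25 ms
# window starting at each grid time (same labelling as the LN grid).
flash_at_window_start <- function(stimulus, binned, probe = 25) {
  a <- binned$window_starts
  out <- numeric(length(a))
  fl <- stimulus$flashes
  for (j in seq_len(nrow(fl)))
    out[a < fl$onset[j] + stimulus$flash_duration & fl$onset[j] < a + probe] <- 1
  out
}

naive_linear_output <- function(decoder, recording) {
  recording <- subset_cells(recording, decoder$cell_ids)
  b <- bin_response(recording, window_length = decoder$window,
                    overlap = 1 - decoder$stride / decoder$window)
  s_hat <- as.numeric(crossprod(b$counts, decoder$weights) + decoder$constant)
  list(s_hat = s_hat, times = b$window_starts)
}

#' Train/test evaluation of an onset detector
#'
#' Fits nothing: applies a fitted detector to a (test) recording and scores
#' detection and timing.
#'
#' @param decoder A fitted `onset_ln_decoder` or `naive_detector`.
#' @param recording The evaluation `population_recording`.
#' @param tolerance Matching tolerance (ms).
#' @return List with `detection` ([score_detection()] report) and `timing`
#'   ([timing_errors()] report).
#' @export
evaluate_detector <- function(decoder, recording, tolerance = 125) {
  est <- detect_onsets(decoder, recording)
  det <- score_detection(est, recording$stimulus, tolerance)
  list(detection = det, timing = timing_errors(det))
}

#' Detection accuracy versus population size
#'
#' For each population size, draws `n_subgroups` random cell subsets
#' (seeded), fits the detector on the training half, evaluates on the test
#' half, and averages the detection and timing statistics across subgroups.
#'
#' @param recording A full `population_recording` (will be split in half).
#' @param sizes Integer vector of population sizes (each <= number of
#'   cells).
#' @param n_subgroups Random subgroups per size (default 50).
#' @param detector_factory Function `(train_recording, cell_ids) ->
#'   detector`; defaults to the LN detector with `filter_length`.
#' @param filter_length LN filter length for the default factory (ms).
#' @param tolerance Matching tolerance (ms).
#' @param seed Seed for subgroup sampling.
#' @return Data frame, one row per size: mean FN, FP, RMS, bias.
#' @export
population_size_sweep <- function(recording, sizes, n_subgroups = 50,
                                  detector_factory = NULL,
                                  filter_length = 250, tolerance = 125,
                                  seed = 1L) {
  stopifnot(inherits(recording, "population_recording"))
  n_cells <- length(recording$cell_ids)
  if (any(sizes > n_cells)) stop("size exceeds population")
  if (is.null(detector_factory))
    detector_factory <- function(train, ids)
      fit_onset_ln(train, cell_subset = ids, filter_length = filter_length)
  halves <- split_recording(recording)
  subsets <- withr::with_seed(seed, {
    lapply(sizes, function(sz)
      lapply(seq_len(n_subgroups), function(k)
        sample(recording$cell_ids, sz)))
  })
  rows <- lapply(seq_along(sizes), function(si) {
    res <- lapply(subsets[[si]], function(ids) {
      dec <- detector_factory(halves$train, ids)
      evaluate_detector(dec, halves$test, tolerance)
    })
    data.frame(
      size = sizes[si],
      false_negative_rate = mean(vapply(res, function(r)
        r$detection$false_negative_rate, 0)),
      false_positive_rate = mean(vapply(res, function(r)
        r$detection$false_positive_rate, 0)),
      rms_error = mean(vapply(res, function(r)
        r$timing$rms_error, 0), na.rm = TRUE),
      bias = mean(vapply(res, function(r) r$timing$bias, 0), na.rm = TRUE),
      abs_bias = mean(vapply(res, function(r) abs(r$timing$bias), 0),
                      na.rm = TRUE))
  })
  do.call(rbind, rows)
}
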