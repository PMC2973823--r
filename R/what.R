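#' Build single-cell colour trials aligned to stimulus onsets
#'
#' For each flash, extracts the cell's spike counts in overlapping windows
#' spanning `filter_length` ms from the alignment time (the true onset by
#' default, or externally supplied estimated onsets for the causal combined
#' readout). The result is the trial-by-lag count matrix the colour
#' readouts consume.
#'
#' @param train Numeric spike-time vector of one cell.
#' @param stimulus A `stimulus_sequence`.
#' @param filter_length Filter span in ms (default 375).
#' @param onsets Optional alignment times (ms), one per flash; defaults to
#'   the true flash onsets.
#' @param window_length,overlap Window parameters (default 25 ms, 50%).
#' @return A `colour_trials` object: list with `X` (trials x lags counts),
#'   `colour` (1 = red, 2 = green), `intensity`, `onset_used`.
#' @export
colour_trials <- function(train, stimulus, filter_length = 375,
                          onsets = NULL, window_length = 25, overlap = 0.5) {
  stopifnot(inherits(stimulus, "stimulus_sequence"))
  fl <- stimulus$flashes
  if (is.null(onsets)) onsets <- fl$onset
  if (length(onsets) != nrow(fl))
    stop("need one alignment time per flash")
  stride <- window_length * (1 - overlap)
  L <- round(filter_length / stride)
  starts <- outer(onsets, (seq_len(L) - 1) * stride, `+`)   # trials x lags
  s <- sort(train)
  nless <- function(x) findInterval(x, s, left.open = TRUE)
  X <- matrix(nless(starts + window_length) - nless(starts),
              nrow = nrow(fl), ncol = L)
  structure(list(X = X, colour = colour_code(fl$colour),
                 intensity = fl$intensity, onset_used = onsets,
                 window_length = window_length, overlap = overlap,
                 filter_length = filter_length),
            class = "colour_trials")
}

#' Fit the linear-nonlinear colour decoder for one cell
#'
#' The linear stage estimates the colour code (1 = red, 2 = green) as
#' `s_hat = sum_tau h(tau) x(tau) + C`, with the filter `h` and constant `C`
#' chosen to minimise the squared error `sum_n (s_n - s_hat_n)^2` over
#' trials (ridge-stabilised normal equations). The nonlinearity is a
#' threshold `theta` chosen to minimise the misclassification count on the
#' fitting set; on balanced data the optimal threshold sits very close to
#' 1.5, midway between the two colour codes.
#'
#' @param trials A [colour_trials()] object (the training trials).
#' @param lambda Ridge penalty on the Gram matrix (default 1e-6).
#' @return A `colour_ln_decoder`: `filter`, `constant`, `threshold`, plus
#'   the window geometry.
#' @export
fit_colour_ln <- function(trials, lambda = 1e-6) {
  stopifnot(inherits(trials, "colour_trials"))
  if (sum(trials$colour == 1) < 1 || sum(trials$colour == 2) < 1)
    stop("need trials of both colours")
  fit <- ls_ridge_fit(trials$X, trials$colour, lambda)
  th <- threshold_search(fit$fitted, trials$colour == 2)
  structure(list(filter = fit$w, constant = fit$C, threshold = th$theta,
                 filter_length = trials$filter_length,
                 window_length = trials$window_length,
                 overlap = trials$overlap,
                 train_errors = th$train_errors,
                 n_train = nrow(trials$X)),
            class = "colour_ln_decoder")
}

#' Linear output of the colour decoder
#' @param decoder A `colour_ln_decoder`.
#' @param trials A [colour_trials()] object.
#' @return Numeric vector of linear estimates, one per trial.
#' @export
colour_linear_output <- function(decoder, trials) {
  stopifnot(inherits(decoder, "colour_ln_decoder"),
            inherits(trials, "colour_trials"))
  if (ncol(trials$X) != length(decoder$filter))
    stop("trial response length does not match the filter")
  as.numeric(trials$X %*% decoder$filter + decoder$constant)
}

#' Classify trial colour with the LN decoder
#'
#' Predicts green (2) iff the linear output is at or above the threshold,
#' red (1) otherwise (ties go to green).
#'
#' @inheritParams colour_linear_output
#' @return Integer labels (1 = red, 2 = green).
#' @export
predict_colour <- function(decoder, trials) {
  s_hat <- colour_linear_output(decoder, trials)
  ifelse(s_hat >= decoder$threshold, 2L, 1L)
}

#' First-spike latencies after each alignment time
#'
#' @param train Spike-time vector.
#' @param onsets Alignment times (ms).
#' @param window Analysis window after each alignment (ms, default 375).
#' @return Numeric vector of latencies; `NA` where no spike fell in the
#'   window.
#' @export
first_spike_latencies <- function(train, onsets, window = 375) {
  s <- sort(train)
  idx <- findInterval(onsets, s, left.open = TRUE) + 1  # first spike >= onset
  lat <- ifelse(idx <= length(s), s[idx] - onsets, NA_real_)
  ifelse(!is.na(lat) & lat < window, lat, NA_real_)
}

#' Fit the first-spike-latency colour decoder
#'
#' Estimates the joint probability of (first-spike latency bin, colour) on
#' training trials; classification is maximum likelihood over the
#' per-colour conditional histograms. Trials with no spike in the analysis
#' window form their own "none" bin and are classified by a fixed fallback
#' label rather than dropped, so accuracy denominators match trial counts.
#'
#' @param latency Numeric latencies (ms), `NA` = no spike in window.
#' @param colour Integer labels (1 = red, 2 = green).
#' @param latency_bin Bin width in ms (default 10).
#' @param window Analysis window length (ms, default 375).
#' @param no_spike_rule Label returned for no-spike trials (default 1, red:
#'   the lower-rate class).
#' @return A `first_spike_decoder` with the joint table and normalised
#'   conditionals.
#' @export
fit_first_spike <- function(latency, colour, latency_bin = 10, window = 375,
                            no_spike_rule = 1L) {
  stopifnot(length(latency) == length(colour))
  if (sum(colour == 1) < 1 || sum(colour == 2) < 1)
    stop("need at least one trial per colour")
  edges <- seq(0, window, by = latency_bin)
  if (edges[length(edges)] < window) edges <- c(edges, window)
  nb <- length(edges) - 1
  bin_of <- function(lat) {
    b <- findInterval(lat, edges, rightmost.closed = TRUE)
    pmin(pmax(b, 1L), nb)
  }
  lev <- c(sprintf("bin%02d", seq_len(nb)), "none")
  bins <- ifelse(is.na(latency), nb + 1L, bin_of(latency))
  joint <- table(factor(lev[bins], levels = lev),
                 factor(colour, levels = 1:2))
  joint <- unclass(joint) / length(latency)
  cond <- sweep(joint, 2, colSums(joint), "/")
  structure(list(joint = joint, conditional = cond, edges = edges,
                 latency_bin = latency_bin, window = window,
                 no_spike_rule = as.integer(no_spike_rule),
                 bin_of = bin_of, n_bins = nb),
            class = "first_spike_decoder")
}

#' Maximum-likelihood colour from a first-spike latency
#'
#' Picks the colour with the larger conditional probability of the
#' latency's bin; ties go to green. No-spike trials (`NA`) get the
#' decoder's fallback label.
#'
#' @param decoder A `first_spike_decoder`.
#' @param latency Numeric latencies (ms), `NA` = no spike.
#' @return Integer labels (1 = red, 2 = green).
#' @export
predict_colour_first_spike <- function(decoder, latency) {
  stopifnot(inherits(decoder, "first_spike_decoder"))
  out <- integer(length(latency))
  none <- is.na(latency)
  out[none] <- decoder$no_spike_rule
  if (any(!none)) {
    b <- decoder$bin_of(latency[!none])
    p_red <- decoder$conditional[b, 1]
    p_green <- decoder$conditional[b, 2]
    out[!none] <- ifelse(p_green >= p_red, 2L, 1L)
  }
  out
}

#' Relative contribution of intensity windows to colour errors
#'
#' Splits the irradiance range into `n_windows` equal bins and reports, per
#' colour, each bin's share of the misclassified trials (a distribution
#' summing to 1 per colour, or all zeros when that colour has no errors).
#' A flat profile means stimulus intensity does not drive the errors.
#'
#' @param correct Logical per-trial correctness.
#' @param intensity Per-trial irradiance (uW/cm^2).
#' @param colour Per-trial labels (1 = red, 2 = green).
#' @param n_windows Number of intensity bins (default 5).
#' @param intensity_range Range to bin over; defaults to the data range.
#' @return Matrix `n_windows x 2` (columns red, green) of error shares.
#' @export
error_by_intensity <- function(correct, intensity, colour, n_windows = 5,
                               intensity_range = range(intensity)) {
  stopifnot(length(correct) == length(intensity),
            length(correct) == length(colour))
  edges <- seq(intensity_range[1], intensity_range[2],
               length.out = n_windows + 1)
  bin <- pmin(pmax(findInterval(intensity, edges, rightmost.closed = TRUE),
                   1L), n_windows)
  out <- matrix(0, n_windows, 2, dimnames = list(NULL, c("red", "green")))
  for (cc in 1:2) {
    err <- !correct & colour == cc
    if (any(err))
      out[, cc] <- tabulate(bin[err], nbins = n_windows) / sum(err)
  }
  out
}

#' Split-half colour-decoding accuracy of one cell
#'
#' The paper-style cross-validated single-cell "what" readout: trials are
#' split into a first (training) and second (test) half in time, the
#' decoder is fitted on the training half and accuracy is reported on the
#' held-out half only.
#'
#' @param train Spike-time vector of the cell.
#' @param stimulus A `stimulus_sequence`.
#' @param method `"ln"` (linear-nonlinear) or `"first_spike"`.
#' @param filter_length LN filter span / first-spike analysis window (ms).
#' @param onsets Optional alignment times (defaults to true onsets).
#' @param latency_bin First-spike histogram bin (ms).
#' @return List with `accuracy` (test half), `predicted`, `truth`,
#'   `test_idx`, `decoder`.
#' @export
colour_accuracy <- function(train, stimulus, method = c("ln", "first_spike"),
                            filter_length = 375, onsets = NULL,
                            latency_bin = 10) {
  method <- match.arg(method)
  n <- nrow(stimulus$flashes)
  if (n < 4) stop("need at least 4 trials")
  tr_idx <- seq_len(floor(n / 2))
  te_idx <- setdiff(seq_len(n), tr_idx)
  truth <- colour_code(stimulus$flashes$colour)
  if (method == "ln") {
    trials <- colour_trials(train, stimulus, filter_length, onsets)
    sub <- function(idx) {
      t2 <- trials
      t2$X <- trials$X[idx, , drop = FALSE]
      t2$colour <- trials$colour[idx]
      t2$intensity <- trials$intensity[idx]
      t2$onset_used <- trials$onset_used[idx]
      t2
    }
    dec <- fit_colour_ln(sub(tr_idx))
    pred <- predict_colour(dec, sub(te_idx))
  } else {
    al <- if (is.null(onsets)) stimulus$flashes$onset else onsets
    lat <- first_spike_latencies(train, al, window = filter_length)
    dec <- fit_first_spike(lat[tr_idx], truth[tr_idx],
                           latency_bin = latency_bin,
                           window = filter_length)
    pred <- predict_colour_first_spike(dec, lat[te_idx])
  }
  list(accuracy = mean(pred == truth[te_idx]), predicted = pred,
       truth = truth[te_idx], test_idx = te_idx, decoder = dec)
}
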