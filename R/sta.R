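#' Gaussian full-field colour flicker stimulus
#'
#' Frame-by-frame red and green intensities drawn independently from
#' Gaussian distributions, used to characterise cells by spike-triggered
#' averaging (and to classify them as ON or OFF).
#'
#' @param n_frames Number of frames.
#' @param frame_interval Frame duration in ms (default 33).
#' @param mean Mean intensity per channel (default 0.35 uW/cm^2, mid
#'   stimulus range).
#' @param sd Intensity standard deviation (default 0.1).
#' @param seed Integer seed.
#' @return A `flicker_stimulus`: `intensity` (frames x 2 matrix, columns
#'   red/green), `frame_interval`, `mean`, `sd`.
#' @export
flicker_stimulus <- function(n_frames, frame_interval = 33, mean = 0.35,
                             sd = 0.1, seed = 1L) {
  stopifnot(n_frames >= 1, frame_interval > 0, sd > 0)
  I <- withr::with_seed(seed, {
    matrix(stats::rnorm(2 * n_frames, mean, sd), ncol = 2,
           dimnames = list(NULL, c("red", "green")))
  })
  structure(list(intensity = I, frame_interval = frame_interval,
                 mean = mean, sd = sd,
                 duration = n_frames * frame_interval),
            class = "flicker_stimulus")
}

#' Simulate a cell's response to Gaussian flicker
#'
#' A linear-rate model for flicker: the luminance contrast (mean of the two
#' channels, standardised) is filtered by the cell's causal alpha kernel
#' and modulates the baseline rate multiplicatively, with sign set by the
#' cell's polarity — OFF cells fire more after intensity decrements, ON
#' cells after increments. Spikes are then drawn by Poisson thinning at
#' 1 ms resolution, as in [simulate_cell()].
#'
#' @param params A [cell_params()] (uses `baseline_rate`, `polarity`,
#'   `kernel_width`, `latency` for the response delay).
#' @param flicker A [flicker_stimulus()].
#' @param modulation Contrast-to-rate modulation depth (default 1.5).
#' @param seed Integer seed.
#' @return Sorted spike-time vector (ms).
#' @export
simulate_flicker_train <- function(params, flicker, modulation = 1.5,
                                   seed = 1L) {
  stopifnot(inherits(params, "cell_params"),
            inherits(flicker, "flicker_stimulus"))
  n_bins <- floor(flicker$duration)
  frame_of <- pmin(floor((seq_len(n_bins) - 0.5) / flicker$frame_interval) + 1,
                   nrow(flicker$intensity))
  contrast <- (rowMeans(flicker$intensity)[frame_of] - flicker$mean) /
    flicker$sd
  tau <- params$kernel_width
  span <- ceiling(10 * tau)
  u <- seq_len(span) - 0.5
  kern <- (u / tau^2) * exp(-u / tau)
  drive <- stats::filter(c(rep(0, span), contrast), rev(kern),
                         sides = 1)[-(seq_len(span))]
  drive[is.na(drive)] <- 0
  sgn <- if (params$polarity == "OFF") -1 else 1
  lag <- round(min(params$latency))
  drive <- c(rep(0, lag), drive)[seq_len(n_bins)]
  rate <- pmax(0, params$baseline_rate / 1000 *
                 (1 + sgn * modulation * drive))
  rmax <- max(rate)
  if (rmax <= 0) return(numeric(0))
  res <- withr::with_seed(seed, {
    n_cand <- stats::rpois(1, rmax * n_bins)
    if (n_cand == 0) {
      numeric(0)
    } else {
      cand <- sort(stats::runif(n_cand, 0, n_bins))
      keep <- stats::runif(n_cand) < rate[floor(cand) + 1] / rmax
      cand[keep]
    }
  })
  res
}

#' Spike-triggered average stimulus
#'
#' Mean of the flicker intensity trajectory preceding each spike, per
#' colour channel, on the frame grid. Spikes earlier than `window` ms into
#' the recording are dropped (their pre-spike window is incomplete).
#'
#' @param train Spike-time vector (ms).
#' @param flicker A [flicker_stimulus()].
#' @param window Averaging window before the spike (ms, default 300).
#' @param min_spikes Minimum usable spike count (default 50).
#' @return An `sta_result`: `sta` (lags x 2 matrix), `lags` (ms before the
#'   spike, negative to 0), `n_spikes`, `stim_mean`, `stim_sd`.
#' @export
spike_triggered_average <- function(train, flicker, window = 300,
                                    min_spikes = 50) {
  stopifnot(inherits(flicker, "flicker_stimulus"), window > 0)
  use <- train[train >= window & train < flicker$duration]
  if (length(use) < min_spikes)
    stop(sprintf("too few spikes for an STA: %d usable (need >= %d)",
                 length(use), min_spikes))
  dt <- flicker$frame_interval
  lags <- -rev(seq(0, window - dt, by = dt))        # ms before spike
  times <- outer(use, lags, `+`)                    # spikes x lags
  frame <- pmin(pmax(floor(times / dt) + 1, 1), nrow(flicker$intensity))
  sta <- vapply(c("red", "green"), function(ch) {
    colMeans(matrix(flicker$intensity[frame, ch], nrow = length(use)))
  }, numeric(length(lags)))
  structure(list(sta = sta, lags = lags, n_spikes = length(use),
                 stim_mean = flicker$mean, stim_sd = flicker$sd),
            class = "sta_result")
}

#' Classify response polarity from an STA
#'
#' Takes the largest-magnitude deflection of the STA from the stimulus mean
#' across lags and channels: a dip (stimulus darker than average before
#' spikes) marks an OFF cell, a peak an ON cell. Deflections smaller than
#' `n_se` standard errors of the STA are returned as `"unclassified"`.
#'
#' @param sta An `sta_result`.
#' @param n_se Significance multiple of the STA standard error (default 3).
#' @return `"ON"`, `"OFF"` or `"unclassified"`.
#' @export
classify_polarity <- function(sta, n_se = 3) {
  stopifnot(inherits(sta, "sta_result"))
  dev <- sta$sta - sta$stim_mean
  se <- sta$stim_sd / sqrt(sta$n_spikes)
  peak <- dev[which.max(abs(dev))]
  if (abs(peak) < n_se * se) return("unclassified")
  if (peak < 0) "OFF" else "ON"
}
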