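#' Firing-rate profile of a simulated cell (1 ms resolution)
#'
#' Builds the piecewise-constant intensity function of the inhomogeneous
#' Poisson model: baseline plus, for each flash, an alpha-kernel transient
#' `gain * k(t - onset - latency)` with `k(u) = (u/tau^2) exp(-u/tau)` (unit
#' area, so `gain` is the expected number of evoked spikes per flash).
#'
#' @param params A [cell_params()] object.
#' @param stimulus A [generate_stimulus()] sequence.
#' @return Numeric vector of rates in spikes/ms, one entry per 1 ms bin from
#'   time 0 to `stimulus$total_duration`.
#' @export
cell_rate_profile <- function(params, stimulus) {
  n_bins <- ceiling(stimulus$total_duration)
  rate <- rep(params$baseline_rate / 1000, n_bins)   # Hz -> spikes/ms
  fl <- stimulus$flashes
  if (nrow(fl) == 0 || n_bins == 0) return(rate)
  tau <- params$kernel_width
  span <- ceiling(10 * tau)                          # kernel support cutoff
  u <- seq_len(span) - 0.5                           # bin centres
  kern <- (u / tau^2) * exp(-u / tau)
  base_ms <- params$baseline_rate / 1000
  for (j in seq_len(nrow(fl))) {
    g <- flash_gain(params, fl$colour[j], fl$intensity[j])
    if (g <= 0) next                                 # no response, no pause
    lat <- flash_latency(params, fl$colour[j], fl$intensity[j])
    if (params$suppression > 0) {                    # pause before the burst
      s0 <- floor(fl$onset[j])
      s1 <- min(floor(fl$onset[j] + lat), n_bins)
      if (s1 > s0)
        rate[(s0 + 1):s1] <- rate[(s0 + 1):s1] -
          params$suppression * base_ms
    }
    start <- floor(fl$onset[j] + lat)                # first bin of transient
    if (start + 1 > n_bins) next
    idx <- (start + 1):min(start + span, n_bins)
    rate[idx] <- rate[idx] + g * kern[seq_along(idx)]
  }
  rate <- pmax(rate, 0)
  rate
}

#' Simulate one cell's spike train
#'
#' Draws spikes from the inhomogeneous Poisson process defined by
#' [cell_rate_profile()] using thinning: homogeneous candidates at the peak
#' rate, accepted with probability `rate(t)/rate_max`. The rate is piecewise
#' constant at 1 ms resolution; spike times are continuous. Deterministic
#' given `seed`.
#'
#' @inheritParams cell_rate_profile
#' @param seed Integer seed.
#' @return Sorted numeric vector of spike times (ms) in
#'   `[0, total_duration)`.
#' @export
simulate_cell <- function(params, stimulus, seed = 1L) {
  stopifnot(inherits(params, "cell_params"),
            inherits(stimulus, "stimulus_sequence"))
  rate <- cell_rate_profile(params, stimulus)
  dur <- length(rate)
  rmax <- max(rate)
  if (dur == 0 || rmax <= 0) return(numeric(0))
  res <- withr::with_seed(seed, {
    n_cand <- stats::rpois(1, rmax * dur)
    if (n_cand == 0) {
      numeric(0)
    } else {
      cand <- sort(stats::runif(n_cand, 0, dur))
      keep <- stats::runif(n_cand) < rate[floor(cand) + 1] / rmax
      cand[keep]
    }
  })
  res
}

#' Simulate a heterogeneous population recording
#'
#' Allocates cells to selectivity classes by the largest-remainder rule,
#' draws each cell's ground-truth parameters, and simulates every spike
#' train against the shared stimulus. Fully reproducible: the same spec and
#' stimulus give byte-identical recordings.
#'
#' @param spec A [population_spec()].
#' @param stimulus A [generate_stimulus()] sequence.
#' @return A `population_recording`: list with `stimulus`, `trains` (named
#'   list of spike-time vectors), `cell_params` (named list of
#'   [cell_params()]) and `cell_ids`.
#' @export
generate_population <- function(spec, stimulus) {
  stopifnot(inherits(spec, "population_spec"),
            inherits(stimulus, "stimulus_sequence"))
  counts <- class_counts(spec)
  classes <- rep(names(counts), counts)
  ids <- sprintf("cell%03d", seq_along(classes))
  params <- withr::with_seed(spec$seed, {
    lapply(seq_along(classes), function(i)
      sample_cell_params(classes[i], ids[i]))
  })
  trains <- lapply(seq_along(params), function(i)
    simulate_cell(params[[i]], stimulus,
                  seed = (spec$seed * 1009L + i) %% 2147483629L))
  names(trains) <- ids
  names(params) <- ids
  structure(list(stimulus = stimulus, trains = trains,
                 cell_params = params, cell_ids = ids),
            class = "population_recording")
}

#' @export
print.population_recording <- function(x, ...) {
  cls <- vapply(x$cell_params, function(p) p$selectivity_class, "")
  cat(sprintf("Population recording: %d cells, %d flashes, %.1f s\n",
              length(x$trains), nrow(x$stimulus$flashes),
              x$stimulus$total_duration / 1000))
  if (length(cls))
    cat("  classes:", paste(names(table(cls)), table(cls), sep = "=",
                            collapse = ", "), "\n")
  invisible(x)
}

#' Restrict a recording to a subset of cells
#'
#' @param recording A `population_recording`.
#' @param cell_ids Character vector of cell ids to keep.
#' @return A `population_recording` with only those cells.
#' @export
subset_cells <- function(recording, cell_ids) {
  stopifnot(inherits(recording, "population_recording"))
  missing <- setdiff(cell_ids, recording$cell_ids)
  if (length(missing)) stop("unknown cell ids: ", paste(missing, collapse = ", "))
  structure(list(stimulus = recording$stimulus,
                 trains = recording$trains[cell_ids],
                 cell_params = recording$cell_params[cell_ids],
                 cell_ids = cell_ids),
            class = "population_recording")
}

#' Split a recording into training and test halves by time
#'
#' Cross-validation follows the two-segment scheme: decoder parameters are
#' learnt on one temporal half of the recording and evaluated on the other.
#' The split point is the midpoint between the last training flash's offset
#' and the first test flash's onset, so no flash straddles the boundary.
#'
#' @param recording A `population_recording`.
#' @return List with `train` and `test`, each a `population_recording` whose
#'   stimulus times are re-zeroed to the segment start, plus `split_ms`.
#' @export
split_recording <- function(recording) {
  stim <- recording$stimulus
  n <- nrow(stim$flashes)
  if (n < 2) stop("need at least 2 flashes to split")
  h <- floor(n / 2)
  cut <- (stim$flashes$onset[h] + stim$flash_duration +
          stim$flashes$onset[h + 1]) / 2
  take <- function(lo, hi) {
    fl <- stim$flashes[stim$flashes$onset >= lo & stim$flashes$onset < hi, ,
                       drop = FALSE]
    fl$onset <- fl$onset - lo
    sub <- new_stimulus_sequence(fl, stim$flash_duration, hi - lo)
    trains <- lapply(recording$trains, function(tt) tt[tt >= lo & tt < hi] - lo)
    structure(list(stimulus = sub, trains = trains,
                   cell_params = recording$cell_params,
                   cell_ids = recording$cell_ids),
              class = "population_recording")
  }
  list(train = take(0, cut),
       test = take(cut, stim$total_duration),
       split_ms = cut)
}
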