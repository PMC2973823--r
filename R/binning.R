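#' Overlapping-window spike count representation
#'
#' All linear readouts operate on spike counts in overlapping boxcar
#' windows: by default 25 ms windows with 50% overlap (12.5 ms stride).
#' Window `t` covers the half-open interval
#' `[start_time + (t-1)*stride, start_time + (t-1)*stride + window_length)`,
#' so a spike interior to the grid is counted in exactly two windows at the
#' default overlap. Spikes exactly on a window's right edge belong to the
#' next window.
#'
#' @param train A numeric vector of spike times (one cell) or a
#'   `population_recording`.
#' @param window_length Window length in ms (> 0). Default 25.
#' @param overlap Fractional overlap in `[0, 1)`. Default 0.5.
#' @param epoch Length-2 numeric `(start, end)` in ms; windows are laid out
#'   from `start` and only windows fully inside the epoch are kept. Defaults
#'   to the recording duration (or the spike range for a bare train).
#'
#' @return A `binned_response`: list with `counts` (cells x windows integer
#'   matrix), `window_starts`, `window_length`, `stride`, `start_time`,
#'   `cell_ids`.
#' @export
#' @examples
#' b <- bin_response(c(30), epoch = c(0, 100))
#' which(b$counts[1, ] > 0)   # windows [12.5,37.5) and [25,50)
bin_response <- function(train, window_length = 25, overlap = 0.5,
                         epoch = NULL) {
  if (window_length <= 0) stop("window_length must be > 0")
  if (overlap < 0 || overlap >= 1) stop("overlap must be in [0, 1)")
  if (inherits(train, "population_recording")) {
    trains <- train$trains
    if (is.null(epoch)) epoch <- c(0, train$stimulus$total_duration)
  } else {
    trains <- list(cell1 = as.numeric(train))
    if (is.null(epoch))
      epoch <- c(0, if (length(train)) max(train) + window_length else window_length)
  }
  if (length(epoch) != 2 || epoch[1] >= epoch[2])
    stop("epoch must be (start, end) with start < end")
  allsp <- unlist(trains, use.names = FALSE)
  if (length(allsp) && (min(allsp) < epoch[1] - 1e-9))
    stop("epoch outside recording: spikes before epoch start")
  stride <- window_length * (1 - overlap)
  n_win <- floor((epoch[2] - epoch[1] - window_length) / stride) + 1
  if (n_win < 1) stop("epoch too short for a single window")
  starts <- epoch[1] + (seq_len(n_win) - 1) * stride
  counts <- t(vapply(trains, function(s) {
    s <- sort(s)
    nless <- function(x) findInterval(x, s, left.open = TRUE)
    as.integer(nless(starts + window_length) - nless(starts))
  }, integer(n_win)))
  structure(list(counts = counts, window_starts = starts,
                 window_length = window_length, stride = stride,
                 start_time = epoch[1], cell_ids = names(trains)),
            class = "binned_response")
}

#' Stimulus indicator on a window grid
#'
#' Projects a stimulus sequence onto a binned response's window grid.
#' Binary coding marks a window 1 if its interval overlaps (even partially)
#' any flash interval `[onset, onset + flash_duration)`, 0 otherwise; this
#' is the target the onset detector is trained to reconstruct. Colour
#' coding instead marks overlapping windows with the flash's colour code
#' (1 = red, 2 = green) and 0 elsewhere.
#'
#' @param stimulus A `stimulus_sequence`.
#' @param binned A `binned_response` supplying the window grid.
#' @param coding `"binary"` or `"colour"`.
#' @return Numeric vector over windows.
#' @export
indicator_from_stimulus <- function(stimulus, binned,
                                    coding = c("binary", "colour")) {
  coding <- match.arg(coding)
  stopifnot(inherits(stimulus, "stimulus_sequence"),
            inherits(binned, "binned_response"))
  a <- binned$window_starts
  b <- a + binned$window_length
  out <- numeric(length(a))
  fl <- stimulus$flashes
  for (j in seq_len(nrow(fl))) {
    hit <- a < fl$onset[j] + stimulus$flash_duration & fl$onset[j] < b
    out[hit] <- if (coding == "binary") 1 else colour_code(fl$colour[j])
  }
  out
}
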