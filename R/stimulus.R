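#' Construct a flash stimulus sequence
#'
#' A stimulus sequence is an ordered set of brief full-field coloured flashes
#' on a black background: each flash has an onset time (ms), a colour
#' (`"red"` or `"green"`) and an irradiance (uW/cm^2). The defaults emulate
#' the two-alternative colour task: 66 ms flashes, colours drawn with equal
#' probability, intensities uniform on 0.07-0.7 uW/cm^2 and inter-flash
#' onset-to-onset gaps i.i.d. uniform on 1.1-2.1 s (aperiodic, to avoid
#' phase-locking the retinal dynamics).
#'
#' @param n_flashes Number of flashes (>= 0).
#' @param interflash_range Length-2 numeric, uniform range of onset-to-onset
#'   gaps in ms. Default `c(1100, 2100)`.
#' @param flash_duration Flash duration in ms. Default 66.
#' @param intensity_range Length-2 numeric, uniform irradiance range in
#'   uW/cm^2. Default `c(0.07, 0.7)`.
#' @param seed Integer seed; the sequence is reproducible given the seed.
#'
#' @return A `stimulus_sequence`: list with `flashes` (data.frame with
#'   columns `onset`, `colour`, `intensity`), `flash_duration` and
#'   `total_duration` (ms).
#' @export
#' @examples
#' stim <- generate_stimulus(10, seed = 1)
#' diff(stim$flashes$onset)   # all gaps within [1100, 2100]
generate_stimulus <- function(n_flashes,
                              interflash_range = c(1100, 2100),
                              flash_duration = 66,
                              intensity_range = c(0.07, 0.7),
                              seed = 1L) {
  if (length(interflash_range) != 2 || interflash_range[1] >= interflash_range[2])
    stop("interflash_range must satisfy low < high")
  if (length(intensity_range) != 2 || intensity_range[1] >= intensity_range[2])
    stop("intensity_range must satisfy low < high")
  if (n_flashes < 0) stop("n_flashes must be >= 0")
  if (n_flashes == 0) {
    flashes <- data.frame(onset = numeric(0), colour = character(0),
                          intensity = numeric(0), stringsAsFactors = FALSE)
    return(new_stimulus_sequence(flashes, flash_duration, total_duration = 0))
  }
  withr::with_seed(seed, {
    gaps <- stats::runif(n_flashes, interflash_range[1], interflash_range[2])
    onsets <- cumsum(gaps)                     # first flash after one gap
    colour <- ifelse(stats::runif(n_flashes) < 0.5, "red", "green")
    intensity <- stats::runif(n_flashes, intensity_range[1], intensity_range[2])
  })
  flashes <- data.frame(onset = onsets, colour = colour, intensity = intensity,
                        stringsAsFactors = FALSE)
  total <- onsets[n_flashes] + flash_duration +
    mean(interflash_range)                    # tail margin after last flash
  new_stimulus_sequence(flashes, flash_duration, total)
}

new_stimulus_sequence <- function(flashes, flash_duration, total_duration) {
  stopifnot(is.data.frame(flashes),
            all(c("onset", "colour", "intensity") %in% names(flashes)))
  if (is.unsorted(flashes$onset)) stop("flashes must be sorted by onset")
  if (any(flashes$onset < 0)) stop("flash onsets must be >= 0")
  if (!all(flashes$colour %in% c("red", "green")))
    stop("colour must be 'red' or 'green'")
  if (nrow(flashes) > 1 &&
      any(diff(flashes$onset) < flash_duration))
    stop("overlapping flashes: onsets closer than flash_duration")
  if (nrow(flashes) > 0 &&
      flashes$onset[nrow(flashes)] + flash_duration > total_duration)
    stop("last flash offset exceeds total_duration")
  structure(list(flashes = flashes, flash_duration = flash_duration,
                 total_duration = total_duration),
            class = "stimulus_sequence")
}

#' @export
print.stimulus_sequence <- function(x, ...) {
  cat(sprintf("Stimulus sequence: %d flashes of %g ms over %.1f s\n",
              nrow(x$flashes), x$flash_duration, x$total_duration / 1000))
  if (nrow(x$flashes) > 0) {
    tab <- table(x$flashes$colour)
    cat("  colours:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Numeric colour code used by the colour decoders
#'
#' Colour labels are coded 1 for red and 2 for green throughout the colour
#' readouts.
#'
#' @param colour Character vector of `"red"` / `"green"` labels.
#' @return Integer vector of 1s and 2s.
#' @export
colour_code <- function(colour) {
  if (!all(colour %in% c("red", "green"))) stop("unknown colour label")
  ifelse(colour == "red", 1L, 2L)
}
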