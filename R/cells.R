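#' Ground-truth response parameters of a simulated ganglion cell
#'
#' Each simulated cell fires as an inhomogeneous Poisson process: a constant
#' baseline rate plus, for every flash, a transient described by a causal
#' alpha-function kernel scaled to deliver `gain` extra spikes per flash and
#' delayed by a colour- and intensity-dependent latency. Gain and latency
#' vary affinely in log10 irradiance around a reference irradiance, so
#' brighter flashes give stronger and earlier responses (the latency slope
#' is typically steeper for red).
#'
#' @param cell_id Cell identifier (character or integer).
#' @param baseline_rate Spontaneous firing rate in Hz (>= 0).
#' @param polarity `"ON"` or `"OFF"`.
#' @param gain Named numeric `c(red=, green=)`: mean evoked spikes per flash
#'   at the reference irradiance (>= 0).
#' @param latency Named numeric `c(red=, green=)`: response latency in ms at
#'   the reference irradiance (> 0).
#' @param kernel_width Time constant tau (ms) of the alpha kernel
#'   `k(u) = (u / tau^2) exp(-u / tau)`, which has unit area and peaks at tau.
#' @param gain_slope Named numeric `c(red=, green=)`: spikes per flash added
#'   per decade of irradiance.
#' @param latency_slope Named numeric `c(red=, green=)`: ms added to the
#'   latency per decade of irradiance (negative = earlier when brighter).
#' @param intensity_ref Reference irradiance (uW/cm^2); default 0.22, the
#'   geometric midpoint of the 0.07-0.7 stimulus range.
#' @param suppression Fraction of the baseline rate suppressed between a
#'   flash's onset and the evoked transient (default 0). Flash responses of
#'   OFF retinal ganglion cells typically pause the maintained discharge
#'   before the burst, which is what gives the first-spike latency its
#'   clean colour boundary; the suppression only accompanies flashes the
#'   cell actually responds to (evoked gain > 0).
#' @param selectivity_class One of `"tuned"`, `"weak"`, `"green_only"`,
#'   `"untuned"`; bookkeeping label, not used by the simulator itself.
#'
#' @return A `cell_params` object.
#' @export
cell_params <- function(cell_id, baseline_rate, polarity = c("OFF", "ON"),
                        gain = c(red = 0, green = 0),
                        latency = c(red = 80, green = 80),
                        kernel_width = 20,
                        gain_slope = c(red = 0, green = 0),
                        latency_slope = c(red = 0, green = 0),
                        intensity_ref = 0.22,
                        suppression = 0,
                        selectivity_class = "untuned") {
  polarity <- match.arg(polarity)
  for (nm in c("gain", "latency", "gain_slope", "latency_slope")) {
    v <- get(nm)
    if (!all(c("red", "green") %in% names(v)))
      stop(nm, " must be a named vector with 'red' and 'green' entries")
  }
  if (baseline_rate < 0) stop("baseline_rate must be >= 0")
  if (any(gain < 0)) stop("gains must be >= 0")
  if (any(latency <= 0)) stop("latencies must be > 0")
  if (kernel_width <= 0) stop("kernel_width must be > 0")
  if (suppression < 0 || suppression > 1)
    stop("suppression must be in [0, 1]")
  if (selectivity_class == "green_only" && gain[["red"]] != 0)
    stop("green_only cells must have red gain 0")
  structure(list(cell_id = cell_id, baseline_rate = baseline_rate,
                 polarity = polarity,
                 gain = gain[c("red", "green")],
                 latency = latency[c("red", "green")],
                 kernel_width = kernel_width,
                 gain_slope = gain_slope[c("red", "green")],
                 latency_slope = latency_slope[c("red", "green")],
                 intensity_ref = intensity_ref,
                 suppression = suppression,
                 selectivity_class = selectivity_class),
            class = "cell_params")
}

# Effective gain/latency for one flash, after the log-intensity coupling.
flash_gain <- function(p, colour, intensity) {
  li <- log10(intensity / p$intensity_ref)
  pmax(0, p$gain[colour] + p$gain_slope[colour] * li)
}
flash_latency <- function(p, colour, intensity) {
  li <- log10(intensity / p$intensity_ref)
  pmax(1, p$latency[colour] + p$latency_slope[colour] * li)
}

#' Specification of a heterogeneous simulated population
#'
#' Describes how many cells to simulate and the mix of selectivity classes.
#' The default mix mirrors the structure seen in flash-stimulated archer-fish
#' retina: ~5% highly colour-tuned cells (strong OFF responses, ~70 ms
#' red-green latency shift), a minority of weakly tuned cells, a small group
#' responding to green flashes only, and ~60% cells whose responses carry no
#' colour information (near-chance colour accuracy).
#'
#' @param n_cells Number of cells (>= 1).
#' @param fractions Named fractions over classes `tuned`, `weak`,
#'   `green_only`, `untuned`; must sum to 1. Class counts are allocated
#'   deterministically by the largest-remainder rule.
#' @param seed Integer seed controlling parameter draws and spiking noise.
#'
#' @return A `population_spec` object.
#' @export
population_spec <- function(n_cells = 100,
                            fractions = c(tuned = 0.05, weak = 0.30,
                                          green_only = 0.05, untuned = 0.60),
                            seed = 1L) {
  if (n_cells < 1) stop("n_cells must be >= 1")
  classes <- c("tuned", "weak", "green_only", "untuned")
  if (!setequal(names(fractions), classes))
    stop("fractions must be named tuned/weak/green_only/untuned")
  fractions <- fractions[classes]
  if (any(fractions < 0) || any(fractions > 1) ||
      abs(sum(fractions) - 1) > 1e-8)
    stop("fractions must lie in [0,1] and sum to 1")
  structure(list(n_cells = as.integer(n_cells), fractions = fractions,
                 seed = as.integer(seed)),
            class = "population_spec")
}

# Largest-remainder apportionment of n cells over the class fractions;
# deterministic (ties broken in class order tuned, weak, green_only, untuned).
class_counts <- function(spec) {
  quota <- spec$fractions * spec$n_cells
  counts <- floor(quota)
  short <- spec$n_cells - sum(counts)
  if (short > 0) {
    ord <- order(quota - counts, decreasing = TRUE)
    counts[ord[seq_len(short)]] <- counts[ord[seq_len(short)]] + 1
  }
  stats::setNames(as.integer(counts), names(spec$fractions))
}

#' Draw ground-truth parameters for one cell of a selectivity class
#'
#' Samples [cell_params()] from the per-class default distributions. The
#' ranges encode the response statistics of the flash experiments:
#' baselines of 6-10 Hz, green responses stronger and earlier than red, a
#' ~70 ms red-green latency shift in tuned cells (green first spikes below
#' the ~170 ms boundary, red above it), intensity coupling stronger for
#' red, and OFF polarity for the colour-informative classes. Uses the
#' current RNG state; wrap in [withr::with_seed()] for reproducibility.
#'
#' @param class `"tuned"`, `"weak"`, `"green_only"` or `"untuned"`.
#' @param cell_id Identifier for the new cell.
#' @return A [cell_params()] object.
#' @export
sample_cell_params <- function(class, cell_id) {
  r <- stats::runif
  switch(class,
    tuned = cell_params(
      cell_id, baseline_rate = r(1, 6, 10), polarity = "OFF",
      gain = c(red = r(1, 2.5, 3.5), green = r(1, 4, 5.5)),
      # OFF cells respond after the 66 ms flash ends; green first spikes
      # land below ~170 ms and red above it (the first-spike boundary)
      latency = local({
        lg <- r(1, 100, 140); c(red = lg + 70, green = lg)
      }),
      kernel_width = r(1, 15, 22),
      gain_slope = c(red = 0.8, green = 0.8),
      latency_slope = c(red = -30, green = -12),
      suppression = 0.95,
      selectivity_class = "tuned"),
    weak = cell_params(
      cell_id, baseline_rate = r(1, 6, 10),
      polarity = if (r(1) < 0.7) "OFF" else "ON",
      gain = c(red = r(1, 0.6, 1.4), green = r(1, 1.0, 2.0)),
      latency = local({
        lg <- r(1, 60, 85); c(red = lg + r(1, 10, 20), green = lg)
      }),
      kernel_width = r(1, 18, 25),
      gain_slope = c(red = 0.3, green = 0.3),
      latency_slope = c(red = -15, green = -8),
      suppression = 0.6,
      selectivity_class = "weak"),
    green_only = cell_params(
      cell_id, baseline_rate = r(1, 3, 6), polarity = "OFF",
      gain = c(red = 0, green = r(1, 0.8, 1.4)),
      latency = c(red = 100, green = r(1, 65, 90)),
      kernel_width = r(1, 18, 25),
      gain_slope = c(red = 0, green = 0.2),
      latency_slope = c(red = 0, green = -8),
      suppression = 0.95,
      selectivity_class = "green_only"),
    untuned = local({
      g <- r(1, 0.5, 1.5); lat <- r(1, 60, 90)
      cell_params(
        cell_id, baseline_rate = r(1, 6, 10),
        polarity = if (r(1) < 0.7) "OFF" else "ON",
        gain = c(red = g, green = g),
        latency = c(red = lat, green = lat),
        kernel_width = r(1, 18, 25),
        gain_slope = c(red = 0.3, green = 0.3),
        latency_slope = c(red = -10, green = -10),
        suppression = 0.6,
        selectivity_class = "untuned")
    }),
    stop("unknown selectivity class: ", class))
}
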