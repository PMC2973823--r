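#' Write spike trains as a delimited-text table
#'
#' Tab-separated with header `cell_id`, `spike_time_ms`; times written with
#' 3 decimal places (microsecond resolution), 0-based from recording start.
#'
#' @param trains Named list of spike-time vectors, or a
#'   `population_recording`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spike_table <- function(trains, path) {
  if (inherits(trains, "population_recording")) trains <- trains$trains
  stopifnot(is.list(trains), !is.null(names(trains)))
  df <- data.frame(
    cell_id = rep(names(trains), lengths(trains)),
    spike_time_ms = sprintf("%.3f", unlist(trains, use.names = FALSE)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read spike trains from a delimited-text table
#'
#' Expects the format written by [write_spike_table()]. Times must be
#' non-negative and sorted within each cell (errors name the offending
#' line); duplicate timestamps within a cell are collapsed with a warning.
#'
#' @param path Input file path.
#' @return Named list of sorted spike-time vectors.
#' @export
read_spike_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("cell_id", "spike_time_ms") %in% names(df)))
    stop("spike table needs columns cell_id, spike_time_ms")
  bad <- which(df$spike_time_ms < 0)
  if (length(bad))
    stop("negative spike time at line ", bad[1] + 1L)  # +1 for header
  trains <- list()
  for (id in unique(df$cell_id)) {
    rows <- which(df$cell_id == id)
    tt <- df$spike_time_ms[rows]
    if (is.unsorted(tt))
      stop("unsorted spike times for cell ", id, " at line ",
           rows[which(diff(tt) < 0)[1] + 1L] + 1L)
    if (anyDuplicated(tt)) {
      warning("duplicate spike times for cell ", id, "; collapsed")
      tt <- unique(tt)
    }
    trains[[as.character(id)]] <- tt
  }
  trains
}

#' Write a stimulus log as delimited text
#'
#' Tab-separated with header `onset_ms`, `colour`, `intensity`; onset times
#' with 3 decimal places, colour labels lowercase.
#'
#' @param stimulus A `stimulus_sequence`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_stimulus_log <- function(stimulus, path) {
  stopifnot(inherits(stimulus, "stimulus_sequence"))
  df <- data.frame(onset_ms = sprintf("%.3f", stimulus$flashes$onset),
                   colour = stimulus$flashes$colour,
                   intensity = stimulus$flashes$intensity)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a stimulus log from delimited text
#'
#' @param path Input file path.
#' @param flash_duration Flash duration (ms, default 66).
#' @param total_duration Recording duration (ms); defaults to the last
#'   flash offset plus one mean inter-flash interval (1.6 s).
#' @return A `stimulus_sequence`. Unknown colour labels and overlapping
#'   flashes are rejected.
#' @export
read_stimulus_log <- function(path, flash_duration = 66,
                              total_duration = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("onset_ms", "colour", "intensity") %in% names(df)))
    stop("stimulus log needs columns onset_ms, colour, intensity")
  if (!all(df$colour %in% c("red", "green")))
    stop("unknown colour label: ",
         paste(setdiff(unique(df$colour), c("red", "green")), collapse = ", "))
  flashes <- data.frame(onset = df$onset_ms, colour = df$colour,
                        intensity = df$intensity, stringsAsFactors = FALSE)
  if (is.null(total_duration))
    total_duration <- if (nrow(flashes))
      max(flashes$onset) + flash_duration + 1600 else 0
  new_stimulus_sequence(flashes, flash_duration, total_duration)
}

#' Assemble a population recording from trains and a stimulus
#'
#' Glue for file-based workflows: combines spike trains read with
#' [read_spike_table()] and a stimulus read with [read_stimulus_log()].
#'
#' @param trains Named list of spike-time vectors.
#' @param stimulus A `stimulus_sequence`.
#' @return A `population_recording` (without ground-truth cell parameters).
#' @export
as_population_recording <- function(trains, stimulus) {
  stopifnot(is.list(trains), inherits(stimulus, "stimulus_sequence"))
  allsp <- unlist(trains, use.names = FALSE)
  if (length(allsp) && max(allsp) > stimulus$total_duration)
    stop("spikes beyond stimulus total_duration")
  structure(list(stimulus = stimulus, trains = trains,
                 cell_params = NULL, cell_ids = names(trains)),
            class = "population_recording")
}

#' Default run configuration
#'
#' All pipeline constants in one place: 66 ms flashes with 1.1-2.1 s gaps
#' and 0.07-0.7 uW/cm^2 intensities; 25 ms windows at 50% overlap; 375 ms
#' colour filter; 250 ms (main) and 125 ms (combined readout) onset
#' filters; the +/-125 ms detection tolerance; 500 flashes and 100 cells by
#' default; sweep sizes with 50 subgroups each.
#'
#' @param ... Named overrides of top-level entries (partial lists are
#'   merged shallowly).
#' @return A nested list (`run_config`).
#' @export
default_config <- function(...) {
  cfg <- list(
    seed = 1L,
    stimulus = list(n_flashes = 500, interflash_range = c(1100, 2100),
                    flash_duration = 66, intensity_range = c(0.07, 0.7)),
    population = list(n_cells = 100,
                      fractions = c(tuned = 0.05, weak = 0.30,
                                    green_only = 0.05, untuned = 0.60)),
    decoder = list(window_length = 25, overlap = 0.5,
                   what_filter_length = 375, when_filter_length = 250,
                   twostage_filter_length = 125, tolerance = 125,
                   latency_bin = 10,
                   sweep_sizes = c(1, 5, 10, 25, 50, 75, 100),
                   n_subgroups = 50))
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(cfg[[nm]]) && is.list(over[[nm]]))
      cfg[[nm]][names(over[[nm]])] <- over[[nm]]
    else cfg[[nm]] <- over[[nm]]
  }
  structure(cfg, class = "run_config")
}

#' Read a YAML run configuration
#'
#' Entries missing from the file fall back to [default_config()] values.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- default_config()
  for (nm in intersect(names(raw), names(cfg))) {
    if (is.list(cfg[[nm]]) && is.list(raw[[nm]])) {
      for (k in names(raw[[nm]])) cfg[[nm]][[k]] <- raw[[nm]][[k]]
    } else cfg[[nm]] <- raw[[nm]]
  }
  if (!is.null(cfg$population$fractions))
    cfg$population$fractions <- unlist(cfg$population$fractions)
  structure(cfg, class = "run_config")
}

#' Write a run configuration to YAML
#' @param cfg A `run_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  # yaml drops names from atomic vectors; promote named vectors to maps
  promote <- function(x) {
    if (is.list(x)) lapply(x, promote)
    else if (!is.null(names(x))) as.list(x)
    else x
  }
  yaml::write_yaml(promote(unclass(cfg)), path)
  invisible(path)
}
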