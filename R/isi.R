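#' Joint distribution of interspike intervals and stimulus condition
#'
#' Relative first-spike latencies of a single cell are its interspike
#' intervals (ISIs), so an onset detector that knows no absolute time
#' reference can only work from ISIs. Each ISI is keyed by its second
#' spike: if that spike falls within `assign_window` ms after a flash onset
#' (default 216 = 150 ms assignment window + 66 ms flash), the ISI is
#' assigned to that flash's colour; otherwise to the black screen. The
#' empirical joint table over (ISI bin, {red, green, black}), the
#' per-stimulus conditionals and the stimulus prior are tabulated.
#'
#' @param train Spike-time vector (>= 2 spikes).
#' @param stimulus A `stimulus_sequence`.
#' @param assign_window Assignment window after flash onset (ms, default
#'   216).
#' @param isi_bin ISI bin width (ms, default 25).
#' @param isi_range ISI range covered by the bins (ms, default 0-1000);
#'   longer ISIs are clamped into the last bin.
#' @return An `isi_joint_distribution`: `joint` (bins x 3, sums to 1),
#'   `conditional` (columns sum to 1), `prior`, `edges`.
#' @export
build_isi_joint <- function(train, stimulus, assign_window = 216,
                            isi_bin = 25, isi_range = c(0, 1000)) {
  train <- sort(train)
  if (length(train) < 2) stop("need at least 2 spikes to form ISIs")
  stopifnot(inherits(stimulus, "stimulus_sequence"))
  isi <- diff(train)
  second <- train[-1]
  onsets <- stimulus$flashes$onset
  lab <- rep("black", length(isi))
  if (length(onsets)) {
    j <- findInterval(second, onsets)
    hit <- j > 0 & (second - onsets[pmax(j, 1)]) < assign_window
    lab[hit] <- stimulus$flashes$colour[j[hit]]
  }
  edges <- seq(isi_range[1], isi_range[2], by = isi_bin)
  nb <- length(edges) - 1
  bins <- pmin(pmax(findInterval(isi, edges, rightmost.closed = TRUE), 1L), nb)
  lev <- c("red", "green", "black")
  joint <- table(factor(bins, levels = seq_len(nb)), factor(lab, levels = lev))
  joint <- unclass(joint) / length(isi)
  prior <- colSums(joint)
  cond <- joint
  for (k in seq_along(lev))
    if (prior[k] > 0) cond[, k] <- joint[, k] / prior[k]
  structure(list(joint = joint, conditional = cond, prior = prior,
                 edges = edges, isi_bin = isi_bin,
                 assign_window = assign_window),
            class = "isi_joint_distribution")
}

# map an ISI to its bin, clamping (with a warning) outside the range
isi_bin_index <- function(dist, isi) {
  nb <- nrow(dist$joint)
  b <- findInterval(isi, dist$edges, rightmost.closed = TRUE)
  if (any(b < 1 | b > nb))
    warning("ISI outside binned range; clamped to edge bin")
  pmin(pmax(b, 1L), nb)
}

# argmax over the three stimulus conditions with the fixed tie-break order
# black > green > red (scan order picks the first maximum)
isi_argmax <- function(p) {
  lev <- c("black", "green", "red")
  lev[which.max(p[lev])]
}

#' Maximum-likelihood stimulus from one ISI
#'
#' Chooses the stimulus condition maximising the conditional probability
#' `P(ISI bin | stimulus)` — the likelihood readout that ignores how rare
#' flashes are. Ties break black > green > red.
#'
#' @param dist An [build_isi_joint()] distribution.
#' @param isi ISI values in ms.
#' @return Character labels in `{red, green, black}`.
#' @export
ml_classify <- function(dist, isi) {
  stopifnot(inherits(dist, "isi_joint_distribution"))
  b <- isi_bin_index(dist, isi)
  vapply(b, function(k) isi_argmax(dist$conditional[k, ]), "")
}

#' Maximum-a-posteriori stimulus from one ISI
#'
#' Chooses the stimulus maximising `P(stimulus | ISI bin) proportional to
#' P(ISI bin | stimulus) * P(stimulus)`. Under a uniform prior this
#' coincides with [ml_classify()]; under the realistic prior — flashes are
#' rare, the black screen dominates — the posterior mass shifts to black
#' for (nearly) every bin.
#'
#' @inheritParams ml_classify
#' @param prior Optional length-3 prior over `c(red, green, black)`;
#'   defaults to the distribution's empirical prior.
#' @return Character labels in `{red, green, black}`.
#' @export
map_classify <- function(dist, isi, prior = NULL) {
  stopifnot(inherits(dist, "isi_joint_distribution"))
  if (is.null(prior)) prior <- dist$prior
  if (is.null(names(prior))) names(prior) <- c("red", "green", "black")
  b <- isi_bin_index(dist, isi)
  vapply(b, function(k) {
    post <- dist$conditional[k, ] * prior[colnames(dist$conditional)]
    isi_argmax(post)
  }, "")
}

#' Posterior over stimulus conditions per ISI bin
#'
#' @param dist An `isi_joint_distribution`.
#' @param prior Optional prior (defaults to the empirical one).
#' @return Matrix bins x 3; rows sum to 1 where defined.
#' @export
isi_posterior <- function(dist, prior = NULL) {
  stopifnot(inherits(dist, "isi_joint_distribution"))
  if (is.null(prior)) prior <- dist$prior
  post <- sweep(dist$conditional, 2, prior, "*")
  rs <- rowSums(post)
  post[rs > 0, ] <- post[rs > 0, ] / rs[rs > 0]
  post
}

#' Expected interval between ISI-readout false alarms on a black screen
#'
#' A cell firing at `baseline_rate` under a black screen produces ISIs at
#' that rate; if a fraction of those ISIs falls in the range the
#' maximum-likelihood readout classifies as a stimulus, false alarms occur
#' at `rate * fraction` per second, i.e. one every
#' `1000 / (rate * fraction)` ms. A 6 Hz cell with half of its baseline
#' ISIs confusable gives one false alarm per ~333 ms; with 10% confusable,
#' one per ~1667 ms.
#'
#' @param baseline_rate Baseline firing rate in Hz (> 0).
#' @param confusable_fraction Fraction of baseline ISIs classified as a
#'   stimulus, in `[0, 1]`.
#' @return Expected ms between false alarms (`Inf` when the fraction is 0).
#' @export
false_alarm_interval <- function(baseline_rate, confusable_fraction) {
  if (baseline_rate <= 0) stop("baseline_rate must be > 0")
  if (confusable_fraction < 0 || confusable_fraction > 1)
    stop("confusable_fraction must be in [0, 1]")
  if (confusable_fraction == 0) return(Inf)
  1000 / (baseline_rate * confusable_fraction)
}
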