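# Shared fixtures, built once per test run. Sizes are kept at desk scale:
# enough flashes for the decoders to fit stably, small enough that the whole
# suite stays fast.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

# 300-flash stimulus shared by single-cell tests
fix_stimulus <- function() memo("stim300", generate_stimulus(300, seed = 42))

# one well-tuned cell (70 ms red-green latency shift) on that stimulus
fix_tuned <- function() memo("tuned", {
  p <- withr::with_seed(7, sample_cell_params("tuned", "tuned1"))
  list(params = p, train = simulate_cell(p, fix_stimulus(), seed = 8))
})

# small heterogeneous population for detection / two-stage tests
fix_population <- function() memo("pop", {
  stim <- generate_stimulus(200, seed = 11)
  generate_population(population_spec(40, seed = 12), stim)
})

# deterministic two-template colour trials: red trials one fixed pattern,
# green trials another (linearly separable)
fix_templates <- function(n_per = 10, L = 8) {
  X <- matrix(0, 2 * n_per, L)
  X[seq_len(n_per), 2] <- 3                 # red template
  X[n_per + seq_len(n_per), 5] <- 3         # green template
  structure(list(X = X,
                 colour = rep(1:2, each = n_per),
                 intensity = rep(0.3, 2 * n_per),
                 onset_used = seq_len(2 * n_per) * 1000,
                 window_length = 25, overlap = 0.5,
                 filter_length = L * 12.5),
            class = "colour_trials")
}

# independent least-squares oracle: exact normal equations via QR, no ridge
ls_oracle <- function(X, y) {
  co <- qr.coef(qr(cbind(X, 1)), y)
  list(w = co[seq_len(ncol(X))], C = co[ncol(X) + 1])
}
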