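# Shared fixtures, built in code at test time.

# A short 12-frame, 60-minute schedule for fast scan-level tests.
toy_schedule <- function() {
  dur <- c(rep(0.5, 4), rep(2, 4), rep(12.5, 4))
  ends <- cumsum(dur)
  frame_schedule(c(0, ends[-length(ends)]), ends)
}

# TAC constructed exactly as k1 * cumulative plasma integral at the frame
# midpoints (pure irreversible model, zero noise).
toy_irreversible_tac <- function(k1, schedule = default_schedule(),
                                 idif = NULL) {
  mid <- frame_midpoints(schedule)
  if (is.null(idif)) {
    tg <- sort(unique(c(seq(0, max(schedule$frame_end), by = 0.05), mid)))
    idif <- simulate_input_function(grid = tg)
  }
  cum <- c(0, cumsum(diff(idif$times) *
                       (idif$concentrations[-1] +
                          idif$concentrations[-length(idif$concentrations)]) / 2))
  list(tac = k1 * stats::approx(idif$times, cum, xout = mid)$y, idif = idif)
}

# A valid random similarity matrix on n regions (via random features).
random_similarity <- function(n, seed = 1) {
  reg <- subset_registry(n)
  withr::with_seed(seed, {
    f <- matrix(rnorm(n * 4), n, 4, dimnames = list(reg$name, NULL))
    build_similarity_matrix(f)
  })
}

fast_config <- function(...) {
  classification_config(n_repeats = 2, n_boot = 200, ...)
}
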