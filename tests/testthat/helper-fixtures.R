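# Shared fixtures: all synthetic, generated in code, memoised per session.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Small coupled population: 30 neurons, 4 identical blocks, short
# presentations, planted coupling of the default shape.
small_sim <- function() {
  memo("small_sim", {
    proto <- generate_protocol(n_blocks = 4, presentation_frames = 15,
                               grey_frames = 10, seed = 2)
    coup <- generate_coupling(30, seed = 3)
    tun <- make_tuning(30, seed = 4)
    simulate_population(proto, coup, tun, seed = 5)
  })
}

small_graph <- function() {
  memo("small_graph", build_functional_graph(small_sim()$dataset))
}

small_suite <- function() {
  memo("small_suite", run_model_suite(small_sim()$dataset, small_graph(),
                                      variants = "unrestricted"))
}

# A coupling ground truth with no edges (for null simulations).
empty_coupling <- function(n_neurons) {
  structure(list(n_neurons = as.integer(n_neurons),
                 edges = data.frame(source = integer(0), target = integer(0),
                                    weight = numeric(0), lag = integer(0)),
                 strong_fraction = 0, positive_fraction_strong = NA_real_),
            class = "coupling_truth")
}

# Random conditioning set: first two series share structure with three
# correlated background series, mimicking a pair plus its conditioners.
random_conditioning_set <- function(t_len = 200) {
  z <- matrix(stats::rnorm(t_len * 3), t_len, 3)
  x <- z %*% stats::rnorm(3) + stats::rnorm(t_len)
  y <- 0.5 * x + z %*% stats::rnorm(3) + stats::rnorm(t_len)
  cbind(x = as.numeric(x), y = as.numeric(y),
        c1 = z[, 1], c2 = z[, 2], c3 = z[, 3])
}

# Independent oracle for the precision-matrix partial correlation: regress
# each of the first two series on the remaining conditioning series and
# correlate the residuals.
residual_correlation_oracle <- function(cond) {
  cond <- as.matrix(cond)
  z <- cond[, -(1:2), drop = FALSE]
  rx <- stats::lm.fit(cbind(1, z), cond[, 1])$residuals
  ry <- stats::lm.fit(cbind(1, z), cond[, 2])$residuals
  stats::cor(rx, ry)
}

# A perfectly separable 13-condition dataset: each condition drives a
# distinct mean response far beyond the noise.
separable_dataset <- function(n_neurons = 3, reps = 40, sep = 50, noise = 0.1,
                              seed = 42) {
  conds <- stim_conditions()
  labels <- rep(rep(conds, each = 5), reps)
  t_total <- length(labels)
  idx <- match(labels, conds)
  set.seed(seed)
  traces <- t(vapply(seq_len(n_neurons), function(i) {
    sep * i * idx + stats::rnorm(t_total, sd = noise)
  }, numeric(t_total)))
  fl_dataset(traces, 30, labels, rep(0, t_total), rep(1L, t_total),
             tuned = rep(TRUE, n_neurons))
}
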