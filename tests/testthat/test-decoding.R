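# Bayesian MAP decoders, confusion matrices and plug-in mutual information.

test_that("uncoupled decoder statistics match group-mean oracles", {
  ds <- small_sim()$dataset
  sp <- split_frames(ds, 0.7, "block")
  dec <- fit_uncoupled_decoder(ds, sp$train)
  for (s in c("grey", "90", "270")) {
    fr <- intersect(sp$train, which(ds$labels == s))
    expect_equal(dec$means[, s], rowMeans(ds$traces[, fr]), tolerance = 1e-12)
    expect_equal(dec$vars[, s],
                 pmax(apply(ds$traces[, fr], 1, stats::var), 1e-6),
                 tolerance = 1e-12)
  }
})

test_that("a separable population decodes perfectly: identity confusion and
           maximal mutual information", {
  ds <- separable_dataset()
  dec <- fit_uncoupled_decoder(ds, seq_len(ds$n_frames))
  res <- decode_map(dec, ds)
  expect_identical(res$decoded, res$true)
  ev <- evaluate_decoding(res)
  expect_equal(ev$accuracy, 100)
  expect_equal(unname(diag(ev$confusion)), rep(100, 13))
  expect_equal(ev$mi_bits, log2(13), tolerance = 1e-10)
})

test_that("MAP decoding matches a brute-force posterior evaluation", {
  ds <- separable_dataset(n_neurons = 2, reps = 10, sep = 1, noise = 2)
  dec <- fit_uncoupled_decoder(ds, seq_len(ds$n_frames))
  res <- decode_map(dec, ds, frames = 1:100)
  conds <- stim_conditions()
  for (t in c(1, 37, 100)) {
    ll <- vapply(seq_along(conds), function(k) {
      sum(stats::dnorm(ds$traces[, t], dec$means[, k], sqrt(dec$vars[, k]),
                       log = TRUE)) + log(1 / 13)
    }, numeric(1))
    expect_identical(res$decoded[t], conds[which.max(ll)])
  }
})

test_that("posterior ties resolve to the lowest condition index", {
  ds <- separable_dataset(n_neurons = 2, reps = 5)
  dec <- fit_uncoupled_decoder(ds, seq_len(ds$n_frames))
  dec$means[] <- 0
  dec$vars[] <- 1
  res <- decode_map(dec, ds, frames = 1:10)
  expect_true(all(res$decoded == "grey"))
})

test_that("unseen conditions in training are rejected", {
  ds <- separable_dataset(n_neurons = 2, reps = 5)
  bad_frames <- which(ds$labels != "60")
  expect_error(fit_uncoupled_decoder(ds, bad_frames), "unseen-?\\s*condition|unseen condition")
})

test_that("coupled covariance estimation is positive-definite and shrinks
           independent noise toward the identity", {
  set.seed(301)
  x <- matrix(rnorm(2000 * 8), 2000, 8)
  s <- popcoupling:::shrunk_covariance(x)
  expect_true(all(eigen(s, symmetric = TRUE, only.values = TRUE)$values > 0))
  expect_lt(max(abs(s[upper.tri(s)])), 0.05)
  expect_equal(unname(diag(s)), rep(1, 8), tolerance = 0.1)
})

test_that("coupled and uncoupled decoders coincide in the diagonal,
           stimulus-only limit", {
  ds <- separable_dataset(n_neurons = 3, reps = 20, sep = 2, noise = 1)
  frames <- seq_len(ds$n_frames)
  unc <- fit_uncoupled_decoder(ds, frames, var_floor = 0)
  # coupled decoder whose LM is the bare stimulus term (psi = 1, all other
  # coefficients 0) and whose covariance is forced diagonal
  conds <- stim_conditions()
  stim_vals <- popcoupling:::stimulus_condition_values(ds, frames)
  stim_vals[, "grey"] <- rowMeans(ds$traces[, ds$labels == "grey"])
  chols <- lapply(conds, function(s) chol(diag(unc$vars[, s])))
  names(chols) <- conds
  coef <- cbind(`(Intercept)` = 0, coupling0 = 0, coupling1 = 0,
                stimulus = 1, running = 0)[rep(1, 3), ]
  dec <- structure(list(variant = "coupled", conditions = conds,
                        prior = rep(1 / 13, 13), coef = coef,
                        stim_values = stim_vals, chol = chols, n_neurons = 3),
                   class = "decoder_model")
  attr(dec, "f0") <- matrix(0, 3, ds$n_frames)
  attr(dec, "f1") <- matrix(0, 3, ds$n_frames)
  # in this limit the coupled mean for grey is stim_values[, "grey"], which
  # matches the uncoupled grey mean by construction above
  res_c <- decode_map(dec, ds)
  res_u <- decode_map(unc, ds)
  expect_identical(res_c$decoded, res_u$decoded)
})

test_that("confusion rows sum to 100 and chance-level decoding sits at 1/13", {
  set.seed(302)
  true <- sample(stim_conditions(), 6000, replace = TRUE)
  decoded <- sample(stim_conditions(), 6000, replace = TRUE)
  ca <- confusion_and_accuracy(true, decoded)
  expect_equal(unname(rowSums(ca$confusion)), rep(100, 13), tolerance = 1e-9)
  expect_lt(abs(ca$accuracy - 100 / 13), 2)
  # perfect decoding gives the identity
  ca2 <- confusion_and_accuracy(true, true)
  expect_equal(unname(ca2$confusion), diag(13) * 100)
  expect_equal(ca2$accuracy, 100)
})

test_that("mutual information follows the plug-in formula", {
  # hand-specified 2x2 joint evaluated directly
  p <- matrix(c(0.4, 0.1, 0.1, 0.4), 2, 2)
  direct <- 0
  pr <- rowSums(p); pc <- colSums(p)
  for (i in 1:2) for (j in 1:2) {
    direct <- direct + p[i, j] * log2(p[i, j] / (pr[i] * pc[j]))
  }
  expect_equal(mutual_information_joint(p), direct, tolerance = 1e-12)
  # independence gives zero
  q <- outer(c(0.3, 0.7), c(0.6, 0.4))
  expect_equal(mutual_information_joint(q), 0, tolerance = 1e-12)
  # identity over 13 uniform conditions gives log2(13)
  conds <- stim_conditions()
  lab <- rep(conds, 100)
  expect_equal(mutual_information(lab, lab), log2(13), tolerance = 1e-12)
  expect_error(mutual_information_joint(matrix(0.3, 2, 2)), "sum to 1")
})

test_that("mutual information is bounded by the marginal entropies", {
  set.seed(303)
  conds <- stim_conditions()
  for (k in 1:20) {
    true <- sample(conds, 500, replace = TRUE)
    decoded <- ifelse(runif(500) < 0.5, true, sample(conds, 500, replace = TRUE))
    mi <- mutual_information(true, decoded)
    ent <- function(x) {
      p <- table(x) / length(x)
      -sum(p * log2(p))
    }
    expect_gte(mi, -1e-12)
    expect_lte(mi, min(ent(true), ent(decoded)) + 1e-12)
    expect_lte(mi, log2(13))
  }
})
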