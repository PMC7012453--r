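# Regressor construction and least-squares machinery of the encoding
# models.

test_that("block split honours the ratio and partitions all frames", {
  proto <- generate_protocol(n_blocks = 10, presentation_frames = 5,
                             grey_frames = 3, seed = 6)
  tun <- make_tuning(5, seed = 6)
  ds <- simulate_population(proto, empty_coupling(5), tun, seed = 6)$dataset
  sp <- split_frames(ds, 0.7, "block")
  expect_equal(sort(unique(ds$block[sp$train])), 1:7)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_equal(sort(c(sp$train, sp$test)), seq_len(ds$n_frames))
  sp2 <- split_frames(ds, 0.7, "block", seed = 9, mode = "random")
  sp3 <- split_frames(ds, 0.7, "block", seed = 9, mode = "random")
  expect_identical(sp2, sp3)
  expect_error(split_frames(ds, 1.2), "ratio")
})

test_that("presentation split balances presentation counts per condition", {
  ds <- small_sim()$dataset
  sp <- split_frames(ds, 0.5, "presentation")
  expect_equal(sort(c(sp$train, sp$test)), seq_len(ds$n_frames))
  pres <- popcoupling:::presentations(ds)
  for (lb in unique(pres$label)) {
    p <- pres[pres$label == lb, ]
    in_train <- vapply(seq_len(nrow(p)), function(r) {
      all(p$start[r]:p$end[r] %in% sp$train)
    }, logical(1))
    expect_equal(sum(in_train), nrow(p) / 2)
  }
})

test_that("average-response stimulus term is the plug-in training mean", {
  ds <- small_sim()$dataset
  sp <- split_frames(ds, 0.7, "block")
  i <- which(ds$tuned)[1]
  s <- stimulus_term_average_response(ds, i, sp$train)
  expect_true(all(s[ds$labels == "grey"] == 0))
  for (d in c("30", "180", "360")) {
    expect_equal(unique(s[ds$labels == d]),
                 mean(ds$traces[i, intersect(sp$train, which(ds$labels == d))]))
  }
  j <- which(!ds$tuned)[1]
  sj <- stimulus_term_average_response(ds, j, sp$train)
  per_dir <- vapply(stim_conditions()[-1], function(d) {
    mean(ds$traces[j, intersect(sp$train, which(ds$labels == d))])
  }, numeric(1))
  expect_equal(unique(sj[ds$labels != "grey"]), mean(per_dir))
})

test_that("block-averaged stimulus term matches a frame-offset group mean", {
  ds <- small_sim()$dataset
  sp <- split_frames(ds, 0.5, "presentation")
  s <- stimulus_term_block_averaged(ds, 1, sp$train)
  expect_true(all(is.na(s[ds$labels == "grey"])))
  pres <- popcoupling:::presentations(ds)
  p <- pres[pres$label == "60", ]
  in_train <- vapply(seq_len(nrow(p)), function(r) {
    all(p$start[r]:p$end[r] %in% sp$train)
  }, logical(1))
  p <- p[in_train, ]
  len <- min(p$end - p$start + 1)
  for (off in c(1, len)) {
    expect_equal(s[p$start[1] + off - 1],
                 mean(ds$traces[1, p$start + off - 1]))
  }
  # identical presentations average to themselves
  ds2 <- separable_dataset(n_neurons = 3, reps = 4, noise = 0)
  s2 <- stimulus_term_block_averaged(ds2, 1, seq_len(ds2$n_frames))
  grate <- ds2$labels != "grey"
  expect_equal(s2[grate], ds2$traces[1, grate])
})

test_that("population-average running term excludes the target neuron", {
  ds <- small_sim()$dataset
  v <- running_term(ds, "population_average", exclude_neuron = 3)
  oracle <- colMeans(ds$traces[-3, ])
  expect_equal(v, oracle, tolerance = 1e-12)
  expect_identical(running_term(ds, "rotary"), ds$running)
})

test_that("least squares is exact on noise-free designs and matches the
           normal-equations oracle", {
  set.seed(201)
  x <- matrix(rnorm(500 * 2), 500, 2, dimnames = list(NULL, c("f1", "f2")))
  y <- 2 * x[, 1] - 3 * x[, 2] + 5
  fit <- fit_lm(x, y)
  expect_equal(unname(fit$coef), c(5, 2, -3), tolerance = 1e-10)
  expect_equal(evaluate_mse(fit, x, y, seq_along(y)), 0, tolerance = 1e-16)
  # response equal to one feature
  y2 <- x[, 2]
  fit2 <- fit_lm(x, y2)
  expect_equal(unname(fit2$coef), c(0, 0, 1), tolerance = 1e-10)
  # random designs against solve(X'X, X'y)
  for (k in 1:25) {
    p <- sample(2:5, 1)
    xx <- matrix(rnorm(200 * p), 200, p)
    colnames(xx) <- paste0("f", 1:p)
    yy <- rnorm(200)
    fit3 <- fit_lm(xx, yy)
    xd <- cbind(1, xx)
    oracle <- solve(crossprod(xd), crossprod(xd, yy))
    expect_equal(unname(fit3$coef), as.numeric(oracle), tolerance = 1e-8)
  }
})

test_that("nonnegative fit lands on the boundary when the sign disagrees", {
  set.seed(202)
  f1 <- abs(rnorm(300))
  y <- -f1 + rnorm(300, sd = 0.01)
  fit <- fit_lm(cbind(f1 = f1), y, nonneg = TRUE)
  expect_equal(unname(fit$coef["f1"]), 0)
  expect_equal(unname(fit$coef["(Intercept)"]), mean(y), tolerance = 1e-10)
  # agrees with the unconstrained fit when that fit is already feasible
  y2 <- 2 * f1 + 1 + rnorm(300, sd = 0.1)
  expect_equal(fit_lm(cbind(f1 = f1), y2, nonneg = TRUE)$coef,
               fit_lm(cbind(f1 = f1), y2)$coef, tolerance = 1e-10)
})

test_that("link fits recover generating coefficients", {
  set.seed(203)
  x <- matrix(runif(400 * 2, 0.5, 1.5), 400, 2,
              dimnames = list(NULL, c("f1", "f2")))
  beta <- c(1, 0.8, 0.5)
  eta <- cbind(1, x) %*% beta
  fit_r <- fit_glm_link(x, as.numeric(1 / eta), link = "reciprocal")
  expect_equal(unname(fit_r$coef), beta, tolerance = 1e-6)
  x2 <- matrix(rnorm(400 * 2), 400, 2, dimnames = list(NULL, c("f1", "f2")))
  eta2 <- cbind(1, x2) %*% c(0.5, 1.5, -2)
  fit_c <- fit_glm_link(x2, sign(eta2) * abs(eta2)^(1 / 3), link = "cube")
  expect_equal(unname(fit_c$coef), c(0.5, 1.5, -2), tolerance = 1e-6)
  # constant response under the cube link predicts the constant
  yc <- rep(2, 400)
  fit_k <- fit_glm_link(x2, yc, link = "cube")
  expect_equal(unname(predict(fit_k, x2)), yc, tolerance = 1e-6)
})

test_that("MSE evaluation matches a direct loop and rejects empty subsets", {
  ds <- small_sim()$dataset
  x <- cbind(f = ds$running)
  fit <- fit_lm(x, ds$traces[1, ], seq_len(ds$n_frames))
  frames <- 101:400
  direct <- {
    pred <- fit$coef[1] + fit$coef[2] * ds$running[frames]
    mean((ds$traces[1, frames] - pred)^2)
  }
  expect_equal(evaluate_mse(fit, x, ds$traces[1, ], frames), direct,
               tolerance = 1e-12)
  # constant zero prediction on a centred response gives its mean square
  fit0 <- fit
  fit0$coef[] <- 0
  expect_equal(evaluate_mse(fit0, x, ds$traces[1, ], frames),
               mean(ds$traces[1, frames]^2), tolerance = 1e-12)
  still <- which(ds$running == 0)
  expect_error(evaluate_mse(fit, x, ds$traces[1, ], still, ds, "running_only"),
               "empty")
})

test_that("percent change in MSE follows the stated sign convention", {
  expect_equal(percent_change_mse(0.05, 0.04), 25)
  expect_equal(percent_change_mse(0.04, 0.04), 0)
  expect_equal(percent_change_mse(0.03, 0.04), -25)
  expect_error(percent_change_mse(0.05, 0), "undefined")
})

test_that("frame subsets select the documented frames", {
  ds <- small_sim()$dataset
  all_frames <- seq_len(ds$n_frames)
  stim <- popcoupling:::subset_frames(ds, all_frames, "stimulus_only")
  expect_true(all(ds$labels[stim] != "grey"))
  run <- popcoupling:::subset_frames(ds, all_frames, "running_only")
  expect_true(all(ds$running[run] > 0))
  onset <- popcoupling:::subset_frames(ds, all_frames, "first_second_after_onset")
  expect_true(all(ds$labels[onset] != "grey"))
  # one second = 30 frames at 30 Hz, but presentations here are 15 frames
  pres <- popcoupling:::presentations(ds)
  expect_length(onset, sum(pmin(pres$end - pres$start + 1, 30)[pres$label != "grey"]))
})

test_that("the suite reports zero change for the unrestricted model and
           keeps the nesting property", {
  ds <- small_sim()$dataset
  g <- small_graph()
  suite <- run_model_suite(ds, g, variants = c("unrestricted", "stim_restricted",
                                               "coupling_restricted"))
  un <- suite$results[suite$results$variant == "unrestricted", ]
  expect_true(all(un$pct_change == 0))
  expect_length(suite$failed, 0)
  # training MSE of nested variants cannot beat the unrestricted model
  # (asserted internally on every run; re-check via a direct refit here)
  i <- 1
  sp <- suite$split
  f0 <- popcoupling:::coupling_feature(ds, coupling_matrices(g, 0L)[[1]], 0L)
  f1 <- popcoupling:::coupling_feature(ds, coupling_matrices(g, 1L)[[1]], 1L)
  s <- stimulus_term_average_response(ds, i, sp$train)
  frames <- suite$fit_frames
  x_full <- cbind(c0 = f0$values[i, ], c1 = f1$values[i, ], s = s, v = ds$running)
  x_sub <- x_full[, c("s", "v")]
  y <- ds$traces[i, ]
  full_mse <- evaluate_mse(fit_lm(x_full, y, frames), x_full, y, frames)
  sub_mse <- evaluate_mse(fit_lm(x_sub, y, frames), x_sub, y, frames)
  expect_lte(full_mse, sub_mse + 1e-10)
})
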