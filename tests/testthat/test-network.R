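# Functional network estimation: the precision-matrix partial correlation
# against its residual-regression oracle, cross-correlogram lags, graph
# assembly and functional groups.

test_that("partial correlation equals the residual-correlation oracle", {
  set.seed(101)
  for (k in 1:50) {
    cond <- random_conditioning_set(300)
    expect_equal(as.numeric(trial_partial_correlation(cond)),
                 residual_correlation_oracle(cond), tolerance = 1e-8)
  }
})

test_that("partial correlation is symmetric and bounded", {
  set.seed(102)
  cond <- random_conditioning_set(3000)
  rho <- trial_partial_correlation(cond)
  swapped <- cond[, c(2, 1, 3, 4, 5)]
  expect_equal(as.numeric(rho),
               as.numeric(trial_partial_correlation(swapped)),
               tolerance = 1e-12)
  expect_true(abs(rho) <= 1)
})

test_that("independent series give a near-zero partial correlation", {
  set.seed(103)
  z <- matrix(rnorm(3000 * 3), 3000, 3)
  cond <- cbind(x = rnorm(3000), y = rnorm(3000), z)
  expect_lt(abs(as.numeric(trial_partial_correlation(cond))), 0.1)
})

test_that("degenerate conditioning sets are rejected or flagged", {
  cond <- random_conditioning_set(100)
  cond[, 3] <- 1  # zero variance
  expect_error(trial_partial_correlation(cond), "zero-variance")
  expect_error(trial_partial_correlation(random_conditioning_set(8)),
               "length >= 10")
  # near-duplicate series trip the ridge guard but still return a value
  cond2 <- random_conditioning_set(100)
  cond2[, 4] <- cond2[, 3] + 1e-14 * rnorm(100)
  rho <- trial_partial_correlation(cond2)
  expect_true(abs(rho) <= 1)
})

test_that("functional weight is the mean of per-block partial correlations", {
  ds <- small_sim()$dataset
  w <- functional_weight(ds, 1, 2)
  per_block <- vapply(1:4, function(b) {
    as.numeric(trial_partial_correlation(conditioning_set(ds, 1, 2, b)))
  }, numeric(1))
  expect_equal(as.numeric(w), mean(per_block), tolerance = 1e-12)
  expect_equal(as.numeric(functional_weight(ds, 2, 1)), as.numeric(w),
               tolerance = 1e-12)
})

test_that("null populations give weights centred on zero", {
  proto <- generate_protocol(n_blocks = 4, presentation_frames = 15,
                             grey_frames = 10, seed = 31)
  tun <- make_tuning(25, tuned_fraction = 0, stim_gain = 0, seed = 32)
  sim <- simulate_population(proto, empty_coupling(25), tun, seed = 33)
  g <- build_functional_graph(sim$dataset)
  expect_lt(abs(mean(g$edges$weight)), 0.05)
})

test_that("functional lag recovers exact shifts and breaks ties as documented", {
  set.seed(104)
  base <- as.numeric(stats::filter(rnorm(500), 0.9, method = "recursive"))
  mx <- base[51:450]
  my2 <- base[49:448]   # y lags x by 2 frames
  cc <- cross_correlogram(mx, my2, max_lag = 5)
  expect_equal(popcoupling:::.argmax_lag(cc, -5:5), 2)
  cc0 <- cross_correlogram(mx, mx, max_lag = 5)
  expect_equal(popcoupling:::.argmax_lag(cc0, -5:5), 0)
  # ties at equal |lag| resolve to the positive lag; smallest |lag| wins
  expect_equal(popcoupling:::.argmax_lag(c(1, 2, 1, 2, 1), -2:2), 1)
  expect_equal(popcoupling:::.argmax_lag(rep(1, 5), -2:2), 0)
  expect_error(cross_correlogram(rep(1, 100), mx[1:100]), "constant")
})

test_that("cross-correlogram matches a brute-force lag scan", {
  set.seed(105)
  mx <- as.numeric(stats::filter(rnorm(300), 0.8, method = "recursive"))
  my <- as.numeric(stats::filter(rnorm(300), 0.8, method = "recursive"))
  cc <- cross_correlogram(mx, my, max_lag = 17)
  brute <- vapply(-17:17, function(l) {
    n <- length(mx)
    if (l >= 0) cor(mx[1:(n - l)], my[(1 + l):n])
    else cor(mx[(1 - l):n], my[1:(n + l)])
  }, numeric(1))
  expect_equal(unname(cc), brute, tolerance = 1e-12)
})

test_that("all-pair lag matrix agrees with the per-pair scan", {
  ds <- small_sim()$dataset
  lags <- popcoupling:::.pair_lag_matrix(ds, max_lag = 17)
  for (pair in list(c(1, 2), c(3, 9), c(5, 20))) {
    expect_equal(lags[pair[1], pair[2]],
                 functional_lag(ds, pair[1], pair[2], max_lag = 17))
  }
})

test_that("graph has one edge per pair and a quartile-consistent strong set", {
  g <- small_graph()
  expect_equal(nrow(g$edges), choose(30, 2))
  aw <- abs(g$edges$weight)
  cut <- stats::quantile(aw, 0.75, names = FALSE)
  expect_equal(g$edges$strong, aw >= cut)
  expect_equal(sum(g$edges$strong), sum(sort(aw, decreasing = TRUE) >= cut))
  # bidirectional edges are exactly the lag-0 edges
  expect_equal(g$edges$direction == "bidirectional", g$edges$lag_signed == 0L)
  expect_error(build_functional_graph(separable_dataset(n_neurons = 2)),
               ">= 3 neurons")
})

test_that("vectorized pair weights agree with the per-pair path", {
  ds <- small_sim()$dataset
  wm <- popcoupling:::.pair_weight_matrix(ds)
  for (pair in list(c(1, 2), c(4, 17), c(10, 30))) {
    expect_equal(wm[pair[1], pair[2]],
                 as.numeric(functional_weight(ds, pair[1], pair[2])),
                 tolerance = 1e-10)
  }
})

test_that("functional groups follow edge direction and bidirectionality", {
  g <- small_graph()
  e <- g$edges
  # a directed edge contributes its source to the target's group only
  fw <- which(e$direction == "a->b")[1]
  expect_true(e$a[fw] %in% functional_group(g, e$b[fw]))
  bi <- which(e$direction == "bidirectional")
  if (length(bi) > 0) {
    expect_true(e$a[bi[1]] %in% functional_group(g, e$b[bi[1]]))
    expect_true(e$b[bi[1]] %in% functional_group(g, e$a[bi[1]]))
  }
  # recount group sizes from the edge list
  orient <- popcoupling:::.edge_orientations(e)
  for (i in c(1, 15, 30)) {
    expect_setequal(functional_group(g, i),
                    unique(orient$source[orient$target == i]))
  }
})

test_that("coupling matrices place weights per incoming edge and lag", {
  g <- small_graph()
  wl <- coupling_matrices(g, lags = c(0L, 1L))
  e <- g$edges
  l1 <- e[e$lag == 1L & !is.na(e$lag_signed), ][1, ]
  src <- if (l1$lag_signed > 0) l1$a else l1$b
  tgt <- if (l1$lag_signed > 0) l1$b else l1$a
  expect_equal(wl[["1"]][src, tgt], l1$weight)
  expect_equal(wl[["1"]][tgt, src], 0)
  bi <- e[e$lag == 0L & !is.na(e$lag_signed), ][1, ]
  expect_equal(wl[["0"]][bi$a, bi$b], bi$weight)
  expect_equal(wl[["0"]][bi$b, bi$a], bi$weight)
  ss <- sign_split_matrices(g)
  expect_true(all(ss$positive@x > 0))
  expect_true(all(ss$negative@x < 0))
})

test_that("graph TSV round trip preserves edges", {
  g <- small_graph()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_graph(g, path)
  g2 <- read_graph(path, n_neurons = g$n_neurons)
  cols <- c("a", "b", "weight", "lag_signed", "strong")
  expect_equal(g2$edges[, cols], g$edges[, cols], tolerance = 1e-12,
               ignore_attr = TRUE)
})
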