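# Functional network estimation: trial-wise partial-correlation weights,
# cross-correlogram lags and directions, strong-edge identification and
# functional groups.

# Ridge guard before inverting a correlation matrix: near-duplicate series
# otherwise make the precision matrix explode.
.safe_precision <- function(omega, ridge = 1e-8, cond_limit = 1e12) {
  degenerate <- FALSE
  if (!all(is.finite(omega)) || kappa(omega, exact = TRUE) > cond_limit) {
    omega <- omega + diag(ridge, nrow(omega))
    degenerate <- TRUE
  }
  p <- tryCatch(solve(omega), error = function(e) NULL)
  if (is.null(p)) {
    p <- tryCatch(solve(omega + diag(ridge, nrow(omega))),
                  error = function(e) NULL)
    degenerate <- TRUE
  }
  list(precision = p, degenerate = degenerate)
}

#' Trial-wise partial correlation from a conditioning set
#'
#' Computes the partial correlation between the first two series of a
#' conditioning set, given the remaining series, from the precision of the
#' full correlation matrix: `rho = -P[1,2] / sqrt(P[1,1] * P[2,2])` with
#' `P = solve(cor(series))`. For a pair of neurons within one trial, the
#' canonical conditioning set is: trial trace of x, trial trace of y, the
#' leave-one-out mean traces of x and y (averaged over all other trials),
#' and the within-trial population mean excluding x and y — conditioning out
#' stimulus-locked and population-wide (running-driven) coactivity, leaving
#' a noise-correlation-like coupling measure.
#'
#' @param cond numeric matrix with >= 10 rows whose columns are the series;
#'   the pair of interest must be columns 1 and 2.
#' @return the partial correlation in `[-1, 1]`. If the correlation matrix
#'   is numerically singular even after a ridge fallback, returns 0 with
#'   attribute `degenerate = TRUE`.
#' @export
trial_partial_correlation <- function(cond) {
  cond <- as.matrix(cond)
  if (nrow(cond) < 10L) stop_invalid("conditioning series must have length >= 10")
  v <- apply(cond, 2L, stats::var)
  if (any(v < .Machine$double.eps))
    stop_invalid("degenerate conditioning set: zero-variance series")
  omega <- stats::cor(cond)
  sp <- .safe_precision(omega)
  if (is.null(sp$precision)) return(structure(0, degenerate = TRUE))
  p <- sp$precision
  rho <- -p[1L, 2L] / sqrt(p[1L, 1L] * p[2L, 2L])
  rho <- min(1, max(-1, rho))
  if (sp$degenerate) attr(rho, "degenerate") <- TRUE
  rho
}

#' Build the conditioning set for a neuron pair in one block
#'
#' @param dataset an [fl_dataset()].
#' @param x,y neuron indices (1-based).
#' @param block block index.
#' @return numeric matrix with columns `x`, `y`, `loo_mean_x`, `loo_mean_y`,
#'   `pop_mean` (the within-block population mean excluding x and y), rows
#'   aligned by within-block frame position.
#' @export
conditioning_set <- function(dataset, x, y, block) {
  idx <- block_frame_index(dataset)
  if (length(idx) < 2L) stop_invalid("need >= 2 blocks for leave-one-out means")
  if (dataset$n_neurons < 3L) stop_invalid("need >= 3 neurons for the population mean")
  cur <- idx[[block]]
  others <- idx[-block]
  loo <- 0
  for (i in others) loo <- loo + dataset$traces[c(x, y), i, drop = FALSE]
  loo <- loo / length(others)
  pop <- (colSums(dataset$traces[, cur, drop = FALSE]) -
            dataset$traces[x, cur] - dataset$traces[y, cur]) / (dataset$n_neurons - 2L)
  cbind(x = dataset$traces[x, cur], y = dataset$traces[y, cur],
        loo_mean_x = loo[1L, ], loo_mean_y = loo[2L, ], pop_mean = pop)
}

#' Functional weight of a neuron pair
#'
#' The trial-averaged partial correlation: [trial_partial_correlation()] is
#' evaluated per block with the block's conditioning set, and the values are
#' averaged across blocks. Blocks whose conditioning sets are degenerate are
#' excluded from the mean; if all blocks are degenerate the weight is 0 with
#' attribute `degenerate = TRUE`.
#'
#' @inheritParams conditioning_set
#' @return the functional weight (symmetric in `x`, `y`).
#' @export
functional_weight <- function(dataset, x, y) {
  idx <- block_frame_index(dataset)
  if (length(idx) < 2L) stop_invalid("need >= 2 blocks")
  vals <- numeric(0)
  for (b in seq_along(idx)) {
    rho <- tryCatch(trial_partial_correlation(conditioning_set(dataset, x, y, b)),
                    error = function(e) NULL)
    if (!is.null(rho) && is.null(attr(rho, "degenerate")))
      vals <- c(vals, as.numeric(rho))
  }
  if (length(vals) == 0L) return(structure(0, degenerate = TRUE))
  mean(vals)
}

#' Cross-correlogram of two series
#'
#' Pearson correlation of mean-subtracted overlapping segments at each
#' integer lag in `[-max_lag, max_lag]`. Positive lags mean the second
#' series follows the first.
#'
#' @param mx,my numeric series of equal length.
#' @param max_lag maximum absolute lag in frames.
#' @return named numeric vector of length `2 * max_lag + 1`.
#' @export
cross_correlogram <- function(mx, my, max_lag = 17L) {
  n <- length(mx)
  stopifnot(length(my) == n, n > max_lag + 2L)
  if (stats::sd(mx) < .Machine$double.eps || stats::sd(my) < .Machine$double.eps)
    stop_invalid("degenerate input: constant mean trace")
  lags <- seq(-max_lag, max_lag)
  vals <- vapply(lags, function(l) {
    if (l >= 0L) stats::cor(mx[seq_len(n - l)], my[seq_len(n - l) + l])
    else stats::cor(mx[seq_len(n + l) - l], my[seq_len(n + l)])
  }, numeric(1))
  names(vals) <- lags
  vals
}

# Correlogram argmax on the coactivity magnitude |r(l)|: for negatively
# coupled pairs the signed maximum sits at an uninformative lag (the true
# lag is the signed *minimum*), so the peak of |r| is the lag of maximal
# coactivity for either sign; it reduces to the signed rule for positively
# correlated pairs. Ties: smallest |lag| first, then the positive lag.
.argmax_lag <- function(vals, lags, tol = 1e-12) {
  av <- abs(vals)
  cand <- which(av >= max(av) - tol)
  l <- lags[cand]
  l <- l[order(abs(l), -sign(l))]
  l[1L]
}

#' Functional lag of a neuron pair
#'
#' The signed integer lag maximizing the coactivity magnitude (the absolute
#' normalized cross-correlation) of the two neurons' block-mean traces; for
#' positively correlated pairs this is the lag of the correlogram maximum,
#' and for negatively coupled pairs it is the lag of the (signed) minimum,
#' which is where their coactivity actually peaks. A positive lag means `y`
#' follows `x` (edge directed x -> y); negative means `x` follows `y`; zero
#' means the coupling is bidirectional. Ties go to the smallest absolute
#' lag, then to the positive lag.
#'
#' @inheritParams conditioning_set
#' @param max_lag maximum absolute lag scanned (frames).
#' @return a signed integer lag.
#' @export
functional_lag <- function(dataset, x, y, max_lag = 17L) {
  m <- block_mean_traces(dataset)
  vals <- cross_correlogram(m[x, ], m[y, ], max_lag)
  .argmax_lag(vals, seq(-max_lag, max_lag))
}

# ---- vectorized all-pair estimators -----------------------------------------

# All-pair functional weight matrix. Per block, every pairwise covariance
# needed for the 5x5 conditioning-set correlation matrix is assembled from a
# handful of N x N cross-covariance matrices, so the per-pair work reduces to
# a 5x5 inversion.
.pair_weight_matrix <- function(dataset) {
  idx <- block_frame_index(dataset)
  n <- dataset$n_neurons
  nb <- length(idx)
  if (nb < 2L) stop_invalid("need >= 2 blocks")
  if (n < 3L) stop_invalid("need >= 3 neurons")
  tb <- length(idx[[1L]])
  q <- 1 / (n - 2)

  s_tot <- 0
  for (i in idx) s_tot <- s_tot + dataset$traces[, i, drop = FALSE]

  wsum <- matrix(0, n, n)
  wcnt <- matrix(0L, n, n)
  for (b in seq_len(nb)) {
    xb <- dataset$traces[, idx[[b]], drop = FALSE]
    lb <- (s_tot - xb) / (nb - 1L)
    pv <- colSums(xb)
    xc <- xb - rowMeans(xb)
    lc <- lb - rowMeans(lb)
    pc <- pv - mean(pv)
    dn <- tb - 1
    A <- tcrossprod(xc) / dn          # cov(x_i, x_j)
    Bm <- tcrossprod(xc, lc) / dn     # cov(x_i, loo_j)
    D <- tcrossprod(lc) / dn          # cov(loo_i, loo_j)
    u <- as.numeric(xc %*% pc) / dn   # cov(x_i, popsum)
    w <- as.numeric(lc %*% pc) / dn   # cov(loo_i, popsum)
    vp <- sum(pc^2) / dn

    dA <- diag(A)
    for (x in seq_len(n - 1L)) {
      axx <- dA[x]
      for (y in (x + 1L):n) {
        axy <- A[x, y]; ayy <- dA[y]
        cm <- matrix(0, 5L, 5L)
        cm[1, 1] <- axx
        cm[1, 2] <- axy
        cm[1, 3] <- Bm[x, x]
        cm[1, 4] <- Bm[x, y]
        cm[1, 5] <- q * (u[x] - axx - axy)
        cm[2, 2] <- ayy
        cm[2, 3] <- Bm[y, x]
        cm[2, 4] <- Bm[y, y]
        cm[2, 5] <- q * (u[y] - axy - ayy)
        cm[3, 3] <- D[x, x]
        cm[3, 4] <- D[x, y]
        cm[3, 5] <- q * (w[x] - Bm[x, x] - Bm[y, x])
        cm[4, 4] <- D[y, y]
        cm[4, 5] <- q * (w[y] - Bm[x, y] - Bm[y, y])
        cm[5, 5] <- q * q * (vp + axx + ayy + 2 * axy - 2 * u[x] - 2 * u[y])
        cm[lower.tri(cm)] <- t(cm)[lower.tri(cm)]
        dv <- diag(cm)
        if (any(dv < .Machine$double.eps)) next
        omega <- cm / sqrt(outer(dv, dv))
        sp <- .safe_precision(omega)
        if (is.null(sp$precision)) next
        p <- sp$precision
        rho <- -p[1L, 2L] / sqrt(p[1L, 1L] * p[2L, 2L])
        if (!is.finite(rho)) next
        rho <- min(1, max(-1, rho))
        wsum[x, y] <- wsum[x, y] + rho
        wcnt[x, y] <- wcnt[x, y] + 1L
      }
    }
  }
  wm <- matrix(0, n, n)
  ok <- wcnt > 0L
  wm[ok] <- wsum[ok] / wcnt[ok]
  wm[lower.tri(wm)] <- t(wm)[lower.tri(wm)]
  attr(wm, "n_degenerate_pairs") <- sum(wcnt[upper.tri(wcnt)] == 0L)
  wm
}

# All-pair signed functional lags from block-mean traces. Returns an N x N
# matrix where entry [x, y] (x < y) is the signed lag of the pair under the
# convention that positive means y follows x.
.pair_lag_matrix <- function(dataset, max_lag = 17L) {
  m <- block_mean_traces(dataset)
  n <- nrow(m); tb <- ncol(m)
  stopifnot(tb > max_lag + 2L)
  lags <- seq(0L, max_lag)
  # corr_arr[, , k]: correlation of x(t) with y(t + lag_k) for all pairs
  corr_pos <- array(NA_real_, c(n, n, max_lag + 1L))
  for (k in seq_along(lags)) {
    l <- lags[k]
    xi <- seq_len(tb - l)
    xm <- m[, xi, drop = FALSE]
    ym <- m[, xi + l, drop = FALSE]
    xc <- xm - rowMeans(xm); yc <- ym - rowMeans(ym)
    nx <- sqrt(rowSums(xc^2)); ny <- sqrt(rowSums(yc^2))
    nx[nx == 0] <- NA_real_; ny[ny == 0] <- NA_real_
    corr_pos[, , k] <- tcrossprod(xc, yc) / outer(nx, ny)
  }
  all_lags <- seq(-max_lag, max_lag)
  lag_mat <- matrix(NA_integer_, n, n)
  vals <- numeric(2L * max_lag + 1L)
  for (x in seq_len(n - 1L)) {
    for (y in (x + 1L):n) {
      # negative lag -l for pair (x, y) equals +l correlation of (y, x)
      vals[seq_len(max_lag)] <- corr_pos[y, x, (max_lag + 1L):2L]
      vals[(max_lag + 1L):(2L * max_lag + 1L)] <- corr_pos[x, y, ]
      if (anyNA(vals)) next
      lag_mat[x, y] <- .argmax_lag(vals, all_lags)
    }
  }
  lag_mat
}

#' Build the functional graph of a dataset
#'
#' Estimates one functional edge per unordered neuron pair: the weight is
#' the trial-averaged partial correlation, the lag and direction come from
#' the cross-correlogram of block-mean traces. Strong edges are those whose
#' weight magnitude lies in the pooled top quartile (inclusive of ties at
#' the 75th-percentile magnitude). `lag_filter` restricts which lags
#' contribute coupling features downstream (the all-lag control passes
#' `0:max_lag`).
#'
#' @param dataset an [fl_dataset()] with >= 3 neurons and >= 2 blocks.
#' @param max_lag maximum absolute cross-correlogram lag (frames).
#' @param lag_filter integer set of lags used when assembling per-neuron
#'   incoming-weight vectors (default `c(0, 1)`).
#' @return an object of class `functional_graph`: fields `n_neurons`,
#'   `edges` (data frame `a`, `b`, `weight`, `lag`, `lag_signed`,
#'   `direction`, `strong`), `max_lag`, `lag_filter`, `strong_cut`.
#' @export
build_functional_graph <- function(dataset, max_lag = 17L, lag_filter = c(0L, 1L)) {
  if (dataset$n_neurons < 3L)
    stop_invalid("functional graph requires >= 3 neurons")
  wm <- .pair_weight_matrix(dataset)
  lm_ <- .pair_lag_matrix(dataset, max_lag)
  n <- dataset$n_neurons
  ut <- which(upper.tri(wm), arr.ind = TRUE)
  a <- ut[, 1L]; b <- ut[, 2L]
  weight <- wm[ut]
  lag_signed <- lm_[ut]
  direction <- ifelse(is.na(lag_signed), NA_character_,
                      ifelse(lag_signed == 0L, "bidirectional",
                             ifelse(lag_signed > 0L, "a->b", "b->a")))
  edges <- data.frame(a = a, b = b, weight = weight,
                      lag = abs(lag_signed), lag_signed = lag_signed,
                      direction = direction, stringsAsFactors = FALSE)
  strong_cut <- stats::quantile(abs(edges$weight), 0.75, names = FALSE)
  edges$strong <- abs(edges$weight) >= strong_cut
  structure(list(n_neurons = n, edges = edges, max_lag = as.integer(max_lag),
                 lag_filter = as.integer(lag_filter), strong_cut = strong_cut,
                 n_degenerate_pairs = attr(wm, "n_degenerate_pairs")),
            class = "functional_graph")
}

#' @export
print.functional_graph <- function(x, ...) {
  e <- x$edges
  cat(sprintf("Functional graph: %d neurons, %d edges (%d strong, |w| >= %.4f)\n",
              x$n_neurons, nrow(e), sum(e$strong), x$strong_cut))
  cat(sprintf("  bidirectional: %.1f%%; lags 0-1: %.1f%%; lag filter: {%s}\n",
              100 * mean(e$lag == 0L, na.rm = TRUE),
              100 * mean(e$lag <= 1L, na.rm = TRUE),
              paste(x$lag_filter, collapse = ",")))
  invisible(x)
}

# Directed incidence of an edge row: list of (source, target) pairs the edge
# contributes; bidirectional edges contribute both orientations.
.edge_orientations <- function(edges) {
  bi <- edges$lag_signed == 0L
  fw <- edges$lag_signed > 0L
  src <- c(edges$a[bi], edges$b[bi], edges$a[fw], edges$b[!bi & !fw])
  tgt <- c(edges$b[bi], edges$a[bi], edges$b[fw], edges$a[!bi & !fw])
  w <- c(edges$weight[bi], edges$weight[bi], edges$weight[fw], edges$weight[!bi & !fw])
  lag <- c(edges$lag[bi], edges$lag[bi], edges$lag[fw], edges$lag[!bi & !fw])
  data.frame(source = src, target = tgt, weight = w, lag = lag)
}

#' Per-lag coupling weight matrices
#'
#' Assembles, for each lag `l` in `lags`, the sparse N x N matrix `W_l` with
#' `W_l[k, i]` equal to the functional weight of an edge directed k -> i
#' with lag `l` (bidirectional lag-0 edges are counted once in each
#' direction). Column `i` of `W_l` is the incoming-weight vector of neuron
#' `i` at that lag.
#'
#' @param graph a [build_functional_graph()] result.
#' @param lags integer lags (defaults to the graph's lag filter).
#' @return named list of `dgCMatrix`, one per lag.
#' @export
coupling_matrices <- function(graph, lags = graph$lag_filter) {
  orient <- .edge_orientations(graph$edges[!is.na(graph$edges$lag_signed), ])
  out <- lapply(lags, function(l) {
    o <- orient[orient$lag == l, , drop = FALSE]
    Matrix::sparseMatrix(i = o$source, j = o$target, x = o$weight,
                         dims = c(graph$n_neurons, graph$n_neurons))
  })
  names(out) <- as.character(lags)
  out
}

#' Sign-split coupling matrices
#'
#' Incoming-weight matrices split by weight sign, pooling all lags and
#' treating them as lag 0 (the construction used by the positive-only and
#' negative-only model variants).
#'
#' @param graph a [build_functional_graph()] result.
#' @return list with sparse matrices `positive` and `negative` (the negative
#'   matrix carries the signed, negative weights).
#' @export
sign_split_matrices <- function(graph) {
  orient <- .edge_orientations(graph$edges[!is.na(graph$edges$lag_signed), ])
  mk <- function(o) Matrix::sparseMatrix(i = o$source, j = o$target, x = o$weight,
                                         dims = c(graph$n_neurons, graph$n_neurons))
  list(positive = mk(orient[orient$weight > 0, , drop = FALSE]),
       negative = mk(orient[orient$weight < 0, , drop = FALSE]))
}

#' Functional group of a neuron
#'
#' The set of neurons with functional edges directed toward `target`
#' (sources of incoming edges); bidirectional edges contribute each
#' endpoint to the other's group.
#'
#' @param graph a [build_functional_graph()] result.
#' @param target neuron index.
#' @param strong_only if `TRUE`, restrict to strong edges.
#' @return integer vector of source neurons.
#' @export
functional_group <- function(graph, target, strong_only = FALSE) {
  if (target > graph$n_neurons) stop_invalid("`target` exceeds the population size")
  e <- graph$edges[!is.na(graph$edges$lag_signed), ]
  if (strong_only) e <- e[e$strong, , drop = FALSE]
  orient <- .edge_orientations(e)
  sort(unique(orient$source[orient$target == target]))
}

#' Export a functional graph as TSV
#'
#' One row per unordered pair with columns `neuron_a`, `neuron_b`, `weight`,
#' `lag`, `direction`, `is_strong`; neuron ids are 0-based in the file.
#'
#' @param graph a [build_functional_graph()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_graph <- function(graph, path) {
  e <- graph$edges
  out <- data.frame(neuron_a = e$a - 1L, neuron_b = e$b - 1L,
                    weight = e$weight, lag = e$lag_signed,
                    direction = e$direction, is_strong = e$strong)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Import a functional graph from TSV
#'
#' @param path a file written by [write_graph()].
#' @param n_neurons population size; inferred from the ids if omitted.
#' @param lag_filter lag filter to attach (default `c(0, 1)`).
#' @return a `functional_graph`.
#' @export
read_graph <- function(path, n_neurons = NULL, lag_filter = c(0L, 1L)) {
  d <- utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  edges <- data.frame(a = d$neuron_a + 1L, b = d$neuron_b + 1L,
                      weight = d$weight, lag = abs(d$lag), lag_signed = d$lag,
                      direction = d$direction, strong = d$is_strong,
                      stringsAsFactors = FALSE)
  n <- n_neurons %||% max(edges$a, edges$b)
  structure(list(n_neurons = n, edges = edges,
                 max_lag = max(edges$lag, na.rm = TRUE),
                 lag_filter = as.integer(lag_filter),
                 strong_cut = min(abs(edges$weight[edges$strong])),
                 n_degenerate_pairs = NA_integer_),
            class = "functional_graph")
}
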