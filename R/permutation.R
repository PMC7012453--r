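# Permutation stress tests of the functional graph: shuffle strong weights
# (topology-preserving) or strong edges (topology-changing) and measure the
# effect on the unrestricted model's prediction error.

#' Enumerate the strong edges of a graph
#'
#' One tuple per strong edge (pooled top quartile of weight magnitudes),
#' carrying the source, target, weight and signed lag. Bidirectional edges
#' are enumerated once with the lower-indexed neuron as source.
#'
#' @param graph a [build_functional_graph()] result.
#' @return data frame `source`, `target`, `weight`, `lag` (nonnegative; 0
#'   marks a bidirectional edge), `row` (row index into `graph$edges`).
#' @export
strong_edge_list <- function(graph) {
  e <- graph$edges
  k <- which(e$strong & !is.na(e$lag_signed))
  fw <- e$lag_signed[k] >= 0L
  data.frame(source = ifelse(fw, e$a[k], e$b[k]),
             target = ifelse(fw, e$b[k], e$a[k]),
             weight = e$weight[k],
             lag = abs(e$lag_signed[k]),
             row = k)
}

#' Permute the strong weights of a graph
#'
#' Applies a uniformly random permutation to the (weight, lag) pairs of the
#' strong edges, jointly, leaving the underlying source-target pairs (and
#' all non-strong edges) untouched. Edge direction follows the permuted
#' lag. Preserves the strong subgraph's topology and the pooled multiset of
#' strong (weight, lag) pairs.
#'
#' @param graph a [build_functional_graph()] result.
#' @param seed integer seed; ignored when `perm` is given.
#' @param perm optional explicit permutation of `seq_len(K)` (e.g. the
#'   identity).
#' @return a new `functional_graph`.
#' @export
permute_strong_weights <- function(graph, seed = NULL, perm = NULL) {
  e <- graph$edges
  k <- which(e$strong & !is.na(e$lag_signed))
  if (length(k) < 2L) {
    warning("fewer than 2 strong edges; returning graph unchanged", call. = FALSE)
    return(graph)
  }
  if (is.null(perm)) perm <- with_seed(seed, sample(length(k)))
  e$weight[k] <- e$weight[k][perm]
  e$lag_signed[k] <- e$lag_signed[k][perm]
  e$lag[k] <- abs(e$lag_signed[k])
  e$direction[k] <- ifelse(e$lag_signed[k] == 0L, "bidirectional",
                           ifelse(e$lag_signed[k] > 0L, "a->b", "b->a"))
  graph$edges <- e
  graph
}

#' Permute the strong edges of a graph
#'
#' Applies a uniformly random permutation to the terminal neurons of the
#' strong edges, keeping each weight and lag attached to its source neuron;
#' functional-group memberships change. Self-edges created by the
#' permutation are repaired by bounded random target swaps (which preserve
#' the terminal-neuron multiset). Non-strong edges are untouched; a
#' permuted strong edge may land on a pair that already carries an edge, in
#' which case both contribute to the coupling vectors.
#'
#' @inheritParams permute_strong_weights
#' @param max_retries cap on self-edge repair swaps.
#' @return a new `functional_graph` with the strong rows rewired.
#' @export
permute_strong_edges <- function(graph, seed = NULL, perm = NULL,
                                 max_retries = 1000L) {
  sel <- strong_edge_list(graph)
  k <- nrow(sel)
  if (k < 2L) {
    warning("fewer than 2 strong edges; returning graph unchanged", call. = FALSE)
    return(graph)
  }
  tgt <- with_seed(seed, {
    tg <- sel$target[if (is.null(perm)) sample(k) else perm]
    # repair self-edges by swapping targets with a random other position
    for (r in seq_len(max_retries)) {
      bad <- which(tg == sel$source)
      if (length(bad) == 0L) break
      a <- bad[1L]; b <- sample(k, 1L)
      if (b != a && tg[b] != sel$source[a] && tg[a] != sel$source[b]) {
        tmp <- tg[a]; tg[a] <- tg[b]; tg[b] <- tmp
      }
    }
    if (any(tg == sel$source))
      stop_invalid("could not repair self-edges in the edge permutation")
    tg
  })
  # rebuild the strong rows: same sources, permuted terminals
  e <- graph$edges
  keep <- e[-sel$row, , drop = FALSE]          # non-strong edges unchanged
  a <- pmin(sel$source, tgt); b <- pmax(sel$source, tgt)
  lag_signed <- ifelse(sel$lag == 0L, 0L,
                       ifelse(sel$source < tgt, sel$lag, -sel$lag))
  new_rows <- data.frame(a = a, b = b, weight = sel$weight,
                         lag = abs(lag_signed), lag_signed = lag_signed,
                         direction = ifelse(lag_signed == 0L, "bidirectional",
                                            ifelse(lag_signed > 0L, "a->b", "b->a")),
                         strong = TRUE, stringsAsFactors = FALSE)
  graph$edges <- rbind(keep, new_rows)
  graph
}

#' Sensitivity of model error to graph permutations
#'
#' For each of `n_permutations` seeded permutations of the graph's strong
#' weights or strong edges, rebuilds the coupling features from the permuted
#' graph and measures the per-neuron percent change in MSE of the
#' unrestricted model. Without refitting, the original coefficients are kept
#' and the change is measured on the *training* frames (refitting would let
#' the coefficients absorb the shuffle); with refitting, coefficients are
#' re-estimated on the training frames and the change is measured on the
#' test frames.
#'
#' @param dataset an [fl_dataset()].
#' @param graph the original [build_functional_graph()].
#' @param suite the [run_model_suite()] result holding the fitted
#'   unrestricted models and the split.
#' @param scheme `"weights"` or `"edges"`.
#' @param n_permutations number of permutations (the study design uses 1000
#'   without refit and 100 with refit).
#' @param refit refit coefficients after each permutation.
#' @param seed root seed; permutation `k` uses `seed + k`, so individual
#'   permutations are reproducible in isolation.
#' @return an object of class `permutation_result`: `pct_change`
#'   (n_permutations x neurons matrix), `summaries` (median of per-
#'   permutation medians and IQR of medians without refit; grand median and
#'   IQR with refit), `scheme`, `refit`, `seed`.
#' @export
permutation_mse_change <- function(dataset, graph, suite,
                                   scheme = c("weights", "edges"),
                                   n_permutations = if (refit) 100L else 1000L,
                                   refit = FALSE, seed = 1L) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(suite, "model_comparison"))
  if (suite$settings$running_model != "rotary" ||
      suite$settings$stimulus_model != "average")
    stop_invalid("permutation analysis expects the average-response / rotary suite")
  n <- dataset$n_neurons
  coefs <- t(vapply(suite$fits, function(f) f$coef, numeric(5L)))
  stopifnot(identical(colnames(coefs),
                      c("(Intercept)", "coupling0", "coupling1", "stimulus", "running")))
  frames <- if (refit) suite$eval_frames else suite$fit_frames
  base_mse <- if (refit) suite$test_mse else suite$train_mse
  y <- dataset$traces[, frames, drop = FALSE]
  smat <- suite$stim_matrix_fit[, frames, drop = FALSE]
  v <- running_term(dataset, "rotary")[frames]

  # per-neuron %MSE change given permuted coupling features
  eval_perm <- function(pg) {
    f0 <- coupling_feature(dataset, coupling_matrices(pg, 0L)[[1L]], 0L)$values
    f1 <- coupling_feature(dataset, coupling_matrices(pg, 1L)[[1L]], 1L)$values
    if (!refit) {
      pred <- coefs[, 1L] + coefs[, 2L] * f0[, frames, drop = FALSE] +
        coefs[, 3L] * f1[, frames, drop = FALSE] +
        coefs[, 4L] * smat + outer(coefs[, 5L], v)
      mse <- rowMeans((y - pred)^2)
    } else {
      fitf <- suite$fit_frames
      mse <- vapply(seq_len(n), function(i) {
        x <- cbind(coupling0 = f0[i, ], coupling1 = f1[i, ],
                   stimulus = suite$stim_matrix_fit[i, ],
                   running = running_term(dataset, "rotary"))
        fit <- fit_lm(x, dataset$traces[i, ], fitf)
        evaluate_mse(fit, x, dataset$traces[i, ], frames)
      }, numeric(1))
    }
    100 * (mse - base_mse) / base_mse
  }

  pct <- matrix(NA_real_, n_permutations, n)
  for (p in seq_len(n_permutations)) {
    pg <- if (scheme == "weights") permute_strong_weights(graph, seed = seed + p)
    else permute_strong_edges(graph, seed = seed + p)
    pct[p, ] <- eval_perm(pg)
  }

  per_perm_median <- apply(pct, 1L, stats::median)
  summaries <- if (!refit) {
    list(median_of_medians = stats::median(per_perm_median),
         iqr_of_medians = iqr_of(per_perm_median))
  } else {
    list(grand_median = stats::median(as.numeric(pct)),
         grand_iqr = iqr_of(as.numeric(pct)))
  }
  structure(list(pct_change = pct, per_perm_median = per_perm_median,
                 summaries = summaries, scheme = scheme, refit = refit,
                 n_permutations = n_permutations, seed = seed),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("Permutation analysis: %s scheme, %d permutations, %s\n",
              x$scheme, x$n_permutations,
              if (x$refit) "refit (test MSE)" else "no refit (training MSE)"))
  for (nm in names(x$summaries))
    cat(sprintf("  %s: %+.2f%%\n", nm, x$summaries[[nm]]))
  invisible(x)
}

#' Write a permutation result as JSON
#'
#' @param result a [permutation_mse_change()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_permutation_result <- function(result, path) {
  jsonlite::write_json(
    list(scheme = result$scheme, refit = result$refit,
         n_permutations = result$n_permutations, seed = result$seed,
         summaries = result$summaries,
         pct_change = result$pct_change),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
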