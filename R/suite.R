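# The encoding-model ladder: fits the unrestricted coupled LM and its
# restricted variants per neuron on a train split and tabulates test-set
# MSE changes.

# Within-block frame position (1-based).
within_block_pos <- function(dataset) {
  stats::ave(seq_len(dataset$n_frames), dataset$block, FUN = seq_along)
}

# Coupling feature at one lag for all neurons: values[i, t] = column i of W
# dotted with r(t - lag). Lagged features never cross block boundaries;
# frames without a valid lagged predecessor are marked invalid.
coupling_feature <- function(dataset, w, lag) {
  r <- dataset$traces
  t_total <- ncol(r)
  if (lag == 0L) {
    vals <- as.matrix(Matrix::crossprod(w, r))
    valid <- rep(TRUE, t_total)
  } else {
    pos <- within_block_pos(dataset)
    valid <- pos > lag
    rs <- matrix(0, nrow(r), t_total)
    rs[, valid] <- r[, which(valid) - lag]
    vals <- as.matrix(Matrix::crossprod(w, rs))
    vals[, !valid] <- 0
  }
  list(values = vals, valid = valid)
}

.core_variants <- c("unrestricted", "stim_restricted", "run_restricted",
                    "coupling_restricted", "lag0_only", "lag1_only",
                    "positive_only", "negative_only")
.extra_variants <- c("all_lag", "nonneg", "reciprocal", "cube")

# Which feature columns each variant uses (c0/c1 = lag-0/lag-1 coupling,
# cp/cn = sign-split coupling, al = all-lag coupling block, s/v = stimulus
# and running terms).
.variant_terms <- list(
  unrestricted = c("c0", "c1", "s", "v"),
  stim_restricted = c("c0", "c1", "v"),
  run_restricted = c("c0", "c1", "s"),
  coupling_restricted = c("s", "v"),
  lag0_only = c("c0", "s", "v"),
  lag1_only = c("c1", "s", "v"),
  positive_only = c("cp", "s", "v"),
  negative_only = c("cn", "s", "v"),
  all_lag = c("al", "s", "v"),
  nonneg = c("c0", "c1", "s", "v"),
  reciprocal = c("c0", "c1", "s", "v"),
  cube = c("c0", "c1", "s", "v")
)

#' Fit the encoding-model ladder and compare variants
#'
#' Fits, for every neuron, the unrestricted coupled linear model (lag-0 and
#' lag-1 coupling features with measured weights, stimulus term, running
#' term) and each requested restricted or control variant on the train
#' split, evaluates test-set MSE on the requested frame subsets, and
#' tabulates the percent change of each variant relative to the
#' unrestricted model evaluated on the same frames.
#'
#' Variants: `unrestricted`, `stim_restricted`, `run_restricted`,
#' `coupling_restricted`, `lag0_only`, `lag1_only`, `positive_only`,
#' `negative_only` (sign-split coupling over all lags treated as lag 0),
#' plus controls `all_lag` (coupling at every lag up to the graph's
#' `max_lag`), `nonneg` (nonnegative term coefficients), `reciprocal` and
#' `cube` (nonlinear links).
#'
#' @param dataset an [fl_dataset()].
#' @param graph the [build_functional_graph()] of the same dataset.
#' @param variants character vector of variant names (default: the core
#'   eight).
#' @param split_ratio,granularity,split_mode,seed passed to [split_frames()].
#' @param stimulus_model `"average"` (average response; grey frames carry a
#'   zero stimulus term and stay in the fit) or `"block_averaged"`
#'   (within-presentation dynamics preserved; grey frames are excluded from
#'   fitting and evaluation).
#' @param running_model `"rotary"` or `"population_average"`.
#' @param subsets evaluation frame subsets (see [evaluate_mse()]).
#' @param run_threshold minimum speed counting as running.
#' @return an object of class `model_comparison`: `results` (data frame
#'   `neuron`, `variant`, `subset`, `test_mse`, `pct_change`), `summaries`
#'   (median and IQR of percent change per variant and subset), `fits`
#'   (per-neuron unrestricted fits), `train_mse`, `test_mse` baselines,
#'   `split`, and the settings needed to rebuild features.
#' @export
run_model_suite <- function(dataset, graph, variants = .core_variants,
                            split_ratio = 0.7,
                            granularity = c("block", "presentation"),
                            split_mode = c("earliest", "random"), seed = NULL,
                            stimulus_model = c("average", "block_averaged"),
                            running_model = c("rotary", "population_average"),
                            subsets = "all", run_threshold = 0) {
  granularity <- match.arg(granularity)
  split_mode <- match.arg(split_mode)
  stimulus_model <- match.arg(stimulus_model)
  running_model <- match.arg(running_model)
  bad <- setdiff(variants, c(.core_variants, .extra_variants))
  if (length(bad) > 0L) stop_invalid("unknown variants: ", paste(bad, collapse = ", "))
  if (!"unrestricted" %in% variants) variants <- c("unrestricted", variants)

  n <- dataset$n_neurons
  split <- split_frames(dataset, split_ratio, granularity, seed, split_mode)

  # coupling features from the measured graph
  wl <- coupling_matrices(graph, lags = c(0L, 1L))
  f0 <- coupling_feature(dataset, wl[["0"]], 0L)
  f1 <- coupling_feature(dataset, wl[["1"]], 1L)
  ss <- sign_split_matrices(graph)
  fp <- coupling_feature(dataset, ss$positive, 0L)
  fn <- coupling_feature(dataset, ss$negative, 0L)
  need_all_lag <- "all_lag" %in% variants
  fal <- NULL
  if (need_all_lag) {
    wal <- coupling_matrices(graph, lags = seq(0L, graph$max_lag))
    fal <- lapply(seq_along(wal), function(k) {
      coupling_feature(dataset, wal[[k]], as.integer(names(wal)[k]))
    })
  }

  # stimulus terms
  grate <- dataset$labels != "grey"
  if (stimulus_model == "average") {
    s_fit <- t(vapply(seq_len(n), function(i) {
      stimulus_term_average_response(dataset, i, split$train)
    }, numeric(dataset$n_frames)))
    s_eval <- s_fit
  } else {
    s_fit <- t(vapply(seq_len(n), function(i) {
      stimulus_term_block_averaged(dataset, i, split$train)
    }, numeric(dataset$n_frames)))
    s_eval <- t(vapply(seq_len(n), function(i) {
      stimulus_term_block_averaged(dataset, i, split$test)
    }, numeric(dataset$n_frames)))
  }

  # running term (per neuron when the population average excludes the target)
  v_of <- if (running_model == "rotary") {
    local({
      vrun <- running_term(dataset, "rotary")
      function(i) vrun
    })
  } else {
    function(i) running_term(dataset, "population_average", exclude_neuron = i)
  }

  valid1 <- f1$valid
  fit_core <- intersect(split$train, which(valid1))
  eval_core <- intersect(split$test, which(valid1))
  if (stimulus_model == "block_averaged") {
    fit_core <- intersect(fit_core, which(grate & !is.na(s_fit[1L, ])))
    eval_core <- intersect(eval_core, which(grate & !is.na(s_eval[1L, ])))
  }
  if (need_all_lag) {
    valid_al <- Reduce(`&`, lapply(fal, `[[`, "valid"))
    fit_al <- intersect(fit_core, which(valid_al))
    eval_al <- intersect(eval_core, which(valid_al))
  }

  design <- function(i, variant, which_s) {
    terms <- .variant_terms[[variant]]
    cols <- list()
    if ("c0" %in% terms) cols$coupling0 <- f0$values[i, ]
    if ("c1" %in% terms) cols$coupling1 <- f1$values[i, ]
    if ("cp" %in% terms) cols$coupling_pos <- fp$values[i, ]
    if ("cn" %in% terms) cols$coupling_neg <- fn$values[i, ]
    if ("al" %in% terms) {
      for (k in seq_along(fal)) cols[[paste0("coupling_lag", k - 1L)]] <- fal[[k]]$values[i, ]
    }
    if ("s" %in% terms) {
      sm <- if (which_s == "fit") s_fit else s_eval
      sv <- sm[i, ]
      sv[is.na(sv)] <- 0
      cols$stimulus <- sv
    }
    if ("v" %in% terms) cols$running <- v_of(i)
    do.call(cbind, cols)
  }

  results <- vector("list", length(variants) * n * length(subsets))
  fits_unres <- vector("list", n)
  train_mse <- numeric(n)
  test_mse_unres <- numeric(n)
  ri <- 0L
  failed <- character(0)
  for (i in seq_len(n)) {
    y <- dataset$traces[i, ]
    xf_un <- design(i, "unrestricted", "fit")
    fit_un <- fit_lm(xf_un, y, fit_core)
    fits_unres[[i]] <- fit_un
    train_mse[i] <- evaluate_mse(fit_un, xf_un, y, fit_core)
    xe_un <- design(i, "unrestricted", "eval")
    test_mse_unres[i] <- evaluate_mse(fit_un, xe_un, y, eval_core)

    for (v in variants) {
      fit_frames <- if (v == "all_lag") fit_al else fit_core
      eval_frames <- if (v == "all_lag") eval_al else eval_core
      res <- tryCatch({
        xf <- design(i, v, "fit")
        fit <- switch(v,
                      unrestricted = fit_un,
                      nonneg = fit_lm(xf, y, fit_frames, nonneg = TRUE),
                      reciprocal = suppressWarnings(fit_glm_link(xf, y, fit_frames, "reciprocal")),
                      cube = suppressWarnings(fit_glm_link(xf, y, fit_frames, "cube")),
                      fit_lm(xf, y, fit_frames))
        # nesting sanity: an unconstrained submodel of the unrestricted LM can
        # never beat it on its own training frames
        if (v %in% c("stim_restricted", "run_restricted", "coupling_restricted",
                     "lag0_only", "lag1_only")) {
          sub_train <- evaluate_mse(fit, xf, y, fit_frames)
          if (sub_train < train_mse[i] - 1e-8)
            stop("training-MSE nesting violated for variant ", v)
        }
        xe <- design(i, v, "eval")
        lapply(subsets, function(sb) {
          mse_v <- evaluate_mse(fit, xe, y, eval_frames, dataset, sb, run_threshold)
          frames_sb <- if (sb == "all") eval_frames
          else subset_frames(dataset, eval_frames, sb, run_threshold)
          mse_un <- evaluate_mse(fit_un, xe_un, y, frames_sb)
          data.frame(neuron = i, variant = v, subset = sb, test_mse = mse_v,
                     pct_change = percent_change_mse(mse_v, mse_un),
                     stringsAsFactors = FALSE)
        })
      }, error = function(e) {
        failed <<- c(failed, sprintf("neuron %d, variant %s: %s", i, v, conditionMessage(e)))
        NULL
      })
      if (!is.null(res)) for (r in res) { ri <- ri + 1L; results[[ri]] <- r }
    }
  }
  results <- do.call(rbind, results[seq_len(ri)])

  summaries <- do.call(rbind, lapply(split(results, list(results$variant, results$subset), drop = TRUE),
    function(d) data.frame(variant = d$variant[1L], subset = d$subset[1L],
                           median_pct_change = stats::median(d$pct_change),
                           iqr_pct_change = iqr_of(d$pct_change),
                           median_test_mse = stats::median(d$test_mse),
                           iqr_test_mse = iqr_of(d$test_mse),
                           n_neurons = nrow(d), stringsAsFactors = FALSE)))
  rownames(summaries) <- NULL

  structure(list(
    results = results, summaries = summaries, fits = fits_unres,
    train_mse = train_mse, test_mse = test_mse_unres,
    split = split, fit_frames = fit_core, eval_frames = eval_core,
    stim_matrix_fit = s_fit, stim_matrix_eval = s_eval,
    settings = list(variants = variants, split_ratio = split_ratio,
                    granularity = granularity, split_mode = split_mode,
                    seed = seed, stimulus_model = stimulus_model,
                    running_model = running_model, run_threshold = run_threshold),
    failed = failed
  ), class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("Encoding-model comparison (percent change in test MSE vs unrestricted)\n")
  print(x$summaries, digits = 4)
  if (length(x$failed) > 0L)
    cat(sprintf("  %d neuron/variant fits failed (see $failed)\n", length(x$failed)))
  invisible(x)
}

#' Write suite results
#'
#' Persists the per-neuron results as CSV and the population summaries as
#' JSON.
#'
#' @param suite a [run_model_suite()] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_suite <- function(suite, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(suite$results, file.path(dir, "model_comparison.csv"),
                   row.names = FALSE)
  jsonlite::write_json(suite$summaries, file.path(dir, "model_summaries.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
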