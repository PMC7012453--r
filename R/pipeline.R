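# End-to-end orchestration: simulate (or load) -> graph -> encoding suite ->
# permutations -> decoders, with seeded stages, persisted artifacts and a
# summary report.

#' Build a pipeline configuration
#'
#' Collects every knob of the end-to-end analysis into one serializable
#' list. Each stochastic stage receives a seed derived from the root seed
#' via [derive_seed()], so stages are reproducible in isolation.
#'
#' @param dataset_dir path to an existing dataset directory, or `NULL` to
#'   simulate one.
#' @param n_neurons,n_blocks simulation scale (used when simulating).
#' @param running_gain simulated locomotion gain.
#' @param split_ratio,granularity train/test split settings.
#' @param max_lag,lag_filter functional-graph settings.
#' @param variants encoding-model variants to fit.
#' @param n_permutations permutations per scheme (no refit).
#' @param refit_permutations additionally run the refit variant with this
#'   many permutations (0 disables).
#' @param decode_frames `"all"` or `"test"`.
#' @param seed root seed.
#' @param out_dir output directory for artifacts (`NULL`: nothing written).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(dataset_dir = NULL, n_neurons = 100L, n_blocks = 10L,
                            running_gain = 0, split_ratio = 0.7,
                            granularity = "block", max_lag = 17L,
                            lag_filter = c(0L, 1L),
                            variants = .core_variants,
                            n_permutations = 200L, refit_permutations = 0L,
                            decode_frames = "all", seed = 1L, out_dir = NULL) {
  structure(list(dataset_dir = dataset_dir, n_neurons = as.integer(n_neurons),
                 n_blocks = as.integer(n_blocks), running_gain = running_gain,
                 split_ratio = split_ratio, granularity = granularity,
                 max_lag = as.integer(max_lag), lag_filter = as.integer(lag_filter),
                 variants = variants, n_permutations = as.integer(n_permutations),
                 refit_permutations = as.integer(refit_permutations),
                 decode_frames = decode_frames, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Save / load a pipeline configuration
#'
#' JSON round trip: `load_config(save_config(cfg, path))` reproduces `cfg`.
#'
#' @param config a [pipeline_config()].
#' @param path JSON file path.
#' @return `path` (save) or the config (load).
#' @export
save_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, raw[!vapply(raw, is.null, logical(1))])
}

# Stable content hash of a config (md5 of its canonical JSON).
config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  save_config(config, tf)
  unname(tools::md5sum(tf))
}

#' Summarize a functional graph
#'
#' Weight and lag histograms, the share of bidirectional (lag-0) edges, the
#' share of weights at lags 0-1, mean +/- sem functional group size, and
#' the sign/lag composition of the strong edges.
#'
#' @param graph a [build_functional_graph()] result.
#' @return a list of summary statistics.
#' @export
summarize_graph <- function(graph) {
  e <- graph$edges[!is.na(graph$edges$lag_signed), ]
  wh <- graphics::hist(e$weight, breaks = 30, plot = FALSE)
  lag_tab <- table(factor(e$lag, levels = 0:graph$max_lag))
  gs <- vapply(seq_len(graph$n_neurons), function(i) {
    length(functional_group(graph, i))
  }, numeric(1))
  strong <- e[e$strong, , drop = FALSE]
  list(
    n_neurons = graph$n_neurons,
    n_edges = nrow(e),
    weight_hist = list(breaks = wh$breaks, counts = wh$counts),
    lag_hist = as.numeric(lag_tab),
    pct_bidirectional = 100 * mean(e$lag == 0L),
    frac_lag01 = mean(e$lag <= 1L),
    group_size_mean = mean(gs),
    group_size_sem = stats::sd(gs) / sqrt(length(gs)),
    n_strong = nrow(strong),
    strong_pct_positive = 100 * mean(strong$weight > 0),
    strong_pct_lag0 = 100 * mean(strong$lag == 0L),
    strong_cut = graph$strong_cut
  )
}

#' Functional-group size scaling with population size
#'
#' Regresses the mean incoming-edge count (total, and the strong positive
#' bidirectional subset) on the number of imaged neurons across graphs, the
#' population-size scaling analysis.
#'
#' @param graphs list of `functional_graph` objects of different population
#'   sizes.
#' @return list with the per-graph table and the two least-squares slopes.
#' @export
group_size_scaling <- function(graphs) {
  tab <- do.call(rbind, lapply(graphs, function(g) {
    e <- g$edges[!is.na(g$edges$lag_signed), ]
    orient <- .edge_orientations(e)
    total <- nrow(orient) / g$n_neurons
    spb <- e[e$strong & e$weight > 0 & e$lag == 0L, , drop = FALSE]
    spb_mean <- 2 * nrow(spb) / g$n_neurons   # bidirectional: incoming at both ends
    data.frame(population_size = g$n_neurons, mean_incoming_total = total,
               mean_incoming_strong_pos_bidir = spb_mean)
  }))
  fit1 <- stats::lm(mean_incoming_total ~ population_size, data = tab)
  fit2 <- stats::lm(mean_incoming_strong_pos_bidir ~ population_size, data = tab)
  list(table = tab,
       slope_total = unname(stats::coef(fit1)[2L]),
       slope_strong_pos_bidir = unname(stats::coef(fit2)[2L]))
}

#' Run the full analysis pipeline
#'
#' Executes simulate (or load) -> functional graph -> encoding-model suite
#' -> strong-weight and strong-edge permutations -> coupled and uncoupled
#' decoders, persisting each stage's artifact under `config$out_dir` when
#' set, and returns a summary report. Reruns with the same config and seed
#' reproduce all artifacts.
#'
#' @param config a [pipeline_config()].
#' @return an object of class `run_report`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  if (!is.null(out)) dir.create(out, showWarnings = FALSE, recursive = TRUE)
  persist <- function(f, name) if (!is.null(out)) f(file.path(out, name))

  stage <- "simulate"
  report <- list(config = unclass(config), config_hash = config_hash(config))
  res <- tryCatch({
    if (is.null(config$dataset_dir)) {
      sim <- simulate_default_population(config$n_neurons, config$n_blocks,
                                         seed = derive_seed(config$seed, "simulate"),
                                         running_gain = config$running_gain)
      dataset <- sim$dataset
      persist(function(p) write_dataset(sim, p), "dataset")
    } else {
      sim <- NULL
      dataset <- read_dataset(config$dataset_dir)
    }

    stage <- "graph"
    graph <- build_functional_graph(dataset, max_lag = config$max_lag,
                                    lag_filter = config$lag_filter)
    persist(function(p) write_graph(graph, p), "graph.tsv")
    report$graph <- summarize_graph(graph)

    stage <- "encode"
    suite <- run_model_suite(dataset, graph, variants = config$variants,
                             split_ratio = config$split_ratio,
                             granularity = config$granularity,
                             seed = derive_seed(config$seed, "encode"))
    persist(function(p) write_suite(suite, p), "encode")
    report$models <- suite$summaries

    stage <- "permute"
    if (config$n_permutations > 0L) {
      pw <- permutation_mse_change(dataset, graph, suite, "weights",
                                   n_permutations = config$n_permutations,
                                   seed = derive_seed(config$seed, "permute_weights"))
      pe <- permutation_mse_change(dataset, graph, suite, "edges",
                                   n_permutations = config$n_permutations,
                                   seed = derive_seed(config$seed, "permute_edges"))
      persist(function(p) write_permutation_result(pw, p), "perm_weights.json")
      persist(function(p) write_permutation_result(pe, p), "perm_edges.json")
      report$permutations <- list(weights = pw$summaries, edges = pe$summaries)
      if (config$refit_permutations > 0L) {
        pwr <- permutation_mse_change(dataset, graph, suite, "weights",
                                      n_permutations = config$refit_permutations,
                                      refit = TRUE,
                                      seed = derive_seed(config$seed, "permute_weights_refit"))
        per <- permutation_mse_change(dataset, graph, suite, "edges",
                                      n_permutations = config$refit_permutations,
                                      refit = TRUE,
                                      seed = derive_seed(config$seed, "permute_edges_refit"))
        report$permutations$weights_refit <- pwr$summaries
        report$permutations$edges_refit <- per$summaries
      }
    }

    stage <- "decode"
    frames <- if (identical(config$decode_frames, "test")) suite$split$test
    else seq_len(dataset$n_frames)
    cd <- fit_coupled_decoder(dataset, suite, graph)
    ud <- fit_uncoupled_decoder(dataset, suite$split$train)
    rc <- decode_coupled(cd, dataset, graph, frames)
    ru <- decode_map(ud, dataset, frames)
    ec <- evaluate_decoding(rc)
    eu <- evaluate_decoding(ru)
    report$decoding <- list(
      coupled = list(accuracy = ec$accuracy, mi_bits = ec$mi_bits),
      uncoupled = list(accuracy = eu$accuracy, mi_bits = eu$mi_bits),
      mi_gain_pct = 100 * (ec$mi_bits - eu$mi_bits) / eu$mi_bits)
    if (!is.null(out)) {
      jsonlite::write_json(list(coupled = c(list(decoded = rc$decoded), ec[c("accuracy", "mi_bits")]),
                                uncoupled = c(list(decoded = ru$decoded), eu[c("accuracy", "mi_bits")])),
                           file.path(out, "decode.json"), auto_unbox = TRUE, digits = NA)
    }
    report
  }, error = function(e) {
    stop_invalid(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)))
  })
  res$version <- as.character(utils::packageVersion("popcoupling"))
  if (!is.null(out))
    jsonlite::write_json(res, file.path(out, "report.json"), auto_unbox = TRUE,
                         digits = NA, force = TRUE)
  structure(res, class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("Pipeline report (config", substr(x$config_hash, 1, 8), ")\n")
  cat(sprintf("  graph: %d neurons, %.1f%% bidirectional, group size %.1f +/- %.1f\n",
              x$graph$n_neurons, x$graph$pct_bidirectional,
              x$graph$group_size_mean, x$graph$group_size_sem))
  if (!is.null(x$models)) {
    cat("  model ladder (median % change in test MSE):\n")
    m <- x$models[x$models$subset == "all", ]
    for (r in seq_len(nrow(m)))
      cat(sprintf("    %-20s %+7.2f%%\n", m$variant[r], m$median_pct_change[r]))
  }
  if (!is.null(x$permutations))
    cat(sprintf("  permutations: weights %+0.2f%%, edges %+0.2f%% (median of medians)\n",
                x$permutations$weights$median_of_medians,
                x$permutations$edges$median_of_medians))
  if (!is.null(x$decoding))
    cat(sprintf("  decoding: coupled %.1f%%, uncoupled %.1f%%, MI gain %+0.1f%%\n",
                x$decoding$coupled$accuracy, x$decoding$uncoupled$accuracy,
                x$decoding$mi_gain_pct))
  invisible(x)
}
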