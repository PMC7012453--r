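# Fluorescence dataset container: per-neuron-normalized traces plus the
# per-frame stimulus label, running speed and block (trial) structure that
# all downstream estimators condition on.

#' Stimulus condition alphabet
#'
#' The 13 stimulus conditions: mean-luminance grey plus 12 drifting-grating
#' directions in 30-degree increments. The ordering (grey first, then
#' ascending direction) is the canonical condition order used for confusion
#' matrices and decoder tie-breaking throughout the package.
#'
#' @return character vector of length 13.
#' @export
stim_conditions <- function() c("grey", as.character(seq(30L, 360L, by = 30L)))

#' Construct a fluorescence dataset
#'
#' Bundles a neurons x frames matrix of per-neuron normalized fluorescence
#' with its per-frame annotation: stimulus label, running speed and block
#' index. Blocks are repeated presentations of an identical stimulus
#' sequence; the constructor enforces that every block carries the same
#' label sequence, which is what allows leave-one-out trial means to be
#' aligned by within-block frame position.
#'
#' @param traces numeric matrix, neurons x frames; no missing values.
#' @param frame_rate_hz imaging frame rate in Hz.
#' @param labels per-frame stimulus label, each in [stim_conditions()].
#' @param running per-frame running speed (arbitrary encoder units, >= 0).
#' @param block per-frame block index (1-based, contiguous, nondecreasing).
#' @param tuned optional logical vector, one flag per neuron, marking
#'   direction/orientation-tuned neurons. If `NULL` all neurons are treated
#'   as untuned until [classify_tuning()] is run.
#' @return an object of class `fl_dataset`.
#' @export
fl_dataset <- function(traces, frame_rate_hz, labels, running, block, tuned = NULL) {
  if (!is.matrix(traces) || !is.numeric(traces))
    stop_invalid("`traces` must be a numeric matrix (neurons x frames)")
  if (anyNA(traces) || any(!is.finite(traces)))
    stop_invalid("`traces` must be finite with no missing values")
  n <- nrow(traces); t_total <- ncol(traces)
  labels <- as.character(labels)
  if (length(labels) != t_total || length(running) != t_total || length(block) != t_total)
    stop_invalid("per-frame vectors must have length ncol(traces)")
  if (!all(labels %in% stim_conditions()))
    stop_invalid("labels must be drawn from stim_conditions()")
  block <- as.integer(block)
  if (any(diff(block) < 0L) || block[1L] != 1L || any(diff(unique(block)) != 1L))
    stop_invalid("block indices must be 1-based, contiguous and nondecreasing")
  if (!is.null(tuned)) {
    tuned <- as.logical(tuned)
    if (length(tuned) != n) stop_invalid("`tuned` must have one flag per neuron")
  } else {
    tuned <- rep(FALSE, n)
  }
  if (!is.numeric(frame_rate_hz) || frame_rate_hz <= 0)
    stop_invalid("`frame_rate_hz` must be positive")

  # identical label sequence across blocks (up to the shortest block)
  idx <- split(seq_len(t_total), block)
  len <- lengths(idx)
  tb <- min(len)
  ref <- labels[idx[[1L]][seq_len(tb)]]
  for (b in seq_along(idx)) {
    if (!identical(labels[idx[[b]][seq_len(tb)]], ref))
      stop_invalid("all blocks must share the same stimulus label sequence")
  }

  structure(list(
    traces = traces, frame_rate_hz = as.numeric(frame_rate_hz),
    labels = labels, running = as.numeric(running), block = block,
    tuned = tuned, n_neurons = n, n_frames = t_total
  ), class = "fl_dataset")
}

#' @export
print.fl_dataset <- function(x, ...) {
  cat(sprintf("Fluorescence dataset: %d neurons x %d frames, %d blocks, %.1f Hz\n",
              x$n_neurons, x$n_frames, length(unique(x$block)), x$frame_rate_hz))
  cat(sprintf("  tuned neurons: %d/%d; grating frames: %d; running frames: %d\n",
              sum(x$tuned), x$n_neurons, sum(x$labels != "grey"), sum(x$running > 0)))
  invisible(x)
}

# Frame indices of each block, truncated to the shortest block so that all
# blocks align framewise. Real recordings with unequal blocks lose the tail
# of longer blocks (documented behaviour).
block_frame_index <- function(dataset) {
  idx <- split(seq_len(dataset$n_frames), dataset$block)
  tb <- min(lengths(idx))
  lapply(idx, function(i) i[seq_len(tb)])
}

#' Block-mean traces
#'
#' Averages each neuron's trace across blocks, aligned by within-block frame
#' position (blocks truncated to the shortest), giving one mean trace per
#' neuron over a single block's duration.
#'
#' @param dataset an [fl_dataset()].
#' @return numeric matrix, neurons x frames-per-block.
#' @export
block_mean_traces <- function(dataset) {
  idx <- block_frame_index(dataset)
  acc <- 0
  for (i in idx) acc <- acc + dataset$traces[, i, drop = FALSE]
  acc / length(idx)
}

# Contiguous constant-label segments ("presentations"), including grey
# segments, one row per segment.
presentations <- function(dataset) {
  key <- paste(dataset$block, dataset$labels, sep = "\r")
  r <- rle(key)
  end <- cumsum(r$lengths)
  start <- end - r$lengths + 1L
  data.frame(
    block = dataset$block[start],
    label = dataset$labels[start],
    start = start, end = end,
    stringsAsFactors = FALSE
  )
}

#' Classify neurons as tuned or untuned
#'
#' A simple surrogate tuning test: per neuron, a Kruskal-Wallis test of the
#' fluorescence trace against the 12 grating directions over grating frames;
#' neurons with Benjamini-Hochberg adjusted p below `alpha` are flagged
#' tuned. This stands in for dataset-specific tuning-significance procedures
#' when ground-truth flags are unavailable.
#'
#' @param dataset an [fl_dataset()].
#' @param alpha significance level on BH-adjusted p-values (default 0.01).
#' @return the dataset with its `tuned` flags replaced.
#' @export
classify_tuning <- function(dataset, alpha = 0.01) {
  grate <- dataset$labels != "grey"
  g <- factor(dataset$labels[grate])
  p <- vapply(seq_len(dataset$n_neurons), function(i) {
    stats::kruskal.test(dataset$traces[i, grate], g)$p.value
  }, numeric(1))
  dataset$tuned <- stats::p.adjust(p, "BH") < alpha
  dataset
}

#' Write a dataset directory
#'
#' Persists a dataset as one directory holding `traces.csv` (dense numeric
#' matrix, neurons x frames, row order = neuron id, no header), `frames.csv`
#' (columns `frame_index`, `block_index`, `stimulus_label`, `running_speed`;
#' 0-based indices) and `meta.json` (frame rate, neuron count, tuned flags,
#' seed and, for synthetic data, the serialized ground truth).
#'
#' @param dataset an [fl_dataset()] or a [simulate_population()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  truth <- NULL; seed <- NULL
  if (inherits(dataset, "synthetic_dataset")) {
    truth <- list(coupling = dataset$coupling$edges,
                  tuning = dataset$tuning, seed = dataset$seed)
    seed <- dataset$seed
    dataset <- dataset$dataset
  }
  stopifnot(inherits(dataset, "fl_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(dataset$traces, file.path(dir, "traces.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  frames <- data.frame(
    frame_index = seq_len(dataset$n_frames) - 1L,
    block_index = dataset$block - 1L,
    stimulus_label = dataset$labels,
    running_speed = dataset$running
  )
  utils::write.csv(frames, file.path(dir, "frames.csv"), row.names = FALSE)
  meta <- list(frame_rate_hz = dataset$frame_rate_hz,
               n_neurons = dataset$n_neurons,
               tuned = dataset$tuned, seed = seed, ground_truth = truth)
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a dataset directory
#'
#' Inverse of [write_dataset()]. Ground truth stored in `meta.json` is
#' attached as the `"ground_truth"` attribute.
#'
#' @param dir directory written by [write_dataset()].
#' @return an [fl_dataset()].
#' @export
read_dataset <- function(dir) {
  traces <- as.matrix(utils::read.csv(file.path(dir, "traces.csv"), header = FALSE))
  dimnames(traces) <- NULL
  frames <- utils::read.csv(file.path(dir, "frames.csv"),
                            colClasses = c(stimulus_label = "character"))
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  ds <- fl_dataset(traces, meta$frame_rate_hz, frames$stimulus_label,
                   frames$running_speed, frames$block_index + 1L,
                   tuned = meta$tuned)
  attr(ds, "ground_truth") <- meta$ground_truth
  ds
}
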