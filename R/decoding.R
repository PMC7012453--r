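# Bayesian MAP stimulus decoding: a coupled decoder whose per-frame mean is
# the unrestricted LM prediction with the stimulus term evaluated at each
# candidate condition (full per-condition covariance), and an uncoupled
# decoder treating neurons as independent (per-neuron condition means and
# variances). Both use a uniform prior over the 13 conditions.

# Per-neuron stimulus-term value for each of the 13 conditions under the
# average-response model (grey = 0; untuned neurons carry the grand mean of
# the 12 per-direction averages on every grating condition).
stimulus_condition_values <- function(dataset, train_frames) {
  conds <- stim_conditions()
  n <- dataset$n_neurons
  out <- matrix(0, n, length(conds), dimnames = list(NULL, conds))
  tr_labels <- dataset$labels[train_frames]
  for (i in seq_len(n)) {
    tr <- dataset$traces[i, train_frames]
    per_dir <- vapply(conds[-1L], function(d) {
      sel <- tr_labels == d
      if (any(sel)) mean(tr[sel]) else NA_real_
    }, numeric(1))
    const <- mean(per_dir, na.rm = TRUE)
    per_dir[is.na(per_dir)] <- const
    out[i, -1L] <- if (dataset$tuned[i]) per_dir else const
  }
  out
}

# Ledoit-Wolf-style shrinkage of a sample covariance toward its diagonal
# (Schafer-Strimmer off-diagonal intensity), plus a small diagonal load.
shrunk_covariance <- function(x, shrinkage = c("ledoit", "none"),
                              diag_load = 1e-8, forced_intensity = NULL) {
  shrinkage <- match.arg(shrinkage)
  n <- nrow(x)
  xc <- sweep(x, 2L, colMeans(x))
  s <- crossprod(xc) / (n - 1)
  lambda <- 0
  if (!is.null(forced_intensity)) {
    lambda <- forced_intensity
  } else if (shrinkage == "ledoit" && n > 3L) {
    w_bar <- s * (n - 1) / n
    var_w <- (n / ((n - 1)^3)) * (crossprod(xc^2) - n * w_bar^2)
    off <- upper.tri(s)
    denom <- sum(s[off]^2)
    lambda <- if (denom > 0) min(1, max(0, sum(var_w[off]) / denom)) else 1
  }
  out <- (1 - lambda) * s
  diag(out) <- diag(s)
  diag(out) <- diag(out) + diag_load
  attr(out, "intensity") <- lambda
  out
}

#' Fit the coupled Bayesian decoder
#'
#' The likelihood of the population response given a candidate condition is
#' multivariate Gaussian with mean equal to the unrestricted LM prediction
#' (coupling and running terms evaluated on the observed data at the frame,
#' stimulus term evaluated at the candidate) and covariance equal to the
#' training-frame covariance of the traces during that condition,
#' regularized by shrinkage toward the diagonal.
#'
#' @param dataset an [fl_dataset()].
#' @param suite a [run_model_suite()] result fitted with the
#'   average-response stimulus model and rotary running model.
#' @param graph the functional graph used by the suite.
#' @param train_frames frames used for covariance and mean estimation
#'   (defaults to the suite's training frames).
#' @param shrinkage `"ledoit"` (data-driven intensity) or `"none"`.
#' @param diag_load small diagonal loading added after shrinkage.
#' @return an object of class `decoder_model` (variant `"coupled"`).
#' @export
fit_coupled_decoder <- function(dataset, suite, graph,
                                train_frames = suite$split$train,
                                shrinkage = "ledoit", diag_load = 1e-8) {
  stopifnot(inherits(suite, "model_comparison"))
  if (suite$settings$stimulus_model != "average" ||
      suite$settings$running_model != "rotary")
    stop_invalid("coupled decoder expects the average-response / rotary suite")
  conds <- stim_conditions()
  tr_labels <- dataset$labels[train_frames]
  missing <- setdiff(conds, unique(tr_labels))
  if (length(missing) > 0L)
    stop_invalid("unseen condition in training frames: ", paste(missing, collapse = ", "))
  n <- dataset$n_neurons
  coefs <- t(vapply(suite$fits, function(f) f$coef, numeric(5L)))
  stim_vals <- stimulus_condition_values(dataset, train_frames)
  sig <- vector("list", length(conds)); names(sig) <- conds
  chols <- vector("list", length(conds)); names(chols) <- conds
  for (s in conds) {
    fr <- train_frames[tr_labels == s]
    forced <- NULL
    if (length(fr) <= n) forced <- 1  # fewer frames than neurons: force diagonal
    cs <- shrunk_covariance(t(dataset$traces[, fr, drop = FALSE]),
                            shrinkage = shrinkage, diag_load = diag_load,
                            forced_intensity = forced)
    sig[[s]] <- cs
    chols[[s]] <- chol(cs)
  }
  structure(list(variant = "coupled", conditions = conds,
                 prior = rep(1 / length(conds), length(conds)),
                 coef = coefs, stim_values = stim_vals,
                 sigma = sig, chol = chols, n_neurons = n),
            class = "decoder_model")
}

#' Fit the uncoupled Bayesian decoder
#'
#' Treats neurons as conditionally independent: for each condition, the
#' likelihood factorizes into per-neuron univariate Gaussians with the
#' neuron's condition mean and variance estimated from the training frames.
#'
#' @param dataset an [fl_dataset()].
#' @param train_frames training frames; every condition must occur.
#' @param var_floor variance floor for zero-variance cells.
#' @return an object of class `decoder_model` (variant `"uncoupled"`).
#' @export
fit_uncoupled_decoder <- function(dataset, train_frames, var_floor = 1e-6) {
  conds <- stim_conditions()
  tr_labels <- dataset$labels[train_frames]
  missing <- setdiff(conds, unique(tr_labels))
  if (length(missing) > 0L)
    stop_invalid("unseen condition in training frames: ", paste(missing, collapse = ", "))
  n <- dataset$n_neurons
  means <- matrix(0, n, length(conds), dimnames = list(NULL, conds))
  vars <- matrix(0, n, length(conds), dimnames = list(NULL, conds))
  for (s in conds) {
    fr <- train_frames[tr_labels == s]
    x <- dataset$traces[, fr, drop = FALSE]
    means[, s] <- rowMeans(x)
    v <- apply(x, 1L, stats::var)
    vars[, s] <- pmax(v, var_floor)
  }
  structure(list(variant = "uncoupled", conditions = conds,
                 prior = rep(1 / length(conds), length(conds)),
                 means = means, vars = vars, n_neurons = n),
            class = "decoder_model")
}

#' Decode the stimulus by maximum a posteriori
#'
#' Evaluates, per frame, the log-likelihood of the observed population
#' response under each of the 13 candidate conditions plus the log-prior,
#' and returns the argmax. Ties are broken toward the lowest condition
#' index (grey first, then ascending direction). Frames with a non-finite
#' log-likelihood under every condition are flagged and excluded.
#'
#' @param decoder a fitted `decoder_model`.
#' @param dataset the dataset to decode.
#' @param frames frames to decode (default all frames, mirroring the study
#'   design; pass the test split for a generalization-only readout).
#' @return an object of class `decoding_result` with `frames`, `decoded`
#'   (character labels), `true` labels and `flagged` frames.
#' @export
decode_map <- function(decoder, dataset, frames = seq_len(dataset$n_frames)) {
  conds <- decoder$conditions
  nf <- length(frames)
  logpost <- matrix(NA_real_, length(conds), nf)
  if (decoder$variant == "coupled") {
    cf <- decoder$coef
    # coupling/running part of the LM mean; lag-1 features use zero where the
    # previous frame falls outside the block
    f0 <- attr(decoder, "f0"); f1 <- attr(decoder, "f1")
    if (is.null(f0)) stop_invalid("decoder is missing its feature context; use decode_coupled()")
    base <- cf[, 1L] + cf[, 2L] * f0[, frames, drop = FALSE] +
      cf[, 3L] * f1[, frames, drop = FALSE] +
      outer(cf[, 5L], dataset$running[frames])
    d <- dataset$traces[, frames, drop = FALSE] - base
    for (k in seq_along(conds)) {
      mu_s <- cf[, 4L] * decoder$stim_values[, k]
      e <- d - mu_s
      u <- decoder$chol[[k]]
      z <- backsolve(u, e, transpose = TRUE)
      logpost[k, ] <- -0.5 * colSums(z^2) - sum(log(diag(u))) + log(decoder$prior[k])
    }
  } else {
    x <- dataset$traces[, frames, drop = FALSE]
    for (k in seq_along(conds)) {
      m <- decoder$means[, k]; v <- decoder$vars[, k]
      logpost[k, ] <- -0.5 * colSums((x - m)^2 / v) - 0.5 * sum(log(v)) +
        log(decoder$prior[k])
    }
  }
  finite <- apply(logpost, 2L, function(col) any(is.finite(col)))
  decoded <- rep(NA_character_, nf)
  if (any(finite)) {
    lp <- logpost[, finite, drop = FALSE]
    lp[!is.finite(lp)] <- -Inf
    decoded[finite] <- conds[apply(lp, 2L, which.max)]
  }
  structure(list(frames = frames, decoded = decoded,
                 true = dataset$labels[frames],
                 flagged = frames[!finite], variant = decoder$variant),
            class = "decoding_result")
}

#' Decode with the coupled decoder
#'
#' Convenience wrapper that attaches the coupling-feature context (computed
#' from the graph on the decoded dataset) to the decoder and runs
#' [decode_map()].
#'
#' @inheritParams decode_map
#' @param graph the functional graph the decoder's suite was built on.
#' @return a `decoding_result`.
#' @export
decode_coupled <- function(decoder, dataset, graph,
                           frames = seq_len(dataset$n_frames)) {
  wl <- coupling_matrices(graph, lags = c(0L, 1L))
  attr(decoder, "f0") <- coupling_feature(dataset, wl[["0"]], 0L)$values
  attr(decoder, "f1") <- coupling_feature(dataset, wl[["1"]], 1L)$values
  decode_map(decoder, dataset, frames)
}

#' Confusion matrix and accuracy
#'
#' Row-normalized percent confusion over the 13 conditions (each row: the
#' percent of that true condition's frames decoded as each label) and the
#' overall accuracy in percent. Conditions absent from the true labels give
#' all-`NA` rows.
#'
#' @param true,decoded equal-length label vectors over
#'   [stim_conditions()].
#' @return list with `confusion` (13 x 13 percent matrix) and `accuracy`
#'   (percent).
#' @export
confusion_and_accuracy <- function(true, decoded) {
  stopifnot(length(true) == length(decoded))
  keep <- !is.na(decoded)
  true <- true[keep]; decoded <- decoded[keep]
  conds <- stim_conditions()
  tab <- table(factor(true, conds), factor(decoded, conds))
  counts <- matrix(as.numeric(tab), length(conds), length(conds),
                   dimnames = list(true = conds, decoded = conds))
  rs <- rowSums(counts)
  conf <- counts / ifelse(rs == 0, NA_real_, rs) * 100
  list(confusion = conf, accuracy = 100 * mean(true == decoded))
}

#' Plug-in mutual information between label sequences
#'
#' The mutual information of the empirical joint distribution of true and
#' decoded labels, in bits, with the convention `0 * log(0) = 0`.
#'
#' @param true,decoded equal-length label vectors.
#' @return mutual information in bits.
#' @export
mutual_information <- function(true, decoded) {
  stopifnot(length(true) == length(decoded), length(true) > 0L)
  keep <- !is.na(decoded)
  joint <- table(true[keep], decoded[keep]) / sum(keep)
  mutual_information_joint(as.matrix(joint))
}

#' Mutual information of a joint distribution
#'
#' @param p joint probability matrix (rows: one variable, columns: the
#'   other); must sum to 1.
#' @return mutual information in bits.
#' @export
mutual_information_joint <- function(p) {
  p <- as.matrix(p)
  if (abs(sum(p) - 1) > 1e-8) stop_invalid("joint distribution must sum to 1")
  pr <- rowSums(p); pc <- colSums(p)
  terms <- p * log2(p / outer(pr, pc))
  sum(terms[p > 0])
}

#' Summarize a decoding result
#'
#' @param result a [decode_map()] result.
#' @return list with `accuracy` (percent), `confusion` (percent matrix) and
#'   `mi_bits` (plug-in mutual information).
#' @export
evaluate_decoding <- function(result) {
  ca <- confusion_and_accuracy(result$true, result$decoded)
  list(accuracy = ca$accuracy, confusion = ca$confusion,
       mi_bits = mutual_information(result$true, result$decoded),
       n_flagged = length(result$flagged), variant = result$variant)
}
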