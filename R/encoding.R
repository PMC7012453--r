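# Coupled linear encoding models: regressor construction (coupling features
# with measured weights, stimulus terms, running terms), least-squares fits
# of the model ladder, and test-set MSE comparison.

#' Split frames into train and test sets
#'
#' Partitions frames at block or presentation granularity so that no
#' presentation straddles the boundary. Block granularity assigns whole
#' blocks (earliest blocks to train by default, or a seeded random block
#' subset). Presentation granularity balances the presentation counts per
#' stimulus condition across the two halves, as required when block-averaged
#' traces are computed separately within each half.
#'
#' @param dataset an [fl_dataset()].
#' @param ratio train fraction in (0, 1).
#' @param granularity `"block"` or `"presentation"`.
#' @param seed integer seed for `mode = "random"`; `NULL` for deterministic
#'   earliest-first assignment.
#' @param mode `"earliest"` or `"random"`.
#' @return list with integer frame index vectors `train` and `test`
#'   (disjoint, exhaustive).
#' @export
split_frames <- function(dataset, ratio = 0.7,
                         granularity = c("block", "presentation"),
                         seed = NULL, mode = c("earliest", "random")) {
  granularity <- match.arg(granularity)
  mode <- match.arg(mode)
  if (ratio <= 0 || ratio >= 1) stop_invalid("`ratio` must be in (0, 1)")
  if (granularity == "block") {
    blocks <- unique(dataset$block)
    nb <- length(blocks)
    n_train <- max(1L, min(nb - 1L, round(ratio * nb)))
    if (nb < 2L) stop_invalid("need >= 2 blocks to split at block granularity")
    train_blocks <- if (mode == "earliest") blocks[seq_len(n_train)]
    else with_seed(seed, sample(blocks, n_train))
    train <- which(dataset$block %in% train_blocks)
    test <- which(!dataset$block %in% train_blocks)
  } else {
    pres <- presentations(dataset)
    train_rows <- logical(nrow(pres))
    for (lb in unique(pres$label)) {
      rows <- which(pres$label == lb)
      k <- length(rows)
      n_train <- round(ratio * k)
      if (k < 2L) stop_invalid("too few presentations per condition to split")
      pick <- if (mode == "earliest") seq_len(n_train)
      else with_seed(seed + match(lb, unique(pres$label)), sample(k, n_train))
      train_rows[rows[pick]] <- TRUE
    }
    fr <- function(rows) {
      unlist(lapply(which(rows), function(r) pres$start[r]:pres$end[r]), use.names = FALSE)
    }
    train <- sort(fr(train_rows))
    test <- sort(fr(!train_rows))
  }
  list(train = train, test = test)
}

#' Average-response stimulus term
#'
#' The per-frame stimulus regressor under the average-response model: for a
#' tuned neuron, the frame's value is the neuron's mean training-set
#' response over all frames carrying the same grating label; for an untuned
#' neuron, a single constant equal to the mean of the 12 per-direction
#' averages is applied on all grating frames. Grey frames get 0. Labels
#' absent from the training set fall back to the untuned constant.
#'
#' @param dataset an [fl_dataset()].
#' @param neuron neuron index.
#' @param train_frames frames used to compute the averages.
#' @return numeric vector over all frames.
#' @export
stimulus_term_average_response <- function(dataset, neuron, train_frames) {
  conds <- stim_conditions()[-1L]
  tr_labels <- dataset$labels[train_frames]
  tr_resp <- dataset$traces[neuron, train_frames]
  per_dir <- vapply(conds, function(d) {
    sel <- tr_labels == d
    if (any(sel)) mean(tr_resp[sel]) else NA_real_
  }, numeric(1))
  untuned_const <- mean(per_dir, na.rm = TRUE)
  per_dir[is.na(per_dir)] <- untuned_const
  s <- numeric(dataset$n_frames)
  grate <- dataset$labels != "grey"
  if (dataset$tuned[neuron]) {
    s[grate] <- per_dir[dataset$labels[grate]]
  } else {
    s[grate] <- untuned_const
  }
  s
}

#' Block-averaged-trace stimulus term
#'
#' The stimulus regressor preserving within-presentation dynamics: for each
#' grating label, the neuron's fluorescence is averaged across the split's
#' presentations of that label at matching within-presentation frame
#' offsets (presentations truncated to the shortest). Averages are computed
#' within the evaluation split itself (training averages when fitting, test
#' averages when testing). Grey frames are excluded and carry `NA`.
#'
#' @param dataset an [fl_dataset()].
#' @param neuron neuron index.
#' @param frames the frames of the evaluation split.
#' @return numeric vector over all frames; `NA` outside grating frames of
#'   the split.
#' @export
stimulus_term_block_averaged <- function(dataset, neuron, frames) {
  pres <- presentations(dataset)
  in_split <- vapply(seq_len(nrow(pres)), function(r) {
    all(pres$start[r]:pres$end[r] %in% frames)
  }, logical(1))
  pres <- pres[in_split & pres$label != "grey", , drop = FALSE]
  s <- rep(NA_real_, dataset$n_frames)
  for (lb in unique(pres$label)) {
    p <- pres[pres$label == lb, , drop = FALSE]
    len <- min(p$end - p$start + 1L)
    seg <- vapply(seq_len(nrow(p)), function(r) {
      dataset$traces[neuron, p$start[r] + seq_len(len) - 1L]
    }, numeric(len))
    avg <- rowMeans(as.matrix(seg))
    for (r in seq_len(nrow(p))) {
      s[p$start[r] + seq_len(len) - 1L] <- avg
    }
  }
  s
}

#' Running term
#'
#' Either the recorded rotary-encoder speed series, or (to allow for
#' nonlinear locomotion drive) the time-varying average population response
#' with the target neuron excluded to avoid self-regression.
#'
#' @param dataset an [fl_dataset()].
#' @param model `"rotary"` or `"population_average"`.
#' @param exclude_neuron neuron index excluded from the population average.
#' @return numeric vector over all frames.
#' @export
running_term <- function(dataset, model = c("rotary", "population_average"),
                         exclude_neuron = NULL) {
  model <- match.arg(model)
  if (model == "rotary") return(dataset$running)
  if (is.null(exclude_neuron)) return(colMeans(dataset$traces))
  (colSums(dataset$traces) - dataset$traces[exclude_neuron, ]) /
    (dataset$n_neurons - 1L)
}

# ---- least squares ----------------------------------------------------------

.ols <- function(x, y) {
  fit <- tryCatch(qr.coef(qr(x), y), error = function(e) NULL)
  if (is.null(fit) || anyNA(fit)) {
    # rank-deficient: minimum-norm solution via the pseudoinverse
    sv <- svd(x)
    pos <- sv$d > max(dim(x)) * .Machine$double.eps * sv$d[1L]
    fit <- sv$v[, pos, drop = FALSE] %*%
      ((crossprod(sv$u[, pos, drop = FALSE], y)) / sv$d[pos])
    fit <- as.numeric(fit)
    attr(fit, "rank_deficient") <- TRUE
  }
  fit
}

#' Fit a linear encoding model by least squares
#'
#' Ordinary least squares of the response on the supplied features plus an
#' intercept. With `nonneg = TRUE` the term coefficients are constrained to
#' be nonnegative (the intercept stays free, since it models baseline
#' fluorescence); the constrained minimizer is found exactly by enumerating
#' active sets and checking feasibility, which is tractable because the
#' ladder's designs have at most a handful of terms.
#'
#' @param features numeric matrix (frames x terms) with named columns.
#' @param response numeric response vector over the same frames.
#' @param train_frames row indices used for fitting.
#' @param nonneg constrain term coefficients to be >= 0.
#' @return an object of class `encoding_fit` with `coef` (named, first
#'   element `(Intercept)`), `link = "identity"`, and `train_frames`.
#' @export
fit_lm <- function(features, response, train_frames = seq_along(response),
                   nonneg = FALSE) {
  features <- as.matrix(features)
  p <- ncol(features)
  if (length(train_frames) < 2L * (p + 1L))
    stop_invalid("need at least twice as many training frames as parameters")
  x <- cbind(`(Intercept)` = 1, features)[train_frames, , drop = FALSE]
  y <- response[train_frames]
  if (!nonneg) {
    beta <- .ols(x, y)
  } else {
    if (p > 20L) stop_invalid("nonnegative fit supports at most 20 terms")
    best <- NULL; best_sse <- Inf
    for (mask in 0:(2^p - 1L)) {
      active <- which(bitwAnd(mask, 2^(seq_len(p) - 1L)) == 0L)
      xs <- x[, c(1L, active + 1L), drop = FALSE]
      bb <- .ols(xs, y)
      if (length(active) > 0L && any(bb[-1L] < 0)) next
      sse <- sum((y - xs %*% bb)^2)
      if (sse < best_sse - 1e-12) {
        best_sse <- sse
        full <- numeric(p + 1L)
        full[c(1L, active + 1L)] <- bb
        best <- full
      }
    }
    beta <- best
  }
  names(beta) <- c("(Intercept)", colnames(features))
  structure(list(coef = beta, link = "identity", nonneg = nonneg,
                 terms = colnames(features), train_frames = train_frames),
            class = "encoding_fit")
}

#' Fit a Gaussian encoding model under a nonlinear link
#'
#' Gauss-Newton least squares under a reciprocal (`1/Y = X beta`) or cube
#' (`Y^3 = X beta`) link: the linear predictor is initialized by regressing
#' the linked response on the design and refined by iteratively reweighted
#' updates. Linear predictors are floored at `eps` in magnitude
#' (sign-preserving) to keep the reciprocal inverse finite.
#'
#' @inheritParams fit_lm
#' @param link `"reciprocal"` or `"cube"`.
#' @param eps magnitude floor on the linear predictor.
#' @param max_iter Gauss-Newton iteration cap.
#' @return an `encoding_fit` with the chosen `link`; if the iteration fails
#'   to converge the partial result carries attribute `converged = FALSE`.
#' @export
fit_glm_link <- function(features, response, train_frames = seq_along(response),
                         link = c("reciprocal", "cube"), eps = 1e-6,
                         max_iter = 50L) {
  link <- match.arg(link)
  features <- as.matrix(features)
  if (length(train_frames) < 2L * (ncol(features) + 1L))
    stop_invalid("need at least twice as many training frames as parameters")
  x <- cbind(`(Intercept)` = 1, features)[train_frames, , drop = FALSE]
  y <- response[train_frames]
  floor_eta <- function(eta) sign(eta + (eta == 0)) * pmax(abs(eta), eps)
  linkfun <- switch(link,
                    reciprocal = function(mu) 1 / floor_eta(mu),
                    cube = function(mu) mu^3)
  linkinv <- switch(link,
                    reciprocal = function(eta) 1 / floor_eta(eta),
                    cube = function(eta) sign(eta) * abs(eta)^(1 / 3))
  dmu_deta <- switch(link,
                     reciprocal = function(eta) -1 / floor_eta(eta)^2,
                     cube = function(eta) (1 / 3) * pmax(abs(eta), eps)^(-2 / 3))
  beta <- .ols(x, linkfun(y))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- as.numeric(x %*% beta)
    mu <- linkinv(eta)
    g <- dmu_deta(eta)
    jac <- x * g
    step <- tryCatch(.ols(jac, y - mu), error = function(e) NULL)
    if (is.null(step) || anyNA(step)) break
    new_sse <- function(b) sum((y - linkinv(as.numeric(x %*% b)))^2)
    lambda <- 1
    cur <- new_sse(beta)
    repeat {
      cand <- beta + lambda * step
      if (new_sse(cand) <= cur + 1e-12 || lambda < 1e-6) break
      lambda <- lambda / 2
    }
    if (max(abs(lambda * step)) < 1e-12) { converged <- TRUE; break }
    beta <- beta + lambda * step
    if (max(abs(lambda * step)) < 1e-10) { converged <- TRUE; break }
  }
  beta <- as.numeric(beta)
  names(beta) <- c("(Intercept)", colnames(features))
  out <- structure(list(coef = beta, link = link, nonneg = FALSE,
                        terms = colnames(features), train_frames = train_frames,
                        eps = eps),
                   class = "encoding_fit")
  if (!converged) {
    attr(out, "converged") <- FALSE
    warning("link fit did not converge; returning partial result", call. = FALSE)
  }
  out
}

#' Predict from an encoding fit
#'
#' @param object an `encoding_fit`.
#' @param features feature matrix over the frames to predict (same columns
#'   as used for fitting).
#' @param ... unused.
#' @return numeric predictions on the response scale.
#' @export
predict.encoding_fit <- function(object, features, ...) {
  x <- cbind(1, as.matrix(features))
  eta <- as.numeric(x %*% object$coef)
  switch(object$link,
         identity = eta,
         reciprocal = {
           eps <- object$eps %||% 1e-6
           1 / (sign(eta + (eta == 0)) * pmax(abs(eta), eps))
         },
         cube = sign(eta) * abs(eta)^(1 / 3))
}

# Frame subsets for evaluation. `running_only` keeps frames with speed above
# `run_threshold` (default: any movement); `first_second_after_onset` keeps
# the first ceiling(frame rate) frames of each grating presentation.
subset_frames <- function(dataset, frames,
                          subset = c("all", "stimulus_only", "running_only",
                                     "first_second_after_onset"),
                          run_threshold = 0) {
  subset <- match.arg(subset)
  keep <- switch(subset,
                 all = frames,
                 stimulus_only = frames[dataset$labels[frames] != "grey"],
                 running_only = frames[dataset$running[frames] > run_threshold],
                 first_second_after_onset = {
                   pres <- presentations(dataset)
                   pres <- pres[pres$label != "grey", , drop = FALSE]
                   k <- ceiling(dataset$frame_rate_hz)
                   onset <- unlist(lapply(seq_len(nrow(pres)), function(r) {
                     pres$start[r]:min(pres$end[r], pres$start[r] + k - 1L)
                   }), use.names = FALSE)
                   intersect(frames, onset)
                 })
  keep
}

#' Test-set mean squared error of an encoding model
#'
#' Mean squared prediction error over a frame subset: all frames, grating
#' frames only, frames where the animal runs, or the first second after each
#' stimulus onset.
#'
#' @param fit an `encoding_fit`.
#' @param features feature matrix over all frames (columns as fitted).
#' @param response response vector over all frames.
#' @param frames evaluation frames.
#' @param dataset the dataset (needed to resolve subsets other than "all").
#' @param subset one of `"all"`, `"stimulus_only"`, `"running_only"`,
#'   `"first_second_after_onset"`.
#' @param run_threshold minimum speed counting as running.
#' @return the MSE (>= 0); signals an error if the subset is empty.
#' @export
evaluate_mse <- function(fit, features, response, frames, dataset = NULL,
                         subset = "all", run_threshold = 0) {
  if (subset != "all") {
    if (is.null(dataset)) stop_invalid("`dataset` required for frame subsets")
    frames <- subset_frames(dataset, frames, subset, run_threshold)
  }
  if (length(frames) == 0L) stop_invalid("empty evaluation subset")
  pred <- predict(fit, as.matrix(features)[frames, , drop = FALSE])
  mean((response[frames] - pred)^2)
}

#' Percent change in MSE of a restricted model
#'
#' `100 * (restricted - unrestricted) / unrestricted`: positive values mean
#' the restricted model predicts worse, i.e. the excluded term was
#' informative.
#'
#' @param restricted_mse,unrestricted_mse MSEs on the same frames.
#' @return percent change.
#' @export
percent_change_mse <- function(restricted_mse, unrestricted_mse) {
  if (unrestricted_mse <= 0)
    stop_invalid("undefined comparison: unrestricted MSE must be > 0")
  100 * (restricted_mse - unrestricted_mse) / unrestricted_mse
}
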