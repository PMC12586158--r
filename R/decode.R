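# Cross-validated multiclass linear decoding and "inference decoding":
# probing a decoder trained on the illusory/recombined image set with
# held-out real-edge stimuli, subset manipulations (zeroing-out /
# subset-only training), and cross-decoding of holography-evoked
# activity.
#
# The classifier is a linear support vector machine in a one-vs-one
# multiclass scheme with majority vote; vote ties are broken by summed
# decision-function margins and then by the lowest class index.  Each
# fold standardizes every neuron by the mean and s.d. of its *training*
# trials only; probe trials never influence standardization.

scale_cols <- function(X, mu, s) sweep(sweep(X, 2, mu), 2, s, "/")

# one-vs-one vote aggregation from libsvm decision values
ovo_predict <- function(fit, newx, classes) {
  pr <- stats::predict(fit, newx, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  votes <- matrix(0, nrow(newx), length(classes),
                  dimnames = list(NULL, classes))
  marg <- votes
  for (cn in colnames(dv)) {
    ab <- strsplit(cn, "/", fixed = TRUE)[[1]]
    pos <- dv[, cn] >= 0
    votes[, ab[1]] <- votes[, ab[1]] + pos
    votes[, ab[2]] <- votes[, ab[2]] + !pos
    marg[, ab[1]] <- marg[, ab[1]] + dv[, cn]
    marg[, ab[2]] <- marg[, ab[2]] - dv[, cn]
  }
  idx <- vapply(seq_len(nrow(newx)), function(r) {
    cand <- which(votes[r, ] == max(votes[r, ]))
    if (length(cand) > 1) cand <- cand[marg[r, cand] == max(marg[r, cand])]
    cand[1]
  }, integer(1))
  factor(classes[idx], levels = classes)
}

#' Train a cross-validated multiclass linear decoder
#'
#' Stratified k-fold cross-validation (the k test sets are disjoint and
#' cover all trials; the training split is (k-1)/k of the trials).  On
#' each fold the response matrix is z-scored by the training trials'
#' mean/s.d. (zero-variance neurons get a floored s.d.), a linear SVM is
#' fit, and the held-out trials are evaluated.
#'
#' @param X trials x neurons response matrix.
#' @param y Trial labels (coerced to factor).
#' @param k Number of folds (10 by convention; every class needs at
#'   least `k` trials).
#' @param seed Seed for the stratified fold assignment.
#' @param cost SVM regularization constant C.
#' @return Object of class `ic_decoder`: per-fold train/test indices,
#'   standardization parameters and fitted SVM, plus `cv_accuracy`,
#'   `fold_accuracy` and the row-normalized `confusion` matrix.
#' @export
train_cv_decoder <- function(X, y, k = 10, seed = 1, cost = 1) {
  y <- factor(y)
  classes <- levels(y)
  if (any(table(y) < k))
    stop("every class needs at least k trials for ", k, "-fold CV")
  set.seed(child_seed(seed, 7))
  fold <- integer(nrow(X))
  for (cl in classes) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds <- vector("list", k)
  conf <- matrix(0, length(classes), length(classes),
                 dimnames = list(true = classes, predicted = classes))
  acc <- numeric(k)
  for (f in seq_len(k)) {
    tr <- which(fold != f); te <- which(fold == f)
    mu <- colMeans(X[tr, , drop = FALSE])
    s <- floor_sd(apply(X[tr, , drop = FALSE], 2, stats::sd))
    Xtr <- scale_cols(X[tr, , drop = FALSE], mu, s)
    fit <- e1071::svm(Xtr, y[tr], kernel = "linear", cost = cost,
                      scale = FALSE)
    pred <- ovo_predict(fit, scale_cols(X[te, , drop = FALSE], mu, s),
                        classes)
    acc[f] <- mean(pred == y[te])
    conf <- conf + table(y[te], pred)
    folds[[f]] <- list(train_idx = tr, test_idx = te, mu = mu, sd = s,
                       fit = fit)
  }
  structure(list(folds = folds, classes = classes, k = k, cost = cost,
                 seed = seed, n_neurons = ncol(X),
                 cv_accuracy = mean(acc), fold_accuracy = acc,
                 confusion = conf / pmax(rowSums(conf), 1)),
            class = "ic_decoder")
}

#' @export
print.ic_decoder <- function(x, ...) {
  cat(sprintf("%d-fold linear decoder on %d neurons, classes {%s}\n",
              x$k, x$n_neurons, paste(x$classes, collapse = ", ")))
  cat(sprintf("  CV accuracy %.3f (chance %.3f)\n", x$cv_accuracy,
              1 / length(x$classes)))
  invisible(x)
}

#' Probe a trained decoder with out-of-class trials
#'
#' Every fold-model classifies every probe trial (after applying that
#' fold's training standardization); the hard-label fractions are
#' averaged over the folds.
#'
#' @param model An `ic_decoder`.
#' @param X_probe probe-trials x neurons matrix (same neurons as used in
#'   training).
#' @param zero_idx Optional neuron indices zeroed out *after*
#'   standardization (see [zero_out()]).
#' @return Named vector of class fractions (sums to 1).
#' @export
probe <- function(model, X_probe, zero_idx = NULL) {
  if (ncol(X_probe) != model$n_neurons)
    stop("probe matrix has ", ncol(X_probe), " neurons; decoder expects ",
         model$n_neurons)
  fr <- matrix(0, length(model$folds), length(model$classes),
               dimnames = list(NULL, model$classes))
  for (f in seq_along(model$folds)) {
    fo <- model$folds[[f]]
    Z <- scale_cols(X_probe, fo$mu, fo$sd)
    if (length(zero_idx)) Z[, zero_idx] <- 0
    pred <- ovo_predict(fo$fit, Z, model$classes)
    fr[f, ] <- as.numeric(table(pred)) / nrow(X_probe)
  }
  colMeans(fr)
}

#' T_RE inference decoding
#'
#' Probes a decoder trained on `{I_C1, L_C1, L_C2, I_C2}` with the
#' ambiguous real-edge T_RE images and computes the difference between
#' classification as the corresponding illusory vs recombined image,
#' averaged across the two image sets.  A positive score means the
#' population's real-edge response resembles its illusory-image response
#' more than the pixel-matched control -- the signature of represented
#' inference.
#'
#' @param model `ic_decoder` with classes `I_C1`, `L_C1`, `L_C2`,
#'   `I_C2`.
#' @param X_tre1,X_tre2 Probe matrices of T_RE1 and T_RE2 trials.
#' @param zero_idx Optional neurons zeroed after standardization.
#' @return List `frac_ic`, `frac_lc`, `score = frac_ic - frac_lc`, and
#'   the per-image fraction tables.
#' @export
tre_inference <- function(model, X_tre1, X_tre2, zero_idx = NULL) {
  f1 <- probe(model, X_tre1, zero_idx)
  f2 <- probe(model, X_tre2, zero_idx)
  frac_ic <- mean(c(f1["I_C1"], f2["I_C2"]))
  frac_lc <- mean(c(f1["L_C1"], f2["L_C2"]))
  list(frac_ic = frac_ic, frac_lc = frac_lc, score = frac_ic - frac_lc,
       fractions = rbind(T_RE1 = f1, T_RE2 = f2))
}

#' X_RE inference decoding
#'
#' Probes a binary decoder trained on the real-edge images `X_RE1` vs
#' `X_RE2` with illusory-image trials; the score is the average
#' probability that I_C1 is decoded as X_RE1 and I_C2 as X_RE2 (chance
#' 0.5).
#'
#' @param model `ic_decoder` with classes `X_RE1`, `X_RE2`.
#' @param X_ic1,X_ic2 Probe matrices of I_C1 and I_C2 trials.
#' @return List `score`, `frac_ic1_as_xre1`, `frac_ic2_as_xre2`.
#' @export
xre_inference <- function(model, X_ic1, X_ic2) {
  f1 <- probe(model, X_ic1)
  f2 <- probe(model, X_ic2)
  list(score = mean(c(f1["X_RE1"], f2["X_RE2"])),
       frac_ic1_as_xre1 = unname(f1["X_RE1"]),
       frac_ic2_as_xre2 = unname(f2["X_RE2"]))
}

#' Zero out a neuron subset in the decoder input
#'
#' Re-evaluates a trained decoder after setting the indicated neurons'
#' *standardized* input to zero (i.e. clamping them at their training
#' mean) -- removing their information without refitting.
#'
#' @param model A trained `ic_decoder`.
#' @param X,y The matrix and labels the model was trained on.
#' @param subset Neuron indices (or logical mask) to zero.
#' @return List `cv_accuracy`, `fold_accuracy`, `confusion` recomputed on
#'   the held-out folds with the subset zeroed.
#' @export
zero_out <- function(model, X, y, subset) {
  y <- factor(y, levels = model$classes)
  zero_idx <- if (is.logical(subset)) which(subset) else subset
  conf <- matrix(0, length(model$classes), length(model$classes),
                 dimnames = list(true = model$classes,
                                 predicted = model$classes))
  acc <- numeric(length(model$folds))
  for (f in seq_along(model$folds)) {
    fo <- model$folds[[f]]
    Z <- scale_cols(X[fo$test_idx, , drop = FALSE], fo$mu, fo$sd)
    if (length(zero_idx)) Z[, zero_idx] <- 0
    pred <- ovo_predict(fo$fit, Z, model$classes)
    acc[f] <- mean(pred == y[fo$test_idx])
    conf <- conf + table(y[fo$test_idx], pred)
  }
  list(cv_accuracy = mean(acc), fold_accuracy = acc,
       confusion = conf / pmax(rowSums(conf), 1), zeroed = zero_idx)
}

#' Train a decoder on a neuron subset only
#'
#' @param X,y Full matrix and labels.
#' @param subset Neuron indices (or logical mask) to keep.
#' @inheritParams train_cv_decoder
#' @return An `ic_decoder` trained on `X[, subset]`, with attribute
#'   `subset`.
#' @export
train_subset <- function(X, y, subset, k = 10, seed = 1, cost = 1) {
  keep <- if (is.logical(subset)) which(subset) else subset
  m <- train_cv_decoder(X[, keep, drop = FALSE], y, k = k, seed = seed,
                        cost = cost)
  m$subset <- keep
  m
}

## ---- holography --------------------------------------------------------

#' Non-photoactivated neuron mask
#'
#' Neurons farther than `min_dist_um` from every holographic target
#' (50 um for standard holography, 25 um in mesoscope mode).
#'
#' @param neurons Neuron table with `x_um`, `y_um`.
#' @param target_ids Ids of the targeted neurons.
#' @param min_dist_um Exclusion radius.
#' @return Logical mask (targets themselves are `FALSE`).
#' @export
nonphoto_mask <- function(neurons, target_ids, min_dist_um = 50) {
  ti <- match(target_ids, neurons$id)
  if (anyNA(ti)) stop("unknown target ids")
  dx <- outer(neurons$x_um, neurons$x_um[ti], "-")
  dy <- outer(neurons$y_um, neurons$y_um[ti], "-")
  dmin <- apply(sqrt(dx^2 + dy^2), 1, min)
  dmin > min_dist_um
}

#' Validate holographic targets against the segmented population
#'
#' A target coordinate is valid only if the closest neuron lies within
#' `max_dist_um` of it.
#'
#' @param target_xy Matrix (targets x 2) of target coordinates (um).
#' @param neurons Neuron table with `x_um`, `y_um`.
#' @param max_dist_um Matching radius (10 um by convention).
#' @return data.frame `target`, `neuron_id`, `dist_um`, `valid`.
#' @export
validate_targets <- function(target_xy, neurons, max_dist_um = 10) {
  target_xy <- rbind(target_xy)
  out <- data.frame(target = seq_len(nrow(target_xy)),
                    neuron_id = NA_integer_, dist_um = NA_real_,
                    valid = FALSE)
  for (i in seq_len(nrow(target_xy))) {
    d <- sqrt((neurons$x_um - target_xy[i, 1])^2 +
                (neurons$y_um - target_xy[i, 2])^2)
    j <- which.min(d)
    out$neuron_id[i] <- neurons$id[j]
    out$dist_um[i] <- d[j]
    out$valid[i] <- d[j] <= max_dist_um
  }
  out
}

#' Cross-decode holography-evoked activity with a visually trained decoder
#'
#' The holography response matrix is normalized per neuron across all
#' holography trials (mean subtracted, s.d. divided); each fold-model of
#' the visually trained decoder then classifies every holography trial,
#' and the fraction of trials assigned the ensemble's expected visual
#' label is averaged over folds.  Only ensembles with at least
#' `min_targets` targets are analyzed.
#'
#' @param model `ic_decoder` trained on visual trials of the *same*
#'   neuron columns as `holo_responses`.
#' @param holo_responses holography-trials x neurons matrix.
#' @param holo_trials data.frame with `ensemble` per trial.
#' @param expected_map Named character: ensemble name -> expected visual
#'   label.
#' @param ensemble_sizes Named target counts per ensemble (for the
#'   `min_targets` rule); NULL skips the rule.
#' @param min_targets Minimum number of targets for analysis.
#' @return data.frame `ensemble`, `n_trials`, `expected_label`,
#'   `expected_fraction`, plus attribute `fractions` (ensembles x
#'   classes).
#' @export
holo_cross_decode <- function(model, holo_responses, holo_trials,
                              expected_map, ensemble_sizes = NULL,
                              min_targets = 10) {
  if (ncol(holo_responses) != model$n_neurons)
    stop("holography matrix and decoder use different neuron subsets")
  ens <- intersect(names(expected_map), unique(holo_trials$ensemble))
  if (!is.null(ensemble_sizes))
    ens <- ens[ensemble_sizes[ens] >= min_targets]
  mu <- colMeans(holo_responses)
  s <- floor_sd(apply(holo_responses, 2, stats::sd))
  Z <- scale_cols(holo_responses, mu, s)
  fr <- matrix(0, length(ens), length(model$classes),
               dimnames = list(ens, model$classes))
  for (e in ens) {
    rows <- which(holo_trials$ensemble == e)
    fe <- matrix(0, length(model$folds), length(model$classes))
    for (f in seq_along(model$folds)) {
      pred <- ovo_predict(model$folds[[f]]$fit, Z[rows, , drop = FALSE],
                          model$classes)
      fe[f, ] <- as.numeric(table(pred)) / length(rows)
    }
    fr[e, ] <- colMeans(fe)
  }
  out <- data.frame(ensemble = ens,
                    n_trials = vapply(ens, function(e)
                      sum(holo_trials$ensemble == e), integer(1)),
                    expected_label = unname(expected_map[ens]),
                    expected_fraction = fr[cbind(ens, expected_map[ens])],
                    row.names = NULL)
  attr(out, "fractions") <- fr
  out
}

#' One-tailed signed-rank test of expected-label fractions against chance
#'
#' @param fractions Per-ensemble expected-label fractions.
#' @param chance Chance level (0.25 for the four-class decoder).
#' @param alternative Test direction.
#' @return The `htest` object.
#' @export
holo_signed_rank <- function(fractions, chance = 0.25,
                             alternative = "greater") {
  stats::wilcox.test(fractions, mu = chance, alternative = alternative,
                     exact = FALSE)
}

#' Holography PSTH contrast between visually responsive groups
#'
#' For each ensemble, subtracts per-neuron baseline activity (-1 to 0 s
#' relative to holography onset), averages the 0-1 s window across that
#' ensemble's trials, and contrasts neurons visually responsive to the
#' ensemble's expected image against non-responsive neurons.
#'
#' @param holo A [simulate_holography()] session with `timecourse`.
#' @param responsive Named list: ensemble name -> logical vector marking
#'   the visually responsive group.
#' @param subset Optional logical mask of neurons to include (e.g. the
#'   non-photoactivated mask).
#' @param baseline,window Time windows in seconds (bin left edges).
#' @return data.frame `ensemble`, `mean_responsive`,
#'   `mean_nonresponsive`, `contrast`, plus the one-tailed signed-rank
#'   p-value across ensembles as attribute `p_value`.
#' @export
holo_psth_contrast <- function(holo, responsive, subset = NULL,
                               baseline = c(-1, 0), window = c(0, 1)) {
  if (is.null(holo$timecourse))
    stop("holography session was simulated without a time course")
  bt <- holo$bin_times
  bl <- which(bt >= baseline[1] & bt < baseline[2])
  wn <- which(bt >= window[1] & bt < window[2])
  ens <- names(responsive)
  out <- data.frame(ensemble = ens, mean_responsive = NA_real_,
                    mean_nonresponsive = NA_real_, contrast = NA_real_)
  for (i in seq_along(ens)) {
    rows <- which(holo$trials$ensemble == ens[i])
    tc <- holo$timecourse[rows, , , drop = FALSE]
    resp <- apply(tc[, , wn, drop = FALSE], 2, mean) -
      apply(tc[, , bl, drop = FALSE], 2, mean)
    grp <- responsive[[i]]
    keep <- if (is.null(subset)) rep(TRUE, length(resp)) else subset
    out$mean_responsive[i] <- mean(resp[grp & keep])
    out$mean_nonresponsive[i] <- mean(resp[!grp & keep])
    out$contrast[i] <- out$mean_responsive[i] - out$mean_nonresponsive[i]
  }
  attr(out, "p_value") <- stats::wilcox.test(out$contrast, mu = 0,
                                             alternative = "greater",
                                             exact = FALSE)$p.value
  out
}
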