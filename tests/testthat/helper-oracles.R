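# Shared fixtures and independent oracles used across the test files.
# Everything is generated in code at test time.

# battery rendered once per test run (all stimulus tests reuse it)
fx_spec <- stimulus_spec()
fx_set <- render_battery(fx_spec)

# reduced deterministic sessions
fx <- make_fixtures(seed = 1)

# --- naive CCG oracle: literal double loop over the defining sum -------
naive_ccg <- function(x1, x2, tau_max = 100) {
  L <- length(x1)
  acc <- numeric(2 * tau_max + 1)
  for (t in (1 + tau_max):(L - tau_max)) {
    if (x1[t] == 0) next
    for (tau in -tau_max:tau_max) {
      acc[tau + tau_max + 1] <- acc[tau + tau_max + 1] +
        x1[t] * x2[t + tau]
    }
  }
  acc / sqrt(sum(x1) * sum(x2))
}

# naive boxcar smoothing (explicit kernel sum, zero-padded)
naive_smooth <- function(x, w) {
  h <- (w - 1) %/% 2
  L <- length(x)
  vapply(seq_len(L), function(t) {
    idx <- max(1, t - h):min(L, t + h)
    sum(x[idx]) / w
  }, numeric(1))
}

# --- nearest-centroid decoder oracle (for CV-accuracy cross-checks) ----
centroid_cv_accuracy <- function(X, y, k = 10, seed = 1) {
  y <- factor(y)
  set.seed(seed)
  fold <- integer(nrow(X))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  acc <- numeric(k)
  for (f in seq_len(k)) {
    tr <- fold != f; te <- fold == f
    cent <- sapply(levels(y), function(cl)
      colMeans(X[tr & y == cl, , drop = FALSE]))
    d <- sapply(seq_len(ncol(cent)), function(ci)
      rowSums(sweep(X[te, , drop = FALSE], 2, cent[, ci])^2))
    pred <- levels(y)[max.col(-d)]
    acc[f] <- mean(pred == y[te])
  }
  mean(acc)
}

# --- exhaustive margin-maximizing separator on 2D two-class toys -------
# scans boundary directions on a fine grid and keeps the direction (and
# midpoint threshold) with the largest worst-case margin
best_margin_separator <- function(X, y) {
  y <- factor(y)
  stopifnot(ncol(X) == 2, nlevels(y) == 2)
  best <- NULL
  for (th in seq(0, pi, length.out = 3601)[-3601]) {
    w <- c(cos(th), sin(th))
    pr <- X %*% w
    a <- pr[y == levels(y)[1]]; b <- pr[y == levels(y)[2]]
    if (max(a) < min(b)) {
      marg <- min(b) - max(a); cut <- (max(a) + min(b)) / 2; sgn <- -1
    } else if (max(b) < min(a)) {
      marg <- min(a) - max(b); cut <- (max(b) + min(a)) / 2; sgn <- 1
    } else next
    if (is.null(best) || marg > best$margin)
      best <- list(w = w, cut = cut, sgn = sgn, margin = marg)
  }
  best
}
predict_margin_separator <- function(sep, X, levels) {
  pr <- as.vector(X %*% sep$w)
  ifelse(sep$sgn * (pr - sep$cut) > 0, levels[1], levels[2])
}

# --- brute-force AUROC by pair counting --------------------------------
naive_auroc <- function(x, y) {
  s <- 0
  for (xi in x) for (yi in y)
    s <- s + (xi > yi) + 0.5 * (xi == yi)
  s / (length(x) * length(y))
}
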