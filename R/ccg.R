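# Spike-train cross-correlogram analysis: the edge-trimmed, geometric-
# mean-normalized CCG, slow-rate correction by subtracting the CCG of
# boxcar-smoothed trains, putative-excitatory-connection calling from the
# 1-10 ms peak against a 7x flank-s.d. threshold, and class-wise input
# count comparison.
#
#   ccg(tau) = sum_{t = 1+tau_max}^{L - tau_max} x1(t) x2(t + tau)
#              / sqrt(lambda1 * lambda2)
#
# lambda are the net spike counts of the *full* trains.  Two
# implementations are provided: a dense reference that evaluates the sum
# literally, and a sparse spike-time path that is exactly equal on
# integer inputs (asserted in the test suite) but scales to hour-long
# recordings.

#' Construct a spike-train pair for CCG analysis
#'
#' @param x1,x2 Either dense per-millisecond count vectors of equal
#'   length, or sorted spike times in seconds (then `duration_s` is
#'   required).
#' @param tau_max Maximum lag in ms (100, so the +/-50-100 ms flanks are
#'   available).
#' @param duration_s Recording duration when `x1`/`x2` are spike times.
#' @param bin_ms Bin width (1 ms fixed for the analysis).
#' @return Object of class `spike_train_pair`.
#' @export
spike_train_pair <- function(x1, x2, tau_max = 100, duration_s = NULL,
                             bin_ms = 1) {
  if (is.null(duration_s)) {
    if (length(x1) != length(x2))
      stop("dense spike trains must have equal length")
    L <- length(x1)
    i1 <- which(x1 > 0); i2 <- which(x2 > 0)
    p <- list(idx1 = i1, cnt1 = as.numeric(x1[i1]), idx2 = i2,
              cnt2 = as.numeric(x2[i2]), L = L,
              lam1 = as.numeric(sum(x1)), lam2 = as.numeric(sum(x2)),
              tau_max = tau_max)
  } else {
    L <- round(duration_s * 1000 / bin_ms)
    b1 <- bin_spike_times(x1, duration_s, bin_ms)
    b2 <- bin_spike_times(x2, duration_s, bin_ms)
    i1 <- which(b1 > 0); i2 <- which(b2 > 0)
    p <- list(idx1 = i1, cnt1 = as.numeric(b1[i1]), idx2 = i2,
              cnt2 = as.numeric(b2[i2]), L = L,
              lam1 = as.numeric(sum(b1)), lam2 = as.numeric(sum(b2)),
              tau_max = tau_max)
  }
  if (p$L <= 2 * tau_max)
    stop("spike trains must be longer than twice tau_max")
  class(p) <- "spike_train_pair"
  p
}

dense_train <- function(idx, cnt, L) {
  x <- numeric(L); x[idx] <- cnt; x
}

# centered boxcar moving sum scaled to a moving average, zero-padded at
# the ends (the kernel support simply extends past the train)
boxcar_smooth <- function(x, w) {
  h <- (w - 1) %/% 2
  S <- c(0, cumsum(x))
  L <- length(x)
  hi <- pmin(seq_len(L) + h, L)
  lo <- pmax(seq_len(L) - h, 1L)
  (S[hi + 1] - S[lo]) / w
}

ccg_dense_core <- function(y1, y2, tau_max) {
  L <- length(y1)
  a <- tau_max + 1; b <- L - tau_max
  win <- y1[a:b]
  vapply(-tau_max:tau_max, function(tau)
    sum(win * y2[(a + tau):(b + tau)]), numeric(1))
}

# sparse raw CCG: tabulate weighted spike-index differences with the
# reference spike inside the trimmed window
ccg_sparse_raw <- function(p) {
  a <- p$tau_max + 1; b <- p$L - p$tau_max
  sel <- p$idx1 >= a & p$idx1 <= b
  s1 <- p$idx1[sel]; c1 <- p$cnt1[sel]
  acc <- numeric(2 * p$tau_max + 1)
  if (!length(s1) || !length(p$idx2)) return(acc)
  lo <- findInterval(s1 - p$tau_max - 0.5, p$idx2)
  hi <- findInterval(s1 + p$tau_max + 0.5, p$idx2)
  np <- hi - lo
  keep <- np > 0
  if (!any(keep)) return(acc)
  j <- sequence(np[keep]) + rep(lo[keep], np[keep])
  i <- rep(which(keep), np[keep])
  d <- p$idx2[j] - s1[i]
  w <- p$cnt2[j] * c1[i]
  tmp <- rowsum(w, d + p$tau_max + 1)
  acc[as.integer(rownames(tmp))] <- tmp
  acc
}

# sparse smoothed CCG, exactly equal to the dense CCG of boxcar-smoothed
# trains: interior spike pairs contribute the boxcar autocorrelation
# triangle at their index difference; pairs whose smoothing kernels reach
# the trimmed-window edges are evaluated by the interval-overlap count.
ccg_sparse_smoothed <- function(p, w) {
  h <- (w - 1) %/% 2
  tau_max <- p$tau_max
  a <- tau_max + 1; b <- p$L - tau_max
  reach <- tau_max + w - 1
  sel1 <- p$idx1 >= a - h & p$idx1 <= b + h
  s1 <- p$idx1[sel1]; c1 <- p$cnt1[sel1]
  acc <- numeric(2 * tau_max + 1)
  if (!length(s1) || !length(p$idx2)) return(acc)
  lo <- findInterval(s1 - reach - 0.5, p$idx2)
  hi <- findInterval(s1 + reach + 0.5, p$idx2)
  np <- hi - lo
  keep <- np > 0
  if (!any(keep)) return(acc)
  j <- sequence(np[keep]) + rep(lo[keep], np[keep])
  i <- rep(which(keep), np[keep])
  s1p <- s1[i]; s2p <- p$idx2[j]
  wp <- c1[i] * p$cnt2[j]
  d <- s2p - s1p
  interior <- s1p >= a + h + w - 1 & s1p <= b - h - w + 1
  # interior pairs: histogram over d, then triangle convolution
  if (any(interior)) {
    hist_d <- numeric(2 * reach + 1)
    tmp <- rowsum(wp[interior], d[interior] + reach + 1)
    hist_d[as.integer(rownames(tmp))] <- tmp
    offs <- -(w - 1):(w - 1)
    tri <- (w - abs(offs)) / w^2
    taus <- -tau_max:tau_max
    for (k in seq_along(offs)) {
      src <- taus + offs[k] + reach + 1
      acc <- acc + tri[k] * hist_d[src]
    }
  }
  # edge pairs: exact overlap count of the two kernel supports with the
  # summation window, per lag
  if (any(!interior)) {
    es1 <- s1p[!interior]; es2 <- s2p[!interior]; ew <- wp[!interior]
    for (q in seq_along(es1)) {
      taus <- (es2[q] - es1[q]) + -(w - 1):(w - 1)
      taus <- taus[abs(taus) <= tau_max]
      if (!length(taus)) next
      m <- es2[q] - taus
      cnt <- pmax(0, pmin(es1[q] + h, m + h, b) -
                    pmax(es1[q] - h, m - h, a) + 1)
      acc[taus + tau_max + 1] <- acc[taus + tau_max + 1] +
        ew[q] * cnt / w^2
    }
  }
  acc
}

#' Compute the raw cross-correlogram
#'
#' Evaluates the edge-trimmed, `sqrt(lambda1*lambda2)`-normalized CCG at
#' lags `-tau_max ... tau_max` (1-ms bins).
#'
#' @param pair A [spike_train_pair()].
#' @param method `"sparse"` (spike-time path, default) or `"dense"`
#'   (literal evaluation of the defining sum); both are exactly equal.
#' @return Numeric vector of length `2*tau_max + 1`, named by lag (ms).
#' @export
compute_ccg <- function(pair, method = c("sparse", "dense")) {
  method <- match.arg(method)
  if (pair$lam1 == 0 || pair$lam2 == 0)
    stop("CCG undefined: a train has zero spikes")
  acc <- if (method == "sparse") {
    ccg_sparse_raw(pair)
  } else {
    ccg_dense_core(dense_train(pair$idx1, pair$cnt1, pair$L),
                   dense_train(pair$idx2, pair$cnt2, pair$L),
                   pair$tau_max)
  }
  stats::setNames(acc / sqrt(pair$lam1 * pair$lam2),
                  -pair$tau_max:pair$tau_max)
}

#' Slow-rate-corrected cross-correlogram
#'
#' Computes the raw CCG, the CCG of the trains smoothed with a centered
#' `smooth_ms` boxcar (which captures co-fluctuations in rate slower than
#' the smoothing window), their difference (the corrected CCG), and the
#' flank s.d. of the corrected CCG over lags 50-100 ms on both sides.
#'
#' @param pair A [spike_train_pair()].
#' @param smooth_ms Smoothing window (25 ms by convention; must be odd).
#' @param method `"sparse"` or `"dense"`.
#' @return Object of class `ccg_result`: `lags`, `raw`, `smoothed`,
#'   `corrected`, `flank_sd`.
#' @export
correct_ccg <- function(pair, smooth_ms = 25,
                        method = c("sparse", "dense")) {
  method <- match.arg(method)
  w <- as.integer(smooth_ms)
  if (w %% 2 == 0) stop("smooth_ms must be odd (centered boxcar)")
  raw <- compute_ccg(pair, method)
  sm <- if (method == "sparse") {
    ccg_sparse_smoothed(pair, w) / sqrt(pair$lam1 * pair$lam2)
  } else {
    y1 <- boxcar_smooth(dense_train(pair$idx1, pair$cnt1, pair$L), w)
    y2 <- boxcar_smooth(dense_train(pair$idx2, pair$cnt2, pair$L), w)
    ccg_dense_core(y1, y2, pair$tau_max) / sqrt(pair$lam1 * pair$lam2)
  }
  lags <- -pair$tau_max:pair$tau_max
  corrected <- unname(raw) - sm
  flank <- abs(lags) >= 50 & abs(lags) <= 100
  structure(list(lags = lags, raw = unname(raw), smoothed = sm,
                 corrected = corrected,
                 flank_sd = stats::sd(corrected[flank])),
            class = "ccg_result")
}

#' @export
print.ccg_result <- function(x, ...) {
  win <- x$lags >= 1 & x$lags <= 10
  cat(sprintf("CCG: peak %.4g at %d ms in 1-10 ms window; flank sd %.4g\n",
              max(x$corrected[win]), x$lags[win][which.max(x$corrected[win])],
              x$flank_sd))
  invisible(x)
}

#' Call a putative excitatory connection
#'
#' Flags a pair as connected (pre -> post) iff the corrected CCG's peak
#' in the 1-10 ms lag window exceeds `threshold_mult` times the flank
#' s.d.
#'
#' @param result A [correct_ccg()] result.
#' @param threshold_mult Threshold multiplier (7 by convention).
#' @param window_ms Peak search window.
#' @return List `is_connection`, `peak`, `lag_ms`, `threshold`,
#'   `flank_sd`.
#' @export
call_connection <- function(result, threshold_mult = 7,
                            window_ms = c(1, 10)) {
  win <- result$lags >= window_ms[1] & result$lags <= window_ms[2]
  peak <- max(result$corrected[win])
  lag <- result$lags[win][which.max(result$corrected[win])]
  thr <- threshold_mult * result$flank_sd
  list(is_connection = is.finite(thr) && peak > thr,
       peak = peak, lag_ms = lag, threshold = thr,
       flank_sd = result$flank_sd)
}

#' Scan unit pairs for putative excitatory connections
#'
#' Evaluates the corrected CCG in both directions for every requested
#' ordered pair and calls connections with the flank-s.d. rule.
#'
#' @param spikes A [simulate_spike_trains()] set (or list of spike-time
#'   vectors with attributes `duration_s`).
#' @param pairs Two-column matrix of ordered (pre, post) unit indices;
#'   NULL scans all ordered pairs.
#' @param tau_max,smooth_ms,threshold_mult CCG constants.
#' @return data.frame `pre`, `post`, `peak`, `lag_ms`, `flank_sd`,
#'   `is_connection`.
#' @export
ccg_scan <- function(spikes, pairs = NULL, tau_max = 100, smooth_ms = 25,
                     threshold_mult = 7) {
  n <- length(spikes$times)
  if (is.null(pairs)) {
    pairs <- expand.grid(pre = seq_len(n), post = seq_len(n))
    pairs <- as.matrix(pairs[pairs$pre != pairs$post, ])
  }
  out <- data.frame(pre = pairs[, 1], post = pairs[, 2], peak = NA_real_,
                    lag_ms = NA_integer_, flank_sd = NA_real_,
                    is_connection = FALSE)
  for (r in seq_len(nrow(out))) {
    p <- spike_train_pair(spikes$times[[out$pre[r]]],
                          spikes$times[[out$post[r]]],
                          tau_max = tau_max,
                          duration_s = spikes$duration_s)
    cc <- call_connection(correct_ccg(p, smooth_ms), threshold_mult)
    out$peak[r] <- cc$peak
    out$lag_ms[r] <- cc$lag_ms
    out$flank_sd[r] <- cc$flank_sd
    out$is_connection[r] <- cc$is_connection
  }
  out
}

#' Compare putative-input counts between two neuron classes
#'
#' Counts, for each neuron of two classes, the incoming called
#' connections from a source population (e.g. higher-visual-area units)
#' and compares the two count distributions with a two-sided rank-sum
#' test.
#'
#' @param edges Edge table from [ccg_scan()] (only rows with
#'   `is_connection` count).
#' @param source_ids Unit ids allowed as presynaptic sources.
#' @param class_a_ids,class_b_ids Unit ids of the two target classes.
#' @return List `counts_a`, `counts_b`, `p_value`.
#' @export
input_count_compare <- function(edges, source_ids, class_a_ids,
                                class_b_ids) {
  called <- edges[edges$is_connection & edges$pre %in% source_ids, ]
  cnt <- function(ids) vapply(ids, function(i) sum(called$post == i),
                              integer(1))
  ca <- cnt(class_a_ids); cb <- cnt(class_b_ids)
  p <- if (length(ca) && length(cb))
    stats::wilcox.test(ca, cb, exact = FALSE)$p.value else NA_real_
  list(counts_a = ca, counts_b = cb, p_value = p)
}
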