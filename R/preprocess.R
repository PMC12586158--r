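# Trace normalization, response-matrix construction, and the trial/unit
# filters applied before classification and decoding.

#' Neuropil correction
#'
#' Subtracts the neuropil signal from an ROI trace:
#' `Fc = F_roi - coeff * F_neu`.
#'
#' @param f_roi,f_neu Numeric traces of equal length.
#' @param coeff Neuropil coefficient (0.7 by convention).
#' @return The corrected trace.
#' @export
neuropil_correct <- function(f_roi, f_neu, coeff = 0.7) {
  if (length(f_roi) != length(f_neu))
    stop("f_roi and f_neu must have equal length")
  f_roi - coeff * f_neu
}

#' Z-score a trace per recording block
#'
#' Each continuous block is z-scored independently:
#' `(Fc - mean(Fc)) / sd(Fc)` over the block's samples.
#'
#' @param fc Numeric trace.
#' @param blocks NULL (one block), or a vector of block ids per sample.
#' @return The z-scored trace.
#' @export
zscore_trace <- function(fc, blocks = NULL) {
  if (is.null(blocks)) blocks <- rep(1L, length(fc))
  if (length(blocks) != length(fc))
    stop("blocks must have one id per sample")
  out <- fc
  for (b in unique(blocks)) {
    sel <- blocks == b
    s <- stats::sd(fc[sel])
    if (!is.finite(s) || s == 0)
      stop("zero-variance block: cannot z-score block ", b)
    out[sel] <- (fc[sel] - mean(fc[sel])) / s
  }
  out
}

#' Baseline-subtracted z-scored response
#'
#' Subtracts the mean z-scored activity over the baseline (gray-screen)
#' window from the trace.
#'
#' @param zf A z-scored trace.
#' @param baseline_idx Indices of the baseline samples.
#' @return The baseline-subtracted trace.
#' @export
delta_zf <- function(zf, baseline_idx) {
  if (!length(baseline_idx)) stop("empty baseline window")
  zf - mean(zf[baseline_idx])
}

#' Build a trials x neurons response matrix
#'
#' Averages each neuron's trace over the stimulus-presentation window of
#' each trial.  For an [simulate_population()] session (which already
#' stores one response per trial) the stored matrix is returned.
#'
#' @param x Either an `ic_session`, or a samples x neurons trace matrix.
#' @param trials Trial table with `t_on` (required for trace input).
#' @param window Response window in seconds relative to stimulus onset
#'   (`c(0, 1)` for 1-s presentations; `c(0, 0.4)` for 0.4-s
#'   electrophysiology presentations).
#' @param times Sample times (seconds) for trace input.
#' @return trials x neurons numeric matrix.
#' @export
build_response_matrix <- function(x, trials = NULL, window = c(0, 1),
                                  times = NULL) {
  if (inherits(x, "ic_session")) return(x$responses)
  if (is.null(trials) || is.null(times))
    stop("trace input requires `trials` and `times`")
  out <- matrix(NA_real_, nrow(trials), ncol(x))
  for (i in seq_len(nrow(trials))) {
    sel <- times >= trials$t_on[i] + window[1] &
      times < trials$t_on[i] + window[2]
    if (!any(sel))
      stop("response window contains no samples for trial ", trials$trial[i])
    out[i, ] <- colMeans(x[sel, , drop = FALSE])
  }
  rownames(out) <- trials$trial
  out
}

# Mode of a 2D point cloud on a 1-degree-binned histogram; ties broken by
# the earliest bin in column-major order.
pupil_mode <- function(x, y, bin_deg = 1) {
  bx <- floor(x / bin_deg)
  by <- floor(y / bin_deg)
  key <- paste(bx, by)
  tab <- table(factor(key, levels = unique(key)))
  best <- names(tab)[which.max(tab)]  # first max = earliest bin
  sel <- key == best
  c(x = mean(x[sel]), y = mean(y[sel]))
}

#' Fixed-gaze trial filter
#'
#' Keeps a trial only if every in-trial pupil sample lies within
#' `threshold_deg` of the resting pupil position (the mode of the pupil
#' position on a 1-degree-binned 2D histogram).
#'
#' @param pupil data.frame `time_s`, `x_deg`, `y_deg` (see
#'   [simulate_pupil()]).
#' @param trials Trial table with `t_on`, `t_off`.
#' @param threshold_deg Maximum excursion (8 degrees by convention).
#' @return Logical vector, one per trial.
#' @export
fixed_gaze_filter <- function(pupil, trials, threshold_deg = 8) {
  m <- pupil_mode(pupil$x_deg, pupil$y_deg)
  d <- sqrt((pupil$x_deg - m["x"])^2 + (pupil$y_deg - m["y"])^2)
  vapply(seq_len(nrow(trials)), function(i) {
    sel <- pupil$time_s >= trials$t_on[i] & pupil$time_s < trials$t_off[i]
    all(d[sel] <= threshold_deg)
  }, logical(1))
}

#' Regular-spiking unit filter
#'
#' Keeps units whose extracellular spike waveform has a trough-to-peak
#' width of at least `min_ms` (putative excitatory, broad-waveform
#' units); the boundary is inclusive.
#'
#' @param trough_to_peak_ms Numeric vector of waveform widths.
#' @param min_ms Minimum width (0.4 ms by convention).
#' @return Logical mask.
#' @export
rs_filter <- function(trough_to_peak_ms, min_ms = 0.4) {
  trough_to_peak_ms >= min_ms
}
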