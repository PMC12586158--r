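# Functional-ensemble identification: exclusively center-responsive
# neurons, IC-encoders, LC-encoders, segment responders, orientation
# preference matching, and AUROC-based ensemble balancing.
#
# All decisions are nonparametric rank tests; labels are therefore
# invariant to any trial-order permutation and to monotone response
# rescaling.

## ---- Tukey-Kramer on mean ranks ---------------------------------------

# Pairwise multiple comparison after a Kruskal-Wallis omnibus test:
# studentized-range comparison of group mean ranks with tie-corrected
# pooled rank variance (the behaviour of the usual kruskalwallis ->
# multcompare chain).  Returns the matrix of pairwise p-values.
tukey_kramer_ranks <- function(values, groups) {
  groups <- as.factor(groups)
  k <- nlevels(groups)
  N <- length(values)
  r <- rank(values)
  mr <- tapply(r, groups, mean)
  nn <- tabulate(groups)
  ties <- table(values)
  tiecor <- sum(ties^3 - ties) / (12 * (N - 1))
  v <- N * (N + 1) / 12 - tiecor
  p <- matrix(NA_real_, k, k, dimnames = list(levels(groups), levels(groups)))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    se <- sqrt(v * (1 / nn[i] + 1 / nn[j]))
    q <- sqrt(2) * abs(mr[i] - mr[j]) / se
    p[i, j] <- p[j, i] <- stats::ptukey(q, k, Inf, lower.tail = FALSE)
  }
  attr(p, "mean_ranks") <- mr
  p
}

## ---- exclusively center-responsive ------------------------------------

#' Exclusively center-responsive neurons
#'
#' Rank-sum test of each receptive-field-mapping position against
#' gray-screen trials (two-sided), Holm-corrected over the nine
#' positions.  A neuron is kept iff the center position (which coincides
#' with the illusory gap region) is significant with a positive sign and
#' none of the eight peripheral positions is significant.
#'
#' @param responses trials x neurons matrix of mapping-block responses.
#' @param condition Per-trial condition: `"rf_pos_1"` ... `"rf_pos_9"`
#'   or `"gray"`.
#' @param alpha Test level.
#' @param center Label of the center position.
#' @return Logical mask with attribute `p` (neurons x 9 Holm-corrected
#'   p-values).
#' @export
find_center_exclusive <- function(responses, condition, alpha = 0.05,
                                  center = "rf_pos_1") {
  pos <- paste0("rf_pos_", 1:9)
  need <- c(pos, "gray")
  cnt <- table(factor(condition, levels = need))
  if (any(cnt < 2))
    stop("need at least 2 trials per position condition and gray")
  gray <- responses[condition == "gray", , drop = FALSE]
  n <- ncol(responses)
  p <- matrix(NA_real_, n, 9, dimnames = list(NULL, pos))
  gt <- matrix(FALSE, n, 9, dimnames = list(NULL, pos))
  for (q in pos) {
    rq <- responses[condition == q, , drop = FALSE]
    for (i in seq_len(n)) {
      p[i, q] <- stats::wilcox.test(rq[, i], gray[, i], exact = FALSE)$p.value
      gt[i, q] <- mean(rank(c(rq[, i], gray[, i]))[seq_len(nrow(rq))]) >
        mean(rank(c(rq[, i], gray[, i]))[-seq_len(nrow(rq))])
    }
  }
  ph <- t(apply(p, 1, stats::p.adjust, method = "holm"))
  keep <- ph[, center] < alpha & gt[, center] &
    rowSums(ph[, setdiff(pos, center), drop = FALSE] < alpha) == 0
  attr(keep, "p") <- ph
  keep
}

## ---- IC / LC encoders --------------------------------------------------

ic_lc_classify <- function(responses, condition, alpha, pos_labels,
                           neg_labels, blank = "blank_circles") {
  conds <- c(blank, pos_labels, neg_labels)
  missing <- setdiff(conds, unique(condition))
  if (length(missing))
    stop("missing stimulus conditions: ", paste(missing, collapse = ", "))
  sel <- condition %in% conds
  cond <- factor(condition[sel], levels = conds)
  X <- responses[sel, , drop = FALSE]
  n <- ncol(X)
  cls <- rep("none", n)
  stats_df <- data.frame(kw_p = rep(NA_real_, n))
  for (lab in c(pos_labels, neg_labels))
    stats_df[[paste0("p_", lab)]] <- NA_real_
  for (i in seq_len(n)) {
    kw <- stats::kruskal.test(X[, i], cond)$p.value
    stats_df$kw_p[i] <- kw
    if (!is.finite(kw) || kw >= alpha) next
    pm <- tukey_kramer_ranks(X[, i], cond)
    mr <- attr(pm, "mean_ranks")
    sig_pos <- vapply(pos_labels, function(l)
      pm[blank, l] < alpha && mr[l] > mr[blank], logical(1))
    sig_neg <- vapply(neg_labels, function(l) pm[blank, l] < alpha, logical(1))
    for (lab in c(pos_labels, neg_labels))
      stats_df[[paste0("p_", lab)]][i] <- pm[blank, lab]
    # respond to exactly one of the target images, and to neither control
    if (sum(sig_pos) == 1 && !any(sig_neg))
      cls[i] <- names(sig_pos)[sig_pos]
  }
  attr(cls, "stats") <- stats_df
  cls
}

#' Identify IC-encoders
#'
#' A neuron is an IC-encoder iff it responds to exactly one of the two
#' illusory images and to neither recombined control: Kruskal-Wallis
#' omnibus across blank vs I_C1 vs L_C1 vs L_C2 vs I_C2 at `alpha`,
#' followed by Tukey-Kramer comparison on mean ranks; the selected I_C
#' must be significantly above blank, the other I_C and both L_C must be
#' non-significant against blank.
#'
#' @param responses trials x neurons response matrix.
#' @param condition Per-trial stimulus label.
#' @param alpha Test level.
#' @return Character vector (`"none"`, `"I_C1"` or `"I_C2"`) with the
#'   per-neuron test statistics as attribute `stats`.
#' @export
find_ic_encoders <- function(responses, condition, alpha = 0.05) {
  ic_lc_classify(responses, condition, alpha,
                 pos_labels = c("I_C1", "I_C2"),
                 neg_labels = c("L_C1", "L_C2"))
}

#' Identify LC-encoders
#'
#' Mirror of [find_ic_encoders()] with the roles of the illusory and
#' recombined images swapped: selective response to exactly one L_C image
#' and to neither I_C image.
#'
#' @inheritParams find_ic_encoders
#' @return Character vector (`"none"`, `"L_C1"` or `"L_C2"`).
#' @export
find_lc_encoders <- function(responses, condition, alpha = 0.05) {
  ic_lc_classify(responses, condition, alpha,
                 pos_labels = c("L_C1", "L_C2"),
                 neg_labels = c("I_C1", "I_C2"))
}

## ---- segment responders ------------------------------------------------

#' Identify segment responders
#'
#' One-sided rank-sum test (inward > outward) per inducer quadrant at
#' `alpha`; a neuron's class is the quadrant with the smallest p-value
#' among its significant quadrants (ties broken by larger AUROC).
#'
#' @param responses trials x neurons matrix.
#' @param condition Per-trial labels among `In_BR`, `Out_BR`, ...,
#'   `In_TR`, `Out_TR`.
#' @param alpha Test level.
#' @return Character vector (`"none"`, `"BR"`, `"BL"`, `"TL"`, `"TR"`)
#'   with per-quadrant p-values as attribute `p`.
#' @export
find_segment_responders <- function(responses, condition, alpha = 0.05) {
  quads <- c("BR", "BL", "TL", "TR")
  n <- ncol(responses)
  p <- matrix(NA_real_, n, 4, dimnames = list(NULL, quads))
  a <- matrix(NA_real_, n, 4, dimnames = list(NULL, quads))
  for (q in quads) {
    rin <- responses[condition == paste0("In_", q), , drop = FALSE]
    rout <- responses[condition == paste0("Out_", q), , drop = FALSE]
    if (!nrow(rin) || !nrow(rout))
      stop("missing In/Out trials for quadrant ", q)
    for (i in seq_len(n)) {
      p[i, q] <- stats::wilcox.test(rin[, i], rout[, i],
                                    alternative = "greater",
                                    exact = FALSE)$p.value
      a[i, q] <- auroc(rin[, i], rout[, i])
    }
  }
  cls <- vapply(seq_len(n), function(i) {
    sig <- which(p[i, ] < alpha)
    if (!length(sig)) return("none")
    best <- sig[order(p[i, sig], -a[i, sig])][1]
    quads[best]
  }, character(1))
  attr(cls, "p") <- p
  attr(cls, "auroc") <- a
  cls
}

## ---- orientation preference -------------------------------------------

#' Preferred-orientation match between illusory and real bars
#'
#' The preferred orientation in each battery is the orientation whose
#' images evoked the strongest mean response; a neuron matches when the
#' two argmax orientations are equal.
#'
#' @param ic_responses neurons x orientations matrix of mean responses to
#'   the illusory-bar battery (columns named by orientation).
#' @param ire_responses neurons x orientations matrix for the real-bar
#'   battery (column names must include the illusory orientations).
#' @return List: `pref_ic`, `pref_ire` (column names), `match` (logical),
#'   `match_fraction`.
#' @export
preferred_orientation_match <- function(ic_responses, ire_responses) {
  pref_ic <- colnames(ic_responses)[max.col(ic_responses, ties.method = "first")]
  pref_ire <- colnames(ire_responses)[max.col(ire_responses, ties.method = "first")]
  match <- pref_ic == pref_ire
  list(pref_ic = pref_ic, pref_ire = pref_ire, match = match,
       match_fraction = mean(match))
}

## ---- AUROC and ensemble balancing -------------------------------------

#' Ideal-observer AUROC
#'
#' Area under the ROC curve for discriminating two response samples,
#' computed from the Mann-Whitney U identity (ties contribute 1/2).
#'
#' @param x Responses under the positive condition.
#' @param y Responses under the negative condition.
#' @return AUROC in `[0, 1]` (1 = `x` perfectly above `y`).
#' @export
auroc <- function(x, y) {
  r <- rank(c(x, y))
  n1 <- length(x); n2 <- length(y)
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' Balance segment-responder ensembles across quadrants
#'
#' Trims every quadrant group to the size N of the smallest group,
#' keeping the top-N neurons by inward-vs-outward AUROC.
#'
#' @param segment_class Per-neuron quadrant labels (from
#'   [find_segment_responders()]).
#' @param responses trials x neurons matrix of segment-image responses.
#' @param condition Per-trial `In_*` / `Out_*` labels.
#' @return Named list of neuron indices (columns of `responses`), one
#'   equally sized vector per quadrant present.
#' @export
balance_segment_ensembles <- function(segment_class, responses, condition) {
  quads <- intersect(c("BR", "BL", "TL", "TR"), unique(segment_class))
  groups <- lapply(quads, function(q) which(segment_class == q))
  names(groups) <- quads
  sizes <- lengths(groups)
  if (!length(sizes) || any(sizes == 0)) return(groups)
  N <- min(sizes)
  lapply(quads, function(q) {
    idx <- groups[[q]]
    if (length(idx) == N) return(idx)
    rin <- responses[condition == paste0("In_", q), idx, drop = FALSE]
    rout <- responses[condition == paste0("Out_", q), idx, drop = FALSE]
    sc <- vapply(seq_along(idx), function(j) auroc(rin[, j], rout[, j]),
                 numeric(1))
    idx[order(sc, decreasing = TRUE)[seq_len(N)]]
  }) |> stats::setNames(quads)
}

#' Classify all functional ensembles of a session
#'
#' Convenience wrapper running [find_ic_encoders()],
#' [find_lc_encoders()] and [find_segment_responders()] on a session's
#' response matrix, plus [find_center_exclusive()] when mapping trials
#' are present.
#'
#' @param session An `ic_session`.
#' @param alpha Test level.
#' @return data.frame: `id`, `ic_class`, `lc_class`, `segment_class`,
#'   `center_exclusive` (NA when no mapping block).
#' @export
classify_session <- function(session, alpha = 0.05) {
  X <- session$responses
  cond <- session$trials$stimulus
  out <- data.frame(id = session$neurons$id)
  out$ic_class <- find_ic_encoders(X, cond, alpha)
  out$lc_class <- find_lc_encoders(X, cond, alpha)
  has_seg <- all(c("In_BR", "Out_BR") %in% cond)
  out$segment_class <- if (has_seg)
    find_segment_responders(X, cond, alpha) else NA_character_
  out$center_exclusive <- if (all(c("rf_pos_1", "gray") %in% cond))
    find_center_exclusive(X, cond, alpha) else NA
  out
}
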