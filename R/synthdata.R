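# Synthetic-session generator.  Produces populations with the statistical
# structure the downstream analyses assume: bottom-up receptive-field
# drive with orientation tuning, planted emergent IC signals, trial
# noise, planted recurrent/feedforward connectivity for holography
# trials, millisecond spike trains with planted synapses, and pupil
# traces.
#
# Generative model for a visual trial of stimulus s:
#   r_i = b_i + g_i * B_i(s) * O_i(s) + c_i * T_i(s) + eps,
#   eps ~ N(0, sigma_i^2)
# B_i: Gaussian-RF-weighted mean |pixel - background|.
# O_i: von Mises factor on the dominant local edge orientation inside the
#      RF (1 when the RF contains no oriented ink).
# T_i: indicator that s carries the neuron's planted emergent feature.

#' Build a synthetic neuron table
#'
#' Assigns positions, areas, receptive fields, orientation preferences,
#' gains and planted functional roles.  IC/LC-encoders get receptive
#' fields jittered around the illusory gap center and (for IC classes) an
#' orientation preference matching their illusory bar; segment responders
#' get receptive fields centered on the inward inducer bar of their
#' quadrant and a matching orientation preference; remaining neurons get
#' uniformly scattered receptive fields and preferences.
#'
#' @param n Total number of neurons.
#' @param seed Integer seed (the table is a pure function of the
#'   arguments).
#' @param n_ic_encoders Named counts of planted IC-encoders, e.g.
#'   `c(IC1 = 10, IC2 = 10)`.
#' @param n_lc_encoders Named counts of planted LC-encoders.
#' @param n_segment Named counts of planted segment responders per
#'   quadrant (`BR`, `BL`, `TL`, `TR`).
#' @param area_counts Named counts of neurons per visual area summing to
#'   at most `n`; unassigned neurons are V1. Areas other than V1 are
#'   placed in a laterally offset field so the holography distance rules
#'   behave as for a separate imaging region.
#' @param emergent_amp Emergent response amplitude `c` (response units)
#'   for planted encoders.
#' @param gain,baseline,noise_sd,rf_sigma_deg,tuning_kappa Population
#'   constants of the generative model.
#' @param field_um Side of the square field over which somata are placed
#'   (micrometers).
#' @return data.frame of class `neuron_table`; one row per neuron.
#' @export
make_neurons <- function(n = 200, seed = 1,
                         n_ic_encoders = c(IC1 = 10, IC2 = 10),
                         n_lc_encoders = c(LC1 = 0, LC2 = 0),
                         n_segment = c(BR = 12, BL = 12, TL = 12, TR = 12),
                         area_counts = c(V1 = n),
                         emergent_amp = 3,
                         gain = 2, baseline = 0, noise_sd = 1,
                         rf_sigma_deg = 5, tuning_kappa = 2,
                         field_um = 1000) {
  set.seed(child_seed(seed, 1))
  n_special <- sum(n_ic_encoders) + sum(n_lc_encoders) + sum(n_segment)
  if (n_special > n) stop("planted classes exceed population size")

  nt <- data.frame(id = seq_len(n),
                   x_um = stats::runif(n, 0, field_um),
                   y_um = stats::runif(n, 0, field_um),
                   z_um = stats::runif(n, 100, 300),
                   area = "V1", layer = "L2/3",
                   rf_x_deg = stats::runif(n, -24, 24),
                   rf_y_deg = stats::runif(n, -24, 24),
                   rf_sigma_deg = rf_sigma_deg,
                   pref_ori_deg = stats::runif(n, 0, 180),
                   tuning_kappa = tuning_kappa,
                   gain = gain, baseline = baseline,
                   emergent_class = "none", emergent_amp = 0,
                   noise_sd = noise_sd,
                   stringsAsFactors = FALSE)

  # area layout: non-V1 areas are shifted by 2 mm per area index so they
  # occupy disjoint cortical fields (as on a mesoscope field-of-view)
  areas <- rep(names(area_counts), area_counts)
  if (length(areas) > n) stop("area_counts exceed population size")
  nt$area[seq_along(areas)] <- areas
  hva <- nt$area != "V1"
  if (any(hva)) {
    idx <- match(nt$area, unique(nt$area)) - 1
    nt$x_um <- nt$x_um + idx * 2000
  }

  # planted roles occupy the first rows of each area-agnostic pool in V1
  v1_pool <- which(nt$area == "V1")
  if (n_special > length(v1_pool))
    stop("planted classes exceed V1 population size")
  take <- function(k) {
    ids <- v1_pool[seq_len(k)]
    v1_pool <<- v1_pool[-seq_len(k)]
    ids
  }
  bar_ori <- c(IC1 = 135, IC2 = 45)
  for (cl in names(n_ic_encoders)) {
    k <- n_ic_encoders[[cl]]
    if (k == 0) next
    ids <- take(k)
    nt$emergent_class[ids] <- cl
    nt$emergent_amp[ids] <- emergent_amp
    # gap-confined receptive fields, as in the classical definition of
    # IC-responsive cells: tight sigma keeps bottom-up drive from the
    # inducers negligible so the planted selectivity is purely emergent
    nt$rf_x_deg[ids] <- stats::rnorm(k, 0, 1)
    nt$rf_y_deg[ids] <- stats::rnorm(k, 0, 1)
    nt$rf_sigma_deg[ids] <- 3
    nt$pref_ori_deg[ids] <- bar_ori[[cl]]
  }
  for (cl in names(n_lc_encoders)) {
    k <- n_lc_encoders[[cl]]
    if (k == 0) next
    ids <- take(k)
    nt$emergent_class[ids] <- cl
    nt$emergent_amp[ids] <- emergent_amp
    nt$rf_x_deg[ids] <- stats::rnorm(k, 0, 1)
    nt$rf_y_deg[ids] <- stats::rnorm(k, 0, 1)
    nt$rf_sigma_deg[ids] <- 3
  }
  # inward-bar centers and axis orientations per quadrant (cfg1 geometry)
  s2 <- sqrt(2) / 2
  seg_geom <- list(BR = c(16 * s2, -16 * s2, 135), TL = c(-16 * s2, 16 * s2, 135),
                   TR = c(16 * s2, 16 * s2, 45),   BL = c(-16 * s2, -16 * s2, 45))
  nt$segment_class <- "none"
  for (q in names(n_segment)) {
    k <- n_segment[[q]]
    if (k == 0) next
    ids <- take(k)
    nt$segment_class[ids] <- q
    nt$rf_x_deg[ids] <- seg_geom[[q]][1] + stats::rnorm(k, 0, 1.5)
    nt$rf_y_deg[ids] <- seg_geom[[q]][2] + stats::rnorm(k, 0, 1.5)
    nt$pref_ori_deg[ids] <- seg_geom[[q]][3]
  }
  class(nt) <- c("neuron_table", "data.frame")
  nt
}

#' Build a randomized trial table
#'
#' @param labels Character vector of stimulus labels, or a named integer
#'   vector of repeat counts per label.
#' @param n_reps Repeats per label when `labels` is unnamed.
#' @param seed Seed for the within-block order randomization.
#' @param block Block name (`visual`, `rf_mapping` or `holography`).
#' @param stim_s,iti_s Stimulus duration and inter-trial interval
#'   (seconds), used to lay out trial windows.
#' @return data.frame with `trial`, `stimulus`, `block`, `holo_ensemble`,
#'   `t_on`, `t_off`.
#' @export
make_trial_table <- function(labels, n_reps = 100, seed = 1,
                             block = "visual", stim_s = 1, iti_s = 0) {
  if (is.null(names(labels))) {
    reps <- stats::setNames(rep(n_reps, length(labels)), labels)
  } else reps <- labels
  stim <- rep(names(reps), reps)
  set.seed(child_seed(seed, 2))
  stim <- sample(stim)
  n <- length(stim)
  t_on <- (seq_len(n) - 1) * (stim_s + iti_s)
  data.frame(trial = seq_len(n), stimulus = stim, block = block,
             holo_ensemble = NA_character_,
             t_on = t_on, t_off = t_on + stim_s,
             stringsAsFactors = FALSE)
}

## ---- bottom-up drive --------------------------------------------------

# Orientation (clockwise from vertical, [0,180)) and energy of the
# luminance gradient at every pixel, plus a 15-degree orientation bin
# index.  Image rows run top to bottom (y decreasing).
stim_gradients <- function(pixels) {
  ny <- nrow(pixels); nx <- ncol(pixels)
  gx <- matrix(0, ny, nx); gy <- matrix(0, ny, nx)
  gx[, 2:(nx - 1)] <- (pixels[, 3:nx] - pixels[, 1:(nx - 2)]) / 2
  gy[2:(ny - 1), ] <- (pixels[1:(ny - 2), ] - pixels[3:ny, ]) / 2
  energy <- gx^2 + gy^2
  theta <- (atan2(-gy, gx) * 180 / pi) %% 180
  bin <- (floor((theta + 7.5) / 15) %% 12) + 1L
  list(energy = energy, bin = bin)
}

ORI_BIN_CENTERS <- seq(0, 165, by = 15)

# Per-neuron, per-image bottom-up factors.  Restricted to a +/-3.5 sigma
# window around the RF center for speed; neurons whose window misses the
# canvas get B = 0 with a warning.
bottomup_drive <- function(neurons, images, grid) {
  n <- nrow(neurons)
  labs <- names(images)
  B <- matrix(0, n, length(labs), dimnames = list(NULL, labs))
  O <- matrix(1, n, length(labs), dimnames = list(NULL, labs))
  if (all(neurons$gain == 0)) return(list(B = B, O = O))
  grads <- lapply(images, function(im) stim_gradients(im$pixels))
  dev <- lapply(images, function(im) abs(im$pixels - 0.5))
  for (i in seq_len(n)) {
    if (neurons$gain[i] == 0) next
    cx <- neurons$rf_x_deg[i]; cy <- neurons$rf_y_deg[i]
    sg <- neurons$rf_sigma_deg[i]
    jx <- which(abs(grid$x - cx) <= 3.5 * sg)
    iy <- which(abs(grid$y - cy) <= 3.5 * sg)
    if (!length(jx) || !length(iy)) {
      warning(sprintf("neuron %d: receptive field outside canvas; B = 0",
                      neurons$id[i]))
      next
    }
    wx <- stats::dnorm(grid$x[jx], cx, sg)
    wy <- stats::dnorm(grid$y[iy], cy, sg)
    W <- outer(wy, wx)
    W <- W / sum(W)
    kap <- neurons$tuning_kappa[i]
    pref <- neurons$pref_ori_deg[i]
    for (k in seq_along(labs)) {
      B[i, k] <- sum(W * dev[[k]][iy, jx, drop = FALSE])
      we <- W * grads[[k]]$energy[iy, jx, drop = FALSE]
      tot <- sum(we)
      if (tot > 1e-12) {
        eb <- rowsum(as.vector(we), as.vector(grads[[k]]$bin[iy, jx, drop = FALSE]))
        dom <- ORI_BIN_CENTERS[as.integer(rownames(eb))[which.max(eb)]]
        O[i, k] <- exp(kap * (cos(2 * (dom - pref) * pi / 180) - 1))
      }
    }
  }
  list(B = B, O = O)
}

# Stimuli that carry each planted emergent feature.  For IC classes the
# real-edge probes (T_RE, X_RE, matching-orientation I_RE) drive the
# emergent response too when `drives_real_edges` is on -- the generative
# hypothesis under which inference decoding is positive; with the switch
# off the emergent response is specific to the illusory image, giving the
# null in which probes carry no emergent signal.
emergent_targets <- function(class, drives_real_edges = TRUE) {
  base <- switch(class,
                 IC1 = "I_C1", IC2 = "I_C2", LC1 = "L_C1", LC2 = "L_C2",
                 character(0))
  if (drives_real_edges && class == "IC1")
    base <- c(base, "T_RE1", "X_RE1", "I_RE_135")
  if (drives_real_edges && class == "IC2")
    base <- c(base, "T_RE2", "X_RE2", "I_RE_45")
  base
}

#' Simulate trial-aligned population responses
#'
#' Draws one response per neuron per trial from the generative model (see
#' the package vignette).  Deterministic given `seed`.
#'
#' @param neurons A [make_neurons()] table.
#' @param stim_set A [render_battery()] stimulus set.  Receptive-field
#'   mapping labels (`rf_pos_1` ... `rf_pos_9`) referenced by the trial
#'   table are rasterized on demand.
#' @param trial_table A [make_trial_table()] table; every `stimulus` must
#'   be a battery label or an rf-mapping label.
#' @param seed Integer seed.
#' @param emergent_drives_real_edges Should planted IC-encoders respond
#'   to the real-edge probe images (`TRUE`, the inference-positive
#'   generative hypothesis) or only to their illusory image (`FALSE`)?
#' @param gain_noise_sd Trial-to-trial multiplicative response-gain
#'   variability shared across the population (the evoked part of every
#'   neuron's response is scaled by `1 + eta`, `eta ~ N(0,
#'   gain_noise_sd^2)` per trial) -- the shared gain fluctuation that
#'   dominates cortical trial-to-trial covariability.
#' @return Object of class `ic_session`: list with `trials`, `responses`
#'   (trials x neurons), `neurons`, `drives` (deterministic mean response
#'   per label x neuron) and `seed`.
#' @export
simulate_population <- function(neurons, stim_set, trial_table, seed = 1,
                                emergent_drives_real_edges = TRUE,
                                gain_noise_sd = 0.3) {
  labs <- unique(trial_table$stimulus)
  images <- stim_set$images[intersect(labs, names(stim_set$images))]
  rf_labs <- grep("^rf_pos_", labs, value = TRUE)
  if (length(rf_labs)) {
    patches <- rf_patch_images(stim_set$spec, stim_set$grid)
    images <- c(images, patches[rf_labs])
  }
  missing <- setdiff(labs, names(images))
  if (length(missing))
    stop("unknown stimulus labels: ", paste(missing, collapse = ", "))

  bu <- bottomup_drive(neurons, images, stim_set$grid)
  n <- nrow(neurons)
  mu <- matrix(neurons$baseline, length(labs), n, byrow = TRUE,
               dimnames = list(labs, neurons$id))
  mu <- mu + t(neurons$gain * (bu$B[, labs, drop = FALSE] *
                                 bu$O[, labs, drop = FALSE]))
  # emergent term
  for (i in which(neurons$emergent_class != "none")) {
    tg <- intersect(emergent_targets(neurons$emergent_class[i],
                                     emergent_drives_real_edges), labs)
    mu[tg, i] <- mu[tg, i] + neurons$emergent_amp[i]
  }
  set.seed(child_seed(seed, 3))
  n_tr <- nrow(trial_table)
  eps <- matrix(stats::rnorm(n_tr * n), n_tr, n)
  eps <- eps * rep(neurons$noise_sd, each = n_tr)
  evoked <- mu[trial_table$stimulus, , drop = FALSE] -
    matrix(neurons$baseline, n_tr, n, byrow = TRUE)
  gam <- 1 + stats::rnorm(n_tr, 0, gain_noise_sd)
  responses <- matrix(neurons$baseline, n_tr, n, byrow = TRUE) +
    gam * evoked + eps
  rownames(responses) <- trial_table$trial
  structure(list(trials = trial_table, responses = responses,
                 neurons = neurons, drives = mu, seed = seed),
            class = "ic_session")
}

#' @export
print.ic_session <- function(x, ...) {
  cat("Synthetic session:", nrow(x$responses), "trials x",
      ncol(x$responses), "neurons;",
      length(unique(x$trials$stimulus)), "stimulus conditions\n")
  invisible(x)
}

## ---- connectivity and holography --------------------------------------

# Neurons visually responsive to a stimulus: deterministic drive exceeds
# the blank-circles drive by more than `thresh` response units.
responsive_to <- function(session, label, thresh = 0.5,
                          blank = "blank_circles") {
  dr <- session$drives
  base <- if (blank %in% rownames(dr)) dr[blank, ] else session$neurons$baseline
  dr[label, ] - base > thresh
}

#' Build planted connectivity for holography simulations
#'
#' Embodies the circuit hypothesis under study: IC-encoders broadcast
#' like-to-like recurrent drive to local V1 neurons responsive to their
#' illusory image, and segment responders project feedforward to
#' higher-visual-area neurons responsive to the illusory image containing
#' their quadrant.  Weights are scaled so the aggregate drive a recipient
#' receives when a full ensemble is photoactivated equals
#' `recurrent_gain * direct_drive` (resp. `ff_gain * direct_drive`).
#'
#' @param session An [simulate_population()] session (supplies the
#'   deterministic drives used to define visual responsiveness).
#' @param like_to_like Enable recurrent IC-encoder output weights.
#' @param feedforward Enable segment-responder to higher-area weights.
#' @param recurrent_gain,ff_gain Aggregate drive per unit direct drive.
#' @param suppression Global suppression `s` (response units) applied to
#'   every neuron on holography trials (the prolonged suppression of the
#'   non-photoactivated population).
#' @param resp_thresh Responsiveness threshold (response units above
#'   blank).
#' @return Object of class `connectivity`: `W` (neurons x neurons,
#'   zero diagonal), `FF`, `FB` and `s`.
#' @export
make_connectivity <- function(session, like_to_like = TRUE,
                              feedforward = FALSE,
                              recurrent_gain = 0.4, ff_gain = 0.4,
                              suppression = 0.5, resp_thresh = 0.5) {
  nt <- session$neurons
  n <- nrow(nt)
  W <- matrix(0, n, n)
  FF <- matrix(0, n, n)
  FB <- matrix(0, n, n)
  ic_of <- c(IC1 = "I_C1", IC2 = "I_C2")
  seg_of <- c(BR = "I_C1", TL = "I_C1", BL = "I_C2", TR = "I_C2")
  if (like_to_like) {
    for (cl in names(ic_of)) {
      src <- which(nt$emergent_class == cl & nt$area == "V1")
      if (!length(src)) next
      if (!ic_of[[cl]] %in% rownames(session$drives)) next
      tgt <- which(responsive_to(session, ic_of[[cl]], resp_thresh) &
                     nt$area == "V1")
      W[src, tgt] <- recurrent_gain / length(src)
    }
  }
  if (feedforward) {
    for (q in names(seg_of)) {
      src <- which(nt$segment_class == q & nt$area == "V1")
      if (!length(src)) next
      if (!seg_of[[q]] %in% rownames(session$drives)) next
      tgt <- which(responsive_to(session, seg_of[[q]], resp_thresh) &
                     nt$area != "V1")
      FF[src, tgt] <- ff_gain / length(src)
    }
  }
  diag(W) <- 0; diag(FF) <- 0; diag(FB) <- 0
  structure(list(W = W, FF = FF, FB = FB, s = suppression),
            class = "connectivity")
}

#' Holography stimulation plan
#'
#' @param ensembles Named list of target neuron ids (e.g. every planted
#'   I_C1-encoder).
#' @param n_reps Photostimulation repeats per ensemble.
#' @param direct_drive Direct photoactivation drive `d` (response units)
#'   delivered to each target.
#' @param pulses,pulse_hz,pulse_ms Pulse-train metadata (10 pulses at
#'   10 Hz, 10 ms width by default).
#' @return Object of class `holography_plan`.
#' @export
holography_plan <- function(ensembles, n_reps = 50, direct_drive = 5,
                            pulses = 10, pulse_hz = 10, pulse_ms = 10) {
  stopifnot(is.list(ensembles), !is.null(names(ensembles)))
  structure(list(ensembles = ensembles, n_reps = n_reps,
                 direct_drive = direct_drive,
                 pulses = pulses, pulse_hz = pulse_hz, pulse_ms = pulse_ms),
            class = "holography_plan")
}

#' Simulate holography-evoked responses
#'
#' On each trial the targeted ensemble receives the direct drive; every
#' neuron additionally receives the connectivity-routed drive from the
#' targets, minus the global suppression, plus trial noise.  A coarse
#' time course (0.5-s bins from -2 to 3 s relative to holography onset)
#' is returned alongside the scalar 0-1 s response for the
#' baseline-subtraction analysis.
#'
#' @param session The visual session whose neurons are being targeted.
#' @param connectivity A [make_connectivity()] object.
#' @param plan A [holography_plan()].
#' @param seed Integer seed.
#' @param noise_sd Trial noise of the holography responses.
#' @param timecourse Return the per-trial time course array?
#' @return Object of class `holo_session`: `trials` (trial, ensemble),
#'   `responses` (trials x neurons, 0-1 s window), optional `timecourse`
#'   (trials x neurons x bins) with `bin_times`, and `plan`.
#' @export
simulate_holography <- function(session, connectivity, plan, seed = 1,
                                noise_sd = 1, timecourse = FALSE) {
  nt <- session$neurons
  n <- nrow(nt)
  bad <- setdiff(unlist(plan$ensembles), nt$id)
  if (length(bad))
    stop("holography plan references unknown neuron ids: ",
         paste(bad, collapse = ", "))
  ens_names <- rep(names(plan$ensembles), each = plan$n_reps)
  set.seed(child_seed(seed, 4))
  ens_names <- sample(ens_names)
  n_tr <- length(ens_names)

  drive <- matrix(0, n_tr, n)
  M <- connectivity$W + connectivity$FF + connectivity$FB
  for (e in names(plan$ensembles)) {
    rows <- which(ens_names == e)
    tgt <- match(plan$ensembles[[e]], nt$id)
    dvec <- -rep(connectivity$s, n)
    dvec <- dvec + plan$direct_drive * colSums(M[tgt, , drop = FALSE])
    dvec[tgt] <- dvec[tgt] + plan$direct_drive
    drive[rows, ] <- matrix(dvec, length(rows), n, byrow = TRUE)
  }
  responses <- drive + matrix(stats::rnorm(n_tr * n, 0, noise_sd), n_tr, n)
  colnames(responses) <- nt$id
  trials <- data.frame(trial = seq_len(n_tr), ensemble = ens_names,
                       stringsAsFactors = FALSE)
  out <- list(trials = trials, responses = responses, plan = plan,
              seed = seed)
  if (timecourse) {
    bin_times <- seq(-2, 2.5, by = 0.5)  # left edges of 0.5-s bins
    nb <- length(bin_times)
    tc <- array(stats::rnorm(n_tr * n * nb, 0, noise_sd),
                dim = c(n_tr, n, nb))
    stim_bins <- which(bin_times >= 0 & bin_times < 1)
    post_bins <- which(bin_times >= 1)
    for (b in stim_bins) tc[, , b] <- tc[, , b] + drive
    for (b in post_bins) tc[, , b] <- tc[, , b] - connectivity$s
    out$timecourse <- tc
    out$bin_times <- bin_times
  }
  structure(out, class = "holo_session")
}

## ---- spike trains ------------------------------------------------------

#' Simulate millisecond-resolution spike trains with planted synapses
#'
#' Each unit fires as a (possibly rate-comodulated) Poisson process; for
#' every planted connection, each presynaptic spike independently inserts
#' a postsynaptic spike at `lag_ms` plus a +/-1 ms jitter with probability
#' `transfer_p`.  Slow shared rate modulation (sinusoidal, timescale >=
#' 100 ms) exercises the smoothing correction of the cross-correlogram
#' analysis.
#'
#' @param base_rates_hz Numeric vector of baseline rates, one per unit.
#' @param connections data.frame with `pre`, `post`, `lag_ms`,
#'   `transfer_p` (may be empty / NULL).
#' @param duration_s Recording duration in seconds.
#' @param comodulation NULL, or `list(freq_hz=, depth=)` applied to all
#'   units (depth in `[0,1]`; rate(t) = base * (1 + depth * sin)).
#' @param seed Integer seed.
#' @return Object of class `spike_train_set`: list `times` (seconds, one
#'   sorted vector per unit), `duration_s`, `bin_ms = 1`.
#' @export
simulate_spike_trains <- function(base_rates_hz, connections = NULL,
                                  duration_s, comodulation = NULL,
                                  seed = 1) {
  set.seed(child_seed(seed, 5))
  n <- length(base_rates_hz)
  times <- vector("list", n)
  for (u in seq_len(n)) {
    rate <- base_rates_hz[u]
    if (rate <= 0) { times[[u]] <- numeric(0); next }
    if (is.null(comodulation)) {
      k <- stats::rpois(1, rate * duration_s)
      tt <- sort(stats::runif(k, 0, duration_s))
    } else {
      peak <- rate * (1 + abs(comodulation$depth))
      k <- stats::rpois(1, peak * duration_s)
      tt <- sort(stats::runif(k, 0, duration_s))
      lam <- rate * (1 + comodulation$depth *
                       sin(2 * pi * comodulation$freq_hz * tt))
      tt <- tt[stats::runif(k) < lam / peak]
    }
    times[[u]] <- tt
  }
  if (!is.null(connections) && nrow(connections)) {
    for (r in seq_len(nrow(connections))) {
      pre <- connections$pre[r]; post <- connections$post[r]
      lag <- connections$lag_ms[r]
      if (lag <= 0 || lag > 10)
        warning("connection lag outside (0, 10] ms is undetectable by the 1-10 ms peak window")
      src <- times[[pre]]
      hit <- src[stats::runif(length(src)) < connections$transfer_p[r]]
      jit <- sample(c(-1, 0, 1), length(hit), replace = TRUE)
      ins <- hit + (lag + jit) / 1000
      ins <- ins[ins >= 0 & ins < duration_s]
      times[[post]] <- sort(c(times[[post]], ins))
    }
  }
  structure(list(times = times, duration_s = duration_s, bin_ms = 1),
            class = "spike_train_set")
}

# 1-ms binned spike counts (vector of length duration_s*1000)
bin_spike_times <- function(times_s, duration_s, bin_ms = 1) {
  L <- round(duration_s * 1000 / bin_ms)
  idx <- floor(times_s * 1000 / bin_ms) + 1L
  idx <- idx[idx >= 1 & idx <= L]
  tabulate(idx, nbins = L)
}

## ---- pupil -------------------------------------------------------------

#' Simulate a pupil-position trace
#'
#' Per-frame 2D pupil position with its mode at the origin, plus
#' configurable large excursions on selected trials (to exercise the
#' fixed-gaze trial filter).
#'
#' @param trial_table Trial table supplying `t_on`/`t_off` windows.
#' @param excursion NULL, or `list(trials=, amp_deg=)`: trial indices
#'   that receive an excursion of `amp_deg` degrees for their whole
#'   duration.
#' @param seed Integer seed.
#' @param frame_hz Sampling rate.
#' @param jitter_sd Small fixational jitter (degrees).
#' @return data.frame `time_s`, `x_deg`, `y_deg`.
#' @export
simulate_pupil <- function(trial_table, excursion = NULL, seed = 1,
                           frame_hz = 30, jitter_sd = 0.3) {
  set.seed(child_seed(seed, 6))
  t_end <- max(trial_table$t_off)
  tm <- seq(0, t_end, by = 1 / frame_hz)
  x <- stats::rnorm(length(tm), 0, jitter_sd)
  y <- stats::rnorm(length(tm), 0, jitter_sd)
  if (!is.null(excursion)) {
    for (tr in excursion$trials) {
      sel <- tm >= trial_table$t_on[tr] & tm < trial_table$t_off[tr]
      th <- stats::runif(1, 0, 2 * pi)
      x[sel] <- x[sel] + excursion$amp_deg * cos(th)
      y[sel] <- y[sel] + excursion$amp_deg * sin(th)
    }
  }
  data.frame(time_s = tm, x_deg = x, y_deg = y)
}
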