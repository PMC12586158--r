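# Pipeline orchestration: configuration, the end-to-end run
# (simulate -> preprocess -> classify -> decode -> holography -> CCG),
# small reproducible fixtures for the test suite, and plain-text session
# I/O.

#' Default pipeline configuration
#'
#' A run is a pure function of `(config, seed)`.  The defaults are the
#' package's study conditions: a 200-neuron population with planted
#' IC-encoders (emergent amplitude 3x the trial noise s.d.) and segment
#' responders, 400 repeats of each training image, 100 repeats of each
#' real-edge probe, 10-fold decoding with C = 1, and the standard
#' holography and CCG constants.
#'
#' @param ... Named overrides of any default entry.
#' @return A list of class `run_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    stimulus = list(),                     # stimulus_spec() overrides
    n_neurons = 200,
    n_ic_encoders = c(IC1 = 10, IC2 = 10),
    n_lc_encoders = c(LC1 = 0, LC2 = 0),
    n_segment = c(BR = 12, BL = 12, TL = 12, TR = 12),
    area_counts = NULL,                    # NULL = all V1
    emergent_amp = 3, gain = 2, noise_sd = 1, gain_noise_sd = 0.3,
    emergent_drives_real_edges = TRUE,
    n_train_reps = 400, n_probe_reps = 100, n_blank_reps = 50,
    alpha = 0.05, k_folds = 10, svm_cost = 1,
    holo = list(enable = FALSE, n_reps = 50, direct_drive = 5,
                recurrent_gain = 0.4, ff_gain = 0.4, suppression = 0.5,
                like_to_like = TRUE, feedforward = FALSE,
                min_dist_um = 50, min_targets = 10),
    ccg = list(enable = FALSE, rate_hz = 10, duration_s = 600,
               tau_max = 100, smooth_ms = 25, threshold_mult = 7)
  )
  ov <- list(...)
  for (nm in names(ov)) {
    cfg[[nm]] <- if (is.list(cfg[[nm]]) && is.list(ov[[nm]]))
      utils::modifyList(cfg[[nm]], ov[[nm]]) else ov[[nm]]
  }
  class(cfg) <- "run_config"
  cfg
}

#' Run the full analysis pipeline on a synthetic session
#'
#' Renders the stimulus battery, simulates a session under `config`,
#' classifies functional ensembles, trains the four-class decoder,
#' computes T_RE and X_RE inference scores with the zero-out and
#' subset-only controls, and (optionally) runs the holography
#' cross-decoding and a small CCG scan.  Deterministic given `(config,
#' seed)`; the returned summary carries a config hash.
#'
#' @param config A [default_config()].
#' @param seed Master integer seed; per-stage child seeds are derived
#'   from it.
#' @return List of class `pipeline_result` with elements `stimuli`,
#'   `session`, `labels`, `decoding`, `holography`, `ccg`, and a tidy
#'   `summary` data.frame (stage, metric, value).
#' @export
run_pipeline <- function(config = default_config(), seed = 1) {
  spec <- do.call(stimulus_spec, config$stimulus)
  sset <- render_battery(spec)
  area_counts <- config$area_counts %||% c(V1 = config$n_neurons)
  nt <- make_neurons(n = config$n_neurons, seed = child_seed(seed, 10),
                     n_ic_encoders = config$n_ic_encoders,
                     n_lc_encoders = config$n_lc_encoders,
                     n_segment = config$n_segment,
                     area_counts = area_counts,
                     emergent_amp = config$emergent_amp,
                     gain = config$gain, noise_sd = config$noise_sd)
  reps <- c(I_C1 = config$n_train_reps, L_C1 = config$n_train_reps,
            L_C2 = config$n_train_reps, I_C2 = config$n_train_reps,
            T_RE1 = config$n_probe_reps, T_RE2 = config$n_probe_reps,
            X_RE1 = config$n_probe_reps, X_RE2 = config$n_probe_reps,
            blank_circles = config$n_blank_reps)
  seg_labels <- paste0(rep(c("In_", "Out_"), each = 4),
                       c("BR", "BL", "TL", "TR"))
  reps <- c(reps, stats::setNames(rep(50, 8), seg_labels))
  tt <- make_trial_table(reps, seed = child_seed(seed, 11))
  ses <- simulate_population(nt, sset, tt, seed = child_seed(seed, 12),
                             emergent_drives_real_edges =
                               config$emergent_drives_real_edges,
                             gain_noise_sd = config$gain_noise_sd)
  X <- build_response_matrix(ses)
  y <- ses$trials$stimulus

  labels <- classify_session(ses, alpha = config$alpha)

  core <- y %in% c("I_C1", "L_C1", "L_C2", "I_C2")
  dec <- train_cv_decoder(X[core, , drop = FALSE], y[core],
                          k = config$k_folds,
                          seed = child_seed(seed, 13),
                          cost = config$svm_cost)
  tre1 <- X[y == "T_RE1", , drop = FALSE]
  tre2 <- X[y == "T_RE2", , drop = FALSE]
  tre <- tre_inference(dec, tre1, tre2)

  ic_idx <- which(labels$ic_class != "none")
  seg_idx <- which(!is.na(labels$segment_class) &
                     labels$segment_class != "none")
  decoding <- list(decoder = dec, tre = tre)
  if (length(ic_idx)) {
    decoding$tre_zero_ic <- tre_inference(dec, tre1, tre2,
                                          zero_idx = ic_idx)
    decoding$cv_zero_ic <- zero_out(dec, X[core, , drop = FALSE],
                                    y[core], ic_idx)
    if (length(ic_idx) >= config$k_folds) {
      dic <- train_subset(X[core, , drop = FALSE], y[core], ic_idx,
                          k = config$k_folds,
                          seed = child_seed(seed, 14),
                          cost = config$svm_cost)
      decoding$subset_ic <- list(
        decoder = dic,
        tre = tre_inference(dic, tre1[, ic_idx, drop = FALSE],
                            tre2[, ic_idx, drop = FALSE]))
    }
  }
  if (length(seg_idx) >= config$k_folds) {
    dseg <- train_subset(X[core, , drop = FALSE], y[core], seg_idx,
                         k = config$k_folds,
                         seed = child_seed(seed, 15),
                         cost = config$svm_cost)
    decoding$subset_seg <- list(
      decoder = dseg,
      tre = tre_inference(dseg, tre1[, seg_idx, drop = FALSE],
                          tre2[, seg_idx, drop = FALSE]))
  }
  xsel <- y %in% c("X_RE1", "X_RE2")
  dx <- train_cv_decoder(X[xsel, , drop = FALSE], y[xsel],
                         k = config$k_folds,
                         seed = child_seed(seed, 16),
                         cost = config$svm_cost)
  decoding$xre_decoder <- dx
  decoding$xre <- xre_inference(dx, X[y == "I_C1", , drop = FALSE],
                                X[y == "I_C2", , drop = FALSE])

  holography <- NULL
  if (isTRUE(config$holo$enable)) {
    ens <- list(
      IC1_encoders = nt$id[nt$emergent_class == "IC1"],
      IC2_encoders = nt$id[nt$emergent_class == "IC2"],
      seg_BR_TL = nt$id[nt$segment_class %in% c("BR", "TL")],
      seg_BL_TR = nt$id[nt$segment_class %in% c("BL", "TR")])
    ens <- ens[lengths(ens) > 0]
    plan <- holography_plan(ens, n_reps = config$holo$n_reps,
                            direct_drive = config$holo$direct_drive)
    conn <- make_connectivity(ses,
                              like_to_like = config$holo$like_to_like,
                              feedforward = config$holo$feedforward,
                              recurrent_gain = config$holo$recurrent_gain,
                              ff_gain = config$holo$ff_gain,
                              suppression = config$holo$suppression)
    holo <- simulate_holography(ses, conn, plan,
                                seed = child_seed(seed, 17))
    expected <- c(IC1_encoders = "I_C1", IC2_encoders = "I_C2",
                  seg_BR_TL = "I_C1", seg_BL_TR = "I_C2")[names(ens)]
    sizes <- lengths(ens)
    all_frac <- holo_cross_decode(dec, holo$responses, holo$trials,
                                  expected, ensemble_sizes = sizes,
                                  min_targets = config$holo$min_targets)
    nontarget <- lapply(names(ens), function(e) {
      np <- nonphoto_mask(nt, ens[[e]], config$holo$min_dist_um) &
        nt$area == "V1"
      dnp <- train_cv_decoder(X[core, np, drop = FALSE], y[core],
                              k = config$k_folds,
                              seed = child_seed(seed, 18),
                              cost = config$svm_cost)
      holo_cross_decode(dnp, holo$responses[, np, drop = FALSE],
                        holo$trials, expected[e],
                        ensemble_sizes = sizes,
                        min_targets = config$holo$min_targets)
    })
    holography <- list(session = holo, plan = plan,
                       all_neurons = all_frac,
                       nontarget = do.call(rbind, nontarget))
  }

  ccg_res <- NULL
  if (isTRUE(config$ccg$enable)) {
    st <- simulate_spike_trains(
      rep(config$ccg$rate_hz, 4),
      data.frame(pre = 1, post = 2, lag_ms = 3, transfer_p = 0.2),
      duration_s = config$ccg$duration_s,
      seed = child_seed(seed, 19))
    ccg_res <- ccg_scan(st, pairs = cbind(c(1, 3), c(2, 4)),
                        tau_max = config$ccg$tau_max,
                        smooth_ms = config$ccg$smooth_ms,
                        threshold_mult = config$ccg$threshold_mult)
  }

  sm <- data.frame(stage = "decode",
                   metric = c("cv_accuracy", "tre_score", "xre_score"),
                   value = c(dec$cv_accuracy, tre$score,
                             decoding$xre$score))
  if (!is.null(decoding$tre_zero_ic))
    sm <- rbind(sm, data.frame(stage = "decode",
                               metric = "tre_score_zero_ic",
                               value = decoding$tre_zero_ic$score))
  if (!is.null(decoding$subset_seg))
    sm <- rbind(sm, data.frame(stage = "decode",
                               metric = "tre_score_seg_only",
                               value = decoding$subset_seg$tre$score))
  sm <- rbind(sm, data.frame(
    stage = "classify",
    metric = c("n_ic_encoders", "n_segment_responders"),
    value = c(sum(labels$ic_class != "none"),
              sum(!is.na(labels$segment_class) &
                    labels$segment_class != "none"))))
  if (!is.null(holography))
    sm <- rbind(sm, data.frame(
      stage = "holography",
      metric = paste0("nontarget_frac_", holography$nontarget$ensemble),
      value = holography$nontarget$expected_fraction))
  sm$config_hash <- config_hash(list(config = unclass(config),
                                     seed = seed))
  sm$seed <- seed

  structure(list(stimuli = sset, session = ses, labels = labels,
                 decoding = decoding, holography = holography,
                 ccg = ccg_res, summary = sm, config = config,
                 seed = seed),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Pipeline run (seed", x$seed, ")\n")
  print(x$summary[, c("stage", "metric", "value")], row.names = FALSE)
  invisible(x)
}

#' Small deterministic fixtures for tests and examples
#'
#' Builds a reduced null session (no emergent signal, gain 0), a reduced
#' planted session, a holography session with like-to-like recurrence,
#' and a short spike-train set with one planted synapse.  Everything is
#' generated in code; nothing is read from disk.
#'
#' @param seed Master seed.
#' @return Named list `stimuli`, `null_session`, `planted_session`,
#'   `holo`, `spikes`.
#' @export
make_fixtures <- function(seed = 1) {
  spec <- stimulus_spec()
  sset <- render_battery(spec)
  labs <- c(I_C1 = 30, L_C1 = 30, L_C2 = 30, I_C2 = 30,
            T_RE1 = 20, T_RE2 = 20, blank_circles = 20)
  nt0 <- make_neurons(n = 40, seed = child_seed(seed, 20), gain = 0,
                      n_ic_encoders = c(IC1 = 0, IC2 = 0),
                      n_segment = c(BR = 0, BL = 0, TL = 0, TR = 0))
  tt <- make_trial_table(labs, seed = child_seed(seed, 21))
  null_ses <- simulate_population(nt0, sset, tt,
                                  seed = child_seed(seed, 22))
  nt1 <- make_neurons(n = 60, seed = child_seed(seed, 23),
                      n_ic_encoders = c(IC1 = 5, IC2 = 5),
                      n_segment = c(BR = 5, BL = 5, TL = 5, TR = 5))
  planted <- simulate_population(nt1, sset, tt,
                                 seed = child_seed(seed, 24))
  ens <- list(IC1_encoders = nt1$id[nt1$emergent_class == "IC1"],
              IC2_encoders = nt1$id[nt1$emergent_class == "IC2"])
  conn <- make_connectivity(planted, like_to_like = TRUE)
  holo <- simulate_holography(planted, conn,
                              holography_plan(ens, n_reps = 20),
                              seed = child_seed(seed, 25),
                              timecourse = TRUE)
  spikes <- simulate_spike_trains(
    c(10, 10, 10, 10),
    data.frame(pre = 1, post = 2, lag_ms = 3, transfer_p = 0.3),
    duration_s = 300, seed = child_seed(seed, 26))
  list(stimuli = sset, null_session = null_ses,
       planted_session = planted, holo = holo, spikes = spikes)
}

## ---- plain-text session I/O -------------------------------------------

#' Write a session to a directory of plain-text files
#'
#' Layout: `trials.csv`, `responses.csv` (trials x neurons),
#' `neurons.csv`, `header.json` (seed and dimensions), plus optional
#' `spikes.csv` (unit, time_s) and `pupil.csv`.
#'
#' @param session An `ic_session`.
#' @param dir Output directory.
#' @param spikes Optional `spike_train_set`.
#' @param pupil Optional pupil data.frame.
#' @return Invisibly, `dir`.
#' @export
write_session <- function(session, dir, spikes = NULL, pupil = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(session$trials, file.path(dir, "trials.csv"),
                   row.names = FALSE)
  utils::write.csv(session$responses, file.path(dir, "responses.csv"),
                   row.names = FALSE)
  utils::write.csv(session$neurons, file.path(dir, "neurons.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(seed = session$seed,
                            n_trials = nrow(session$responses),
                            n_neurons = ncol(session$responses)),
                       file.path(dir, "header.json"), auto_unbox = TRUE)
  if (!is.null(spikes)) {
    df <- data.frame(
      unit = rep(seq_along(spikes$times), lengths(spikes$times)),
      time_s = unlist(spikes$times))
    utils::write.csv(df, file.path(dir, "spikes.csv"), row.names = FALSE)
    jsonlite::write_json(list(duration_s = spikes$duration_s),
                         file.path(dir, "spikes.json"), auto_unbox = TRUE)
  }
  if (!is.null(pupil))
    utils::write.csv(pupil, file.path(dir, "pupil.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a session written by [write_session()]
#'
#' @param dir Directory containing the session files.
#' @return An `ic_session` (with `drives` absent; spikes/pupil attached
#'   as `spikes` / `pupil` when present).
#' @export
read_session <- function(dir) {
  trials <- utils::read.csv(file.path(dir, "trials.csv"),
                            stringsAsFactors = FALSE)
  responses <- as.matrix(utils::read.csv(file.path(dir, "responses.csv")))
  neurons <- utils::read.csv(file.path(dir, "neurons.csv"),
                             stringsAsFactors = FALSE)
  hdr <- jsonlite::read_json(file.path(dir, "header.json"),
                             simplifyVector = TRUE)
  ses <- structure(list(trials = trials, responses = responses,
                        neurons = neurons, drives = NULL,
                        seed = hdr$seed),
                   class = "ic_session")
  sp <- file.path(dir, "spikes.csv")
  if (file.exists(sp)) {
    df <- utils::read.csv(sp)
    meta <- jsonlite::read_json(file.path(dir, "spikes.json"),
                                simplifyVector = TRUE)
    ses$spikes <- structure(
      list(times = split(df$time_s, df$unit),
           duration_s = meta$duration_s, bin_ms = 1),
      class = "spike_train_set")
  }
  pp <- file.path(dir, "pupil.csv")
  if (file.exists(pp)) ses$pupil <- utils::read.csv(pp)
  ses
}
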