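# Cross-validated decoding, inference probes, subset manipulations and
# holography cross-decoding.

test_that("folds are stratified, disjoint and cover every trial", {
  ses <- fx$null_session
  y <- ses$trials$stimulus
  core <- y %in% c("I_C1", "L_C1", "L_C2", "I_C2")
  dec <- train_cv_decoder(ses$responses[core, ], y[core], seed = 2)
  test_sets <- lapply(dec$folds, `[[`, "test_idx")
  expect_equal(sort(unlist(test_sets)), seq_len(sum(core)))
  expect_equal(sum(duplicated(unlist(test_sets))), 0)
  for (f in dec$folds)
    expect_length(intersect(f$train_idx, f$test_idx), 0)
  # standardization comes from training trials only
  f1 <- dec$folds[[1]]
  expect_equal(f1$mu,
               colMeans(ses$responses[core, ][f1$train_idx, ]))
  expect_error(train_cv_decoder(ses$responses[1:30, ], y[1:30], k = 10),
               "at least k")
})

test_that("noiseless orthogonal class patterns decode perfectly", {
  set.seed(3)
  n_per <- 12
  pats <- diag(4) * 5
  X <- pats[rep(1:4, each = n_per), ]
  X <- X + matrix(rnorm(length(X), 0, 1e-3), nrow(X))
  y <- rep(c("I_C1", "L_C1", "L_C2", "I_C2"), each = n_per)
  dec <- train_cv_decoder(X, y, k = 4, seed = 3)
  expect_equal(dec$cv_accuracy, 1)
  expect_equal(unname(diag(dec$confusion)), rep(1, 4))
})

test_that("cv accuracy tracks a nearest-centroid oracle on gaussian classes", {
  for (s in 4:5) {
    set.seed(s)
    n_per <- 100; p <- 8
    mus <- matrix(rnorm(4 * p, 0, 0.5), 4, p)
    X <- mus[rep(1:4, each = n_per), ] +
      matrix(rnorm(4 * n_per * p), 4 * n_per, p)
    y <- rep(c("a", "b", "c", "d"), each = n_per)
    dec <- train_cv_decoder(X, y, seed = s)
    oracle <- centroid_cv_accuracy(X, y, seed = s)
    expect_lt(abs(dec$cv_accuracy - oracle), 0.05)
  }
})

test_that("probe fractions are proper distributions that sharpen with SNR", {
  ses <- fx$planted_session
  y <- ses$trials$stimulus
  core <- y %in% c("I_C1", "L_C1", "L_C2", "I_C2")
  dec <- train_cv_decoder(ses$responses[core, ], y[core], seed = 5)
  fr <- probe(dec, ses$responses[y == "T_RE1", ])
  expect_equal(sum(fr), 1, tolerance = 1e-12)
  expect_true(all(fr >= 0))
  expect_equal(rowSums(dec$confusion), rep(1, 4), ignore_attr = TRUE)
  # probing with a class's own noiseless mean pattern recovers the class
  mu_ic1 <- ses$drives["I_C1", , drop = FALSE]
  fr2 <- probe(dec, mu_ic1[rep(1, 20), , drop = FALSE])
  expect_gt(fr2["I_C1"], 0.95)
  expect_error(probe(dec, ses$responses[1:5, 1:3]), "neurons")
})

test_that("decoding metrics are invariant to a consistent neuron permutation", {
  ses <- fx$planted_session
  y <- ses$trials$stimulus
  core <- y %in% c("I_C1", "L_C1", "L_C2", "I_C2")
  X <- ses$responses
  set.seed(6)
  pm <- sample(ncol(X))
  d1 <- train_cv_decoder(X[core, ], y[core], seed = 6)
  d2 <- train_cv_decoder(X[core, pm], y[core], seed = 6)
  expect_equal(d1$cv_accuracy, d2$cv_accuracy)
  expect_equal(d1$confusion, d2$confusion)
  t1 <- tre_inference(d1, X[y == "T_RE1", ], X[y == "T_RE2", ])
  t2 <- tre_inference(d2, X[y == "T_RE1", pm], X[y == "T_RE2", pm])
  expect_equal(t1$score, t2$score)
})

test_that("linear SVM matches an exhaustively enumerated max-margin separator", {
  # separable 2-class 2-neuron toy: the decision boundary agrees with a
  # brute-force margin-maximizing separator on a probe grid
  set.seed(7)
  X <- rbind(matrix(rnorm(40, -2, 0.4), ncol = 2),
             matrix(rnorm(40, 2, 0.4), ncol = 2))
  y <- rep(c("X_RE1", "X_RE2"), each = 20)
  sep <- best_margin_separator(X, y)
  fit <- e1071::svm(X, factor(y), kernel = "linear", cost = 1e3,
                    scale = FALSE)
  grid <- as.matrix(expand.grid(seq(-3, 3, 0.5), seq(-3, 3, 0.5)))
  away <- abs(grid %*% sep$w - sep$cut) > 0.3  # off the knife edge
  p_or <- predict_margin_separator(sep, grid[away, ], levels(factor(y)))
  p_sv <- as.character(predict(fit, grid[away, ]))
  expect_equal(p_sv, p_or)
})

test_that("inference scores behave under planted, null and ablated populations", {
  ses <- fx$planted_session
  nt <- ses$neurons
  y <- ses$trials$stimulus
  X <- ses$responses
  core <- y %in% c("I_C1", "L_C1", "L_C2", "I_C2")
  dec <- train_cv_decoder(X[core, ], y[core], seed = 8)
  tre <- tre_inference(dec, X[y == "T_RE1", ], X[y == "T_RE2", ])
  expect_gt(tre$score, 0.3)
  expect_lte(tre$frac_ic + tre$frac_lc, 1 + 1e-12)
  # zeroing the planted encoders removes the positive inference signal
  ic_idx <- which(nt$emergent_class %in% c("IC1", "IC2"))
  tre0 <- tre_inference(dec, X[y == "T_RE1", ], X[y == "T_RE2", ],
                        zero_idx = ic_idx)
  expect_lt(tre0$score, 0.1)
  zo <- zero_out(dec, X[core, ], y[core], ic_idx)
  expect_gt(zo$cv_accuracy, 0.25)
  # empty subset leaves the decoder untouched
  z0 <- zero_out(dec, X[core, ], y[core], integer(0))
  expect_equal(z0$cv_accuracy, dec$cv_accuracy)
  expect_equal(z0$confusion, dec$confusion)
  # zeroing everything collapses to constant-class performance
  zall <- zero_out(dec, X[core, ], y[core], seq_len(ncol(X)))
  expect_lte(zall$cv_accuracy, 0.3)
  # training only on encoders keeps the inference signal
  dic <- train_subset(X[core, ], y[core], ic_idx, seed = 8)
  tic <- tre_inference(dic, X[y == "T_RE1", ic_idx],
                       X[y == "T_RE2", ic_idx])
  expect_gt(tic$score, 0.3)
  # subset = all equals the full decoder
  dall <- train_subset(X[core, ], y[core], seq_len(ncol(X)), seed = 8)
  expect_equal(dall$cv_accuracy, dec$cv_accuracy)
})

test_that("null populations probe at chance", {
  ses <- fx$null_session
  y <- ses$trials$stimulus
  X <- ses$responses
  core <- y %in% c("I_C1", "L_C1", "L_C2", "I_C2")
  dec <- train_cv_decoder(X[core, ], y[core], seed = 9)
  expect_lt(abs(dec$cv_accuracy - 0.25), 0.12)
  tre <- tre_inference(dec, X[y == "T_RE1", ], X[y == "T_RE2", ])
  expect_lt(abs(tre$score), 0.3)
})

test_that("holography masks and target validation follow the distance rules", {
  nt <- data.frame(id = 1:4, x_um = c(0, 30, 49, 200),
                   y_um = c(0, 0, 0, 0))
  m <- nonphoto_mask(nt, target_ids = 1, min_dist_um = 50)
  expect_equal(m, c(FALSE, FALSE, FALSE, TRUE))
  m25 <- nonphoto_mask(nt, target_ids = 1, min_dist_um = 25)
  expect_equal(m25, c(FALSE, TRUE, TRUE, TRUE))
  expect_error(nonphoto_mask(nt, 99), "unknown")
  v <- validate_targets(rbind(c(1, 0), c(60, 0)), nt, max_dist_um = 10)
  expect_equal(v$valid, c(TRUE, FALSE))
  expect_equal(v$neuron_id[1], 1)
  v2 <- validate_targets(rbind(c(0, 0), c(30, 0), c(200, 0)), nt)
  expect_true(all(v2$valid))
})

test_that("holography cross-decoding reads out planted pattern completion", {
  ses <- fx$planted_session
  nt <- ses$neurons
  y <- ses$trials$stimulus
  X <- ses$responses
  core <- y %in% c("I_C1", "L_C1", "L_C2", "I_C2")
  holo <- fx$holo
  expected <- c(IC1_encoders = "I_C1", IC2_encoders = "I_C2")
  sizes <- lengths(holo$plan$ensembles)
  dec <- train_cv_decoder(X[core, ], y[core], seed = 10)
  res <- holo_cross_decode(dec, holo$responses, holo$trials, expected,
                           ensemble_sizes = sizes, min_targets = 5)
  expect_true(all(res$expected_fraction > 0.5))
  fr <- attr(res, "fractions")
  expect_equal(rowSums(fr), rep(1, nrow(fr)), ignore_attr = TRUE)
  # the >= min_targets rule drops small ensembles
  res10 <- holo_cross_decode(dec, holo$responses, holo$trials, expected,
                             ensemble_sizes = sizes, min_targets = 10)
  expect_equal(nrow(res10), 0)
  expect_error(holo_cross_decode(dec, holo$responses[, 1:3], holo$trials,
                                 expected), "different neuron subsets")
  p <- holo_signed_rank(c(0.4, 0.5, 0.45, 0.6, 0.38, 0.52), chance = 0.25)
  expect_lt(p$p.value, 0.05)
})

test_that("holography PSTH contrast separates responsive groups", {
  holo <- fx$holo
  ses <- fx$planted_session
  nt <- ses$neurons
  responsive <- list(
    IC1_encoders = unname(icdecode:::responsive_to(ses, "I_C1")),
    IC2_encoders = unname(icdecode:::responsive_to(ses, "I_C2")))
  res <- holo_psth_contrast(holo, responsive)
  expect_true(all(res$contrast > 0))
  # identical groups contrast to ~zero: scramble the responsive flags
  set.seed(11)
  scram <- lapply(responsive, sample)
  res0 <- holo_psth_contrast(holo, scram)
  expect_lt(mean(abs(res0$contrast)), mean(res$contrast))
  expect_error(
    holo_psth_contrast(list(timecourse = NULL), responsive),
    "time course")
})
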