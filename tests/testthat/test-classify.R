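# Functional-ensemble classification by rank tests.

# small synthetic response builder: n trials per condition, given means
make_cond_responses <- function(means, n = 40, sd = 1, seed = 1) {
  set.seed(seed)
  cond <- rep(names(means), each = n)
  X <- sapply(seq_along(means), function(i) rnorm(n, means[[i]], sd))
  list(responses = matrix(as.vector(X), ncol = 1), condition = cond)
}

test_that("tukey-kramer mean-rank comparison agrees with a rank-sum check", {
  set.seed(2)
  vals <- c(rnorm(30, 0), rnorm(30, 3), rnorm(30, 0))
  grp <- rep(c("a", "b", "c"), each = 30)
  p <- icdecode:::tukey_kramer_ranks(vals, grp)
  expect_true(p["a", "b"] < 0.01)
  expect_true(p["b", "c"] < 0.01)
  expect_true(p["a", "c"] > 0.2)
  expect_equal(p["a", "b"], p["b", "a"])
})

test_that("IC-encoder rule keeps single-image selectivity only", {
  cond5 <- c(blank_circles = 0, I_C1 = 3, L_C1 = 0, L_C2 = 0, I_C2 = 0)
  r <- make_cond_responses(as.list(cond5), seed = 3)
  expect_equal(as.character(find_ic_encoders(r$responses, r$condition)), "I_C1")
  # a segment responder (equal I_C and L_C response) is excluded
  seg <- make_cond_responses(list(blank_circles = 0, I_C1 = 3, L_C1 = 3,
                                  L_C2 = 0, I_C2 = 0), seed = 4)
  expect_equal(as.character(find_ic_encoders(seg$responses, seg$condition)), "none")
  # an all-equal responder fails the omnibus
  flat <- make_cond_responses(list(blank_circles = 1, I_C1 = 1, L_C1 = 1,
                                   L_C2 = 1, I_C2 = 1), seed = 5)
  expect_equal(as.character(find_ic_encoders(flat$responses, flat$condition)), "none")
  # both-I_C responders are excluded (exactly-one rule)
  both <- make_cond_responses(list(blank_circles = 0, I_C1 = 3, L_C1 = 0,
                                   L_C2 = 0, I_C2 = 3), seed = 6)
  expect_equal(as.character(find_ic_encoders(both$responses, both$condition)), "none")
  expect_error(find_ic_encoders(r$responses[1:40, , drop = FALSE],
                                r$condition[1:40]), "missing")
})

test_that("LC-encoder rule mirrors the IC rule with roles swapped", {
  lc <- make_cond_responses(list(blank_circles = 0, I_C1 = 0, L_C1 = 3,
                                 L_C2 = 0, I_C2 = 0), seed = 7)
  expect_equal(as.character(find_lc_encoders(lc$responses, lc$condition)), "L_C1")
  expect_equal(as.character(find_ic_encoders(lc$responses, lc$condition)), "none")
  ic <- make_cond_responses(list(blank_circles = 0, I_C1 = 3, L_C1 = 0,
                                 L_C2 = 0, I_C2 = 0), seed = 8)
  expect_equal(as.character(find_lc_encoders(ic$responses, ic$condition)), "none")
})

test_that("planted sessions recover their IC-encoders and only those", {
  ses <- fx$planted_session
  cls <- find_ic_encoders(ses$responses, ses$trials$stimulus)
  truth <- ses$neurons$emergent_class
  expect_true(mean(cls[truth == "IC1"] == "I_C1") >= 0.8)
  expect_true(mean(cls[truth == "IC2"] == "I_C2") >= 0.8)
  expect_true(mean(cls[truth == "none"] == "none") >= 0.9)
})

test_that("segment responders are classed by quadrant with min-p ties", {
  quads <- c("BR", "BL", "TL", "TR")
  conds <- as.list(setNames(rep(0, 8), paste0(rep(c("In_", "Out_"), 4),
                                              rep(quads, each = 2))))
  conds$In_BR <- 2
  r <- make_cond_responses(conds, seed = 9)
  expect_equal(as.character(find_segment_responders(r$responses, r$condition)), "BR")
  # inward = outward everywhere -> none
  r0 <- make_cond_responses(lapply(conds, function(x) 0), seed = 31)
  expect_equal(as.character(find_segment_responders(r0$responses, r0$condition)), "none")
  # responder in two quadrants takes the smaller p (stronger effect)
  conds$In_TL <- 0.8
  r2 <- make_cond_responses(conds, seed = 11)
  expect_equal(as.character(find_segment_responders(r2$responses, r2$condition)), "BR")
})

test_that("exclusively center-responsive selection enforces both rules", {
  pos <- paste0("rf_pos_", 1:9)
  base <- as.list(setNames(rep(0, 10), c(pos, "gray")))
  ctr <- base; ctr$rf_pos_1 <- 3
  r <- make_cond_responses(ctr, seed = 12)
  expect_true(find_center_exclusive(r$responses, r$condition))
  # responding at a peripheral position as well disqualifies
  two <- ctr; two$rf_pos_2 <- 3
  r2 <- make_cond_responses(two, seed = 13)
  expect_false(find_center_exclusive(r2$responses, r2$condition))
  # null neuron excluded
  r3 <- make_cond_responses(base, seed = 14)
  expect_false(find_center_exclusive(r3$responses, r3$condition))
  expect_error(find_center_exclusive(r$responses[1, , drop = FALSE],
                                     r$condition[1]), "at least 2")
})

test_that("labels are invariant to trial-order permutation", {
  ses <- fx$planted_session
  set.seed(20)
  perm <- sample(nrow(ses$responses))
  a <- find_ic_encoders(ses$responses, ses$trials$stimulus)
  b <- find_ic_encoders(ses$responses[perm, , drop = FALSE],
                        ses$trials$stimulus[perm])
  expect_identical(as.character(a), as.character(b))
})

test_that("AUROC matches the brute-force pair-counting oracle", {
  set.seed(15)
  for (i in 1:5) {
    x <- rnorm(20, 1); y <- rnorm(25)
    expect_equal(auroc(x, y), naive_auroc(x, y))
  }
  expect_equal(auroc(2:6, -(1:5)), 1)   # perfect separation
  expect_equal(auroc(1:4, 1:4), 0.5)    # all ties
})

test_that("ensemble balancing trims to the smallest group by AUROC", {
  quads <- c("BR", "BL", "TL", "TR")
  seg_class <- rep(c("BR", "BL", "TL", "TR"), c(3, 5, 5, 5))
  n_neu <- length(seg_class)
  cond <- rep(paste0(rep(c("In_", "Out_"), 4), rep(quads, each = 2)),
              each = 20)
  set.seed(16)
  X <- matrix(rnorm(length(cond) * n_neu), length(cond), n_neu)
  # give each neuron a graded inward preference for its own quadrant
  for (i in seq_len(n_neu)) {
    own <- paste0("In_", seg_class[i])
    X[cond == own, i] <- X[cond == own, i] + i / 4
  }
  bal <- balance_segment_ensembles(seg_class, X, cond)
  expect_true(all(lengths(bal) == 3))
  # kept neurons are the top-AUROC ones within each trimmed group
  for (q in c("BL", "TL", "TR")) {
    idx <- which(seg_class == q)
    sc <- vapply(idx, function(i)
      auroc(X[cond == paste0("In_", q), i], X[cond == paste0("Out_", q), i]),
      numeric(1))
    expect_setequal(bal[[q]], idx[order(sc, decreasing = TRUE)][1:3])
  }
  # equal groups come back unchanged
  eq <- rep(quads, each = 2)
  Xeq <- matrix(rnorm(length(cond) * 8), length(cond), 8)
  expect_true(all(lengths(balance_segment_ensembles(eq, Xeq, cond)) == 2))
})

test_that("preferred-orientation match counts argmax agreement", {
  ic <- rbind(c(1, 3), c(4, 1), c(2, 5))
  colnames(ic) <- c("45", "135")
  ire <- rbind(c(0, 2), c(1, 3), c(1, 4))
  colnames(ire) <- c("45", "135")
  m <- preferred_orientation_match(ic, ire)
  expect_equal(m$match, c(TRUE, FALSE, TRUE))
  expect_equal(m$match_fraction, 2 / 3)
  # planted match fraction is recovered by counting
  set.seed(17)
  n <- 200
  pref <- sample(c("45", "135"), n, replace = TRUE)
  match_flag <- runif(n) < 0.8
  ic2 <- t(sapply(pref, function(p) (c("45", "135") == p) * 2 + rnorm(2, 0, 0.1)))
  pref_ire <- ifelse(match_flag, pref,
                     ifelse(pref == "45", "135", "45"))
  ire2 <- t(sapply(pref_ire, function(p) (c("45", "135") == p) * 2 + rnorm(2, 0, 0.1)))
  colnames(ic2) <- colnames(ire2) <- c("45", "135")
  m2 <- preferred_orientation_match(ic2, ire2)
  expect_equal(m2$match_fraction, mean(match_flag), tolerance = 0.03)
})
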