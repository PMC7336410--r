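test_that("the metric suite reproduces hand-computable confusions", {
  # perfect classifier
  m1 <- compute_metrics(TP = 10, FP = 0, TN = 20, FN = 0)
  expect_equal(unlist(m1[c("SEN", "SPE", "ACC", "PRE", "F1", "MCC")]),
               c(SEN = 1, SPE = 1, ACC = 1, PRE = 1, F1 = 1, MCC = 1))
  # all-negative predictor on mixed labels
  m2 <- compute_metrics(TP = 0, FP = 0, TN = 20, FN = 10)
  expect_equal(m2$SEN, 0)
  expect_equal(m2$PRE, 0)
  expect_true(m2$undefined[["PRE"]])
  expect_equal(m2$SPE, 1)
})

test_that("metric identities hold on random confusion matrices", {
  set.seed(7)
  for (i in 1:50) {
    cts <- rmultinom(1, 60, c(0.25, 0.25, 0.25, 0.25))[, 1]
    m <- compute_metrics(cts[1], cts[2], cts[3], cts[4])
    expect_equal(m$ACC, (cts[1] + cts[3]) / 60)
    if (m$PRE > 0 && m$SEN > 0) {
      expect_equal(m$F1, 2 * m$PRE * m$SEN / (m$PRE + m$SEN),
                   tolerance = 1e-12)
    }
    # MCC symmetric under simultaneous class/prediction swap
    m_sw <- compute_metrics(cts[3], cts[4], cts[1], cts[2])
    expect_equal(m$MCC, m_sw$MCC, tolerance = 1e-12)
  }
})

test_that("AUROC equals the exhaustive pairwise probability", {
  # hand set: pos {0.9, 0.4}, neg {0.8, 0.1} -> 3 wins of 4 pairs
  r <- curve_aucs(c(0.9, 0.4, 0.8, 0.1), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r$auroc, 0.75)
  # perfect ranking
  rp <- curve_aucs(c(3, 2, 1, 0), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(rp$auroc, 1)
  expect_equal(rp$auprc, 1)
  # random small instances vs brute force with ties
  set.seed(11)
  for (i in 1:50) {
    n <- sample(4:30, 1)
    y <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
    s <- sample(seq(0, 1, 0.1), n, replace = TRUE)
    brute <- mean(outer(s[y], s[!y], function(a, b) {
      (a > b) + 0.5 * (a == b)
    }))
    expect_equal(curve_aucs(s, y)$auroc, brute, tolerance = 1e-12)
  }
})

test_that("label-independent scores give a chance-level AUROC", {
  set.seed(3)
  y <- rep(c(TRUE, FALSE), 1000)
  s <- rnorm(2000)
  expect_lt(abs(curve_aucs(s, y)$auroc - 0.5), 0.03)
})

test_that("rank AUROC agrees with an independent reference", {
  skip_if_not_installed("pROC")
  set.seed(21)
  y <- sample(c(TRUE, FALSE), 80, replace = TRUE)
  s <- rnorm(80) + y
  ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                        direction = "<")))
  expect_equal(curve_aucs(s, y)$auroc, ref, tolerance = 1e-9)
})

test_that("CART screening finds a separating feature and is seeded", {
  set.seed(5)
  n <- 120
  y <- rep(c(TRUE, FALSE), n / 2)
  x <- matrix(rnorm(n * 10), n, 10,
              dimnames = list(NULL, sprintf("F%02d", 1:10)))
  x[, 4] <- ifelse(y, 1, -1)   # perfectly separating
  sel <- cart_select(x, y, seed = 2)
  expect_equal(sel[1], "F04")
  expect_identical(sel, cart_select(x, y, seed = 2))
  expect_error(cart_select(x, rep(TRUE, n), seed = 1), "single-class")
})

test_that("the exact support-vector shortcut matches brute-force LOO", {
  d <- make_planted_dataset(n = 60, n_informative = 2, n_noise = 3,
                            shift = 1.5, class_ratio = c(1, 2),
                            group_count = 5, seed = 13)
  fast <- pnhot:::loo_decision_values(d$x, d$y, G = 0.1, C = 40,
                                      per_fold = FALSE)
  z <- standardize(d$x)$x
  brute <- vapply(seq_len(nrow(z)), function(i) {
    f <- pnhot:::svm_fit(z[-i, , drop = FALSE], d$y[-i], 0.1, 40)
    pnhot:::svm_decision(f, z[i, , drop = FALSE])
  }, numeric(1))
  # identical up to the SVM solver's own convergence tolerance
  expect_equal(fast, brute, tolerance = 1e-2)
  expect_equal(fast > 0, brute > 0)
})

test_that("forward selection handles a single candidate in one round", {
  d <- make_planted_dataset(n = 60, n_informative = 1, n_noise = 4,
                            shift = 2, class_ratio = c(1, 1),
                            group_count = 5, seed = 3)
  tr <- sfs_beam_select(d$x, d$y, candidates = "INF01")
  expect_equal(tr$final_set, "INF01")
  expect_equal(length(tr$rounds), 1L)
})

test_that("best F1 is non-decreasing across kept rounds", {
  d <- make_planted_dataset(n = 120, n_informative = 3, n_noise = 7,
                            shift = 1.5, group_count = 6, seed = 8)
  tr <- sfs_beam_select(d$x, d$y, candidates = colnames(d$x)[1:6])
  best <- vapply(tr$rounds, function(r) r$f1[1], numeric(1))
  if (length(best) > 1) {
    expect_true(all(diff(best[-length(best)]) > 0) ||
                  length(best) <= 2)
    # the final round is the first non-improving one (or exhaustion)
    expect_true(tr$best_f1 >= max(best[-length(best)]) ||
                  length(best) == 1)
  }
  expect_true(all(tr$final_set %in% colnames(d$x)[1:6]))
})

test_that("beam width 1 with a monotone scorer is classic greedy", {
  weights <- c(A = 5, B = 3, C = 2, D = 1)
  x <- matrix(0, 30, 4, dimnames = list(NULL, names(weights)))
  y <- rep(c(TRUE, FALSE), 15)
  scorer <- function(features) sum(weights[features]) / 20
  tr <- sfs_beam_select(x, y, candidates = names(weights), beam = 1,
                        scorer = scorer)
  # greedy adds features in weight order and runs to exhaustion
  expect_equal(tr$final_set, sort(names(weights)))
  first_sets <- vapply(tr$rounds, function(r) r$set[1], character(1))
  expect_equal(first_sets[1:3], c("A", "A+B", "A+B+C"))
})

test_that("a failing scorer zeroes the candidate instead of aborting", {
  x <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("a", "b")))
  y <- rep(c(TRUE, FALSE), 10)
  scorer <- function(features) {
    if ("b" %in% features) stop("boom")
    0.7
  }
  ws <- capture_warnings(
    tr <- sfs_beam_select(x, y, candidates = c("a", "b"),
                          scorer = scorer))
  expect_true(any(grepl("boom", ws)))
  expect_equal(tr$final_set, "a")
})

test_that("grid tuning honours the grid and finds separable optima", {
  d <- make_planted_dataset(n = 40, n_informative = 2, n_noise = 0,
                            shift = 8, class_ratio = c(1, 1),
                            group_count = 4, seed = 21)
  fit <- tune_and_train(d$x, d$y)
  expect_equal(max(fit$tuning$f1), 1)
  one <- tune_and_train(d$x, d$y, grid_G = 0.1, grid_C = 40)
  expect_equal(c(one$G, one$C), c(0.1, 40))
  expect_error(tune_and_train(d$x, d$y, grid_G = numeric(0)),
               "empty parameter grid")
})

test_that("permuted labels score near the class-prior baseline", {
  d <- make_planted_dataset(n = 90, n_informative = 3, n_noise = 2,
                            shift = 1.5, group_count = 6, seed = 31)
  p <- mean(d$y)
  baseline <- 2 * p / (1 + p)   # F1 of an all-positive predictor
  f1s <- vapply(1:10, function(s) {
    yp <- pnhot:::with_seed(500 + s, sample(d$y))
    dv <- pnhot:::loo_decision_values(d$x, yp, 0.1, 40)
    pnhot:::f1_score(dv > 0, yp)
  }, numeric(1))
  expect_lt(mean(f1s), baseline + 0.15)
})

test_that("cross-validation bookkeeping isolates every fold", {
  d <- make_planted_dataset(n = 4, n_informative = 1, n_noise = 1,
                            shift = 2, class_ratio = c(1, 1),
                            group_count = 2, seed = 2)
  cv <- crossvalidate(d$x, d$y, mode = "loo", refit_standardize = TRUE)
  expect_length(cv$scores, 4L)
  expect_equal(cv$fold_of, 1:4)

  # group mode: a row's fold is its complex, never seen in training
  d2 <- make_planted_dataset(n = 30, n_informative = 2, n_noise = 2,
                             shift = 2, group_count = 2, seed = 4)
  cv2 <- crossvalidate(d2$x, d2$y, mode = "group", groups = d2$groups)
  expect_equal(cv2$fold_of, match(d2$groups, unique(d2$groups)))
  expect_error(crossvalidate(d2$x, d2$y, mode = "group",
                             groups = rep("g1", 30)), ">= 2 groups")
})

test_that("rank-sum screening has calibrated size and real power", {
  set.seed(9)
  n <- 100
  x <- matrix(rnorm(2 * n * 97), 2 * n, 97,
              dimnames = list(NULL, paste0("f", 1:97)))
  y <- rep(c(TRUE, FALSE), each = n)
  # null: labels carry no signal
  fracs <- vapply(1:20, function(i) {
    ys <- sample(y)
    mean(ranksum_feature_analysis(x, ys)$p_value < 0.05)
  }, numeric(1))
  expect_lt(abs(mean(fracs) - 0.05), 0.03)
  # power: a 3-sigma shift is overwhelming at n = 100 per class
  x2 <- x
  x2[y, 1] <- x2[y, 1] + 3
  expect_lt(ranksum_feature_analysis(x2, y, "f1")$p_value, 1e-6)
  # constant feature
  x2[, 2] <- 1
  r <- ranksum_feature_analysis(x2, y, "f2")
  expect_equal(r$p_value, 1)
  expect_true(r$constant)
})
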