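# Two-step feature selection (CART then beam sequential forward
# selection), RBF-SVM training with grid search, leave-one-residue-out
# and leave-one-complex-out cross-validation, and the metric suite.

#' Classification metric suite from a confusion matrix
#'
#' Sensitivity (recall), specificity, accuracy, precision, F1 and the
#' Matthews correlation coefficient.  Specificity is TN / (TN + FP).
#' A ratio with zero denominator is defined as 0 and flagged.
#'
#' @param TP,FP,TN,FN non-negative integer confusion counts.
#' @return object of class \code{pnhot_metrics}: named list SEN, SPE,
#'   ACC, PRE, F1, MCC plus the counts and an \code{undefined} flag
#'   vector.
#' @examples
#' compute_metrics(TP = 54, FP = 18, TN = 189, FN = 32)
#' @export
compute_metrics <- function(TP, FP, TN, FN) {
  stopifnot(TP >= 0, FP >= 0, TN >= 0, FN >= 0, TP + FP + TN + FN >= 1)
  safe <- function(num, den) if (den == 0) 0 else num / den
  undef <- c(SEN = TP + FN == 0, SPE = TN + FP == 0,
             PRE = TP + FP == 0,
             MCC = (TP + FP) * (TP + FN) * (TN + FP) * (TN + FN) == 0)
  mcc_den <- sqrt((TP + FP)) * sqrt((TP + FN)) * sqrt((TN + FP)) *
    sqrt((TN + FN))
  out <- list(
    SEN = safe(TP, TP + FN),
    SPE = safe(TN, TN + FP),
    ACC = (TP + TN) / (TP + FN + TN + FP),
    PRE = safe(TP, TP + FP),
    F1 = safe(2 * TP, 2 * TP + FN + FP),
    MCC = if (mcc_den == 0) 0 else (TP * TN - FP * FN) / mcc_den,
    counts = c(TP = TP, FP = FP, TN = TN, FN = FN),
    undefined = undef
  )
  class(out) <- "pnhot_metrics"
  out
}

#' @export
print.pnhot_metrics <- function(x, digits = 3, ...) {
  v <- unlist(x[c("SEN", "SPE", "ACC", "PRE", "F1", "MCC")])
  print(round(v, digits))
  invisible(x)
}

metrics_from_predictions <- function(pred, truth) {
  compute_metrics(TP = sum(pred & truth), FP = sum(pred & !truth),
                  TN = sum(!pred & !truth), FN = sum(!pred & truth))
}

f1_score <- function(pred, truth) {
  tp <- sum(pred & truth)
  den <- 2 * tp + sum(!pred & truth) + sum(pred & !truth)
  if (den == 0) 0 else 2 * tp / den
}

#' ROC and precision-recall curves with areas
#'
#' AUROC is computed by the rank statistic (the probability that a
#' random positive scores above a random negative, ties counting one
#' half); the precision-recall curve is integrated step-wise (the
#' precision at each recall step), with tied scores processed as
#' blocks.
#'
#' @param scores real-valued classifier scores (higher = more positive).
#' @param labels logical (or coercible) class labels.
#' @return list with \code{auroc}, \code{auprc}, \code{roc}
#'   (data.frame fpr, tpr) and \code{prc} (data.frame recall,
#'   precision).
#' @export
curve_aucs <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels))
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)   # average ranks handle ties as half wins
  auroc <- (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  thr <- sort(unique(scores), decreasing = TRUE)
  tp <- cumsum(vapply(thr, function(t) sum(labels & scores == t),
                      numeric(1)))
  fp <- cumsum(vapply(thr, function(t) sum(!labels & scores == t),
                      numeric(1)))
  tpr <- tp / n1
  fpr <- fp / n0
  rec <- tpr
  prec <- ifelse(tp + fp > 0, tp / (tp + fp), 1)
  auprc <- sum(diff(c(0, rec)) * prec)
  list(auroc = auroc, auprc = auprc,
       roc = data.frame(fpr = c(0, fpr), tpr = c(0, tpr)),
       prc = data.frame(recall = c(0, rec), precision = c(1, prec)))
}

#' CART screening step of the two-step feature selection
#'
#' Grows a classification tree (Gini impurity, minimum bucket 1, no
#' depth cap beyond the implementation limit) and returns the features
#' used in at least one split, ordered by their total impurity
#' decrease.  By default the fully grown tree is used, matching the
#' behaviour of standard CART fitters whose "best subset" is the set of
#' predictors the grown tree splits on; \code{prune = "cv"} instead
#' prunes by cost-complexity at the minimum internal cross-validation
#' error first, which yields a smaller, less complete subset.
#'
#' @param x feature matrix with column names.
#' @param y logical hotspot labels.
#' @param seed integer seed (drives the internal cross-validation
#'   partition).
#' @param cp complexity parameter for the initial fit.
#' @param prune "none" (default) or "cv".
#' @return character vector of selected feature names.
#' @export
cart_select <- function(x, y, seed = 1, cp = 0.001,
                        prune = c("none", "cv")) {
  prune <- match.arg(prune)
  y <- as.logical(y)
  stopifnot(nrow(x) >= 20, !is.null(colnames(x)))
  if (length(unique(y)) < 2L) stop("labels are single-class")
  df <- data.frame(.y = factor(ifelse(y, "hot", "non"),
                               levels = c("hot", "non")),
                   x, check.names = FALSE)
  fit <- with_seed(seed, rpart::rpart(
    .y ~ ., data = df, method = "class",
    parms = list(split = "gini"),
    control = rpart::rpart.control(minsplit = 2, minbucket = 1,
                                   cp = cp, xval = 10, maxdepth = 30,
                                   maxsurrogate = 0,
                                   maxcompete = 0)))
  pruned <- fit
  if (prune == "cv") {
    cptab <- fit$cptable
    best <- cptab[which.min(cptab[, "xerror"]), "CP"]
    pruned <- rpart::prune(fit, cp = best)
  }
  used <- unique(as.character(pruned$frame$var))
  used <- setdiff(used, "<leaf>")
  if (length(used) == 0L) return(character(0))
  imp <- pruned$variable.importance
  if (is.null(imp)) return(sort(used))
  imp <- imp[names(imp) %in% used]
  missing <- setdiff(used, names(imp))
  c(names(sort(imp, decreasing = TRUE)), sort(missing))
}

# Fit an RBF-SVM on an already-standardized matrix and return decision
# values oriented so that positive means hotspot.  A single-class
# training fold degenerates to a constant vote for the present class.
svm_fit <- function(zx, y, G, C) {
  if (length(unique(y)) < 2L) {
    return(structure(list(vote = y[1]), class = "pnhot_constant_svm"))
  }
  yf <- factor(ifelse(y, "hot", "non"), levels = c("hot", "non"))
  e1071::svm(zx, yf, type = "C-classification", kernel = "radial",
             gamma = G, cost = C, scale = FALSE)
}

svm_decision <- function(fit, zx) {
  if (inherits(fit, "pnhot_constant_svm")) {
    return(rep(if (fit$vote) 1 else -1, nrow(zx)))
  }
  p <- stats::predict(fit, zx, decision.values = TRUE)
  dv <- attr(p, "decision.values")
  first <- strsplit(colnames(dv)[1], "/")[[1]][1]
  d <- as.numeric(dv[, 1])
  if (first != "hot") d <- -d
  d
}

# Leave-one-out decision values.  With global standardization the exact
# support-vector shortcut applies: removing a point with zero dual
# coefficient leaves the solution unchanged, so only support-vector
# folds are refit.  With per-fold standardization every fold is refit.
loo_decision_values <- function(x, y, G, C, per_fold = FALSE) {
  n <- nrow(x)
  if (!per_fold) {
    z <- standardize(x)$x
    fit <- svm_fit(z, y, G, C)
    dv <- svm_decision(fit, z)
    if (inherits(fit, "pnhot_constant_svm")) return(dv)
    for (i in fit$index) {
      f_i <- svm_fit(z[-i, , drop = FALSE], y[-i], G, C)
      dv[i] <- svm_decision(f_i, z[i, , drop = FALSE])
    }
    dv
  } else {
    vapply(seq_len(n), function(i) {
      s <- standardize(x, fit_rows = setdiff(seq_len(n), i))
      f_i <- svm_fit(s$x[-i, , drop = FALSE], y[-i], G, C)
      svm_decision(f_i, s$x[i, , drop = FALSE])
    }, numeric(1))
  }
}

#' Beam sequential forward feature selection scored by cross-validated F1
#'
#' Starting from the candidate pool (normally the CART-selected subset),
#' each round extends every surviving feature set by every unused
#' candidate, scores each extension by the cross-validated F1 of an
#' RBF-SVM at fixed (G, C), and keeps the best \code{beam} sets.  The
#' search stops when the round's best F1 fails to improve on the
#' previous round, returning the previous best set.  Equal-F1 sets are
#' ordered alphabetically by their sorted feature names.
#'
#' @param x feature matrix with column names.
#' @param y logical hotspot labels.
#' @param candidates candidate feature names (nonempty).
#' @param beam beam width (default 3).
#' @param G,C RBF-SVM parameters used by the default scorer.
#' @param per_fold re-standardize inside each cross-validation fold
#'   (default FALSE inside selection: the standardizer is fit once on
#'   the full matrix, as when features are z-scored up front).
#' @param max_rounds hard cap on rounds.
#' @param scorer optional function(feature names) -> F1; overrides the
#'   default leave-one-out SVM scorer.
#' @return object of class \code{pnhot_sfs}: list with \code{final_set},
#'   \code{best_f1}, \code{converged_round} and \code{rounds} (each a
#'   data.frame of evaluated sets and scores, with the kept sets
#'   flagged).
#' @export
sfs_beam_select <- function(x, y, candidates, beam = 3, G = 0.1, C = 40,
                            per_fold = FALSE, max_rounds = 20,
                            scorer = NULL) {
  stopifnot(length(candidates) >= 1,
            all(candidates %in% colnames(x)))
  y <- as.logical(y)
  if (is.null(scorer)) {
    scorer <- function(features) {
      dv <- loo_decision_values(x[, features, drop = FALSE], y, G, C,
                                per_fold = per_fold)
      f1_score(dv > 0, y)
    }
  }
  score_safe <- function(features) {
    tryCatch(scorer(features), error = function(e) {
      warning("scorer failed on {", paste(features, collapse = ","),
              "}: ", conditionMessage(e))
      0
    })
  }
  beams <- list(character(0))
  best_prev <- -Inf
  best_set <- character(0)
  rounds <- list()
  converged <- 0L
  for (r in seq_len(max_rounds)) {
    cand_sets <- list()
    for (b in beams) {
      for (f in setdiff(candidates, b)) {
        s <- sort(c(b, f))
        cand_sets[[paste(s, collapse = "+")]] <- s
      }
    }
    if (length(cand_sets) == 0L) break
    f1s <- vapply(cand_sets, score_safe, numeric(1))
    ord <- order(-f1s, names(cand_sets))
    tab <- data.frame(set = names(cand_sets)[ord],
                      n_features = lengths(cand_sets)[ord],
                      f1 = unname(f1s[ord]),
                      kept = seq_along(ord) <= beam,
                      row.names = NULL, stringsAsFactors = FALSE)
    rounds[[r]] <- tab
    best_now <- tab$f1[1]
    if (best_now <= best_prev) {
      converged <- r
      break
    }
    best_prev <- best_now
    best_set <- cand_sets[[ord[1]]]
    beams <- cand_sets[ord[seq_len(min(beam, length(ord)))]]
    converged <- r
    if (length(best_set) == length(candidates)) break
  }
  structure(list(final_set = best_set, best_f1 = best_prev,
                 converged_round = converged, rounds = rounds,
                 beam = beam, G = G, C = C),
            class = "pnhot_sfs")
}

#' @export
print.pnhot_sfs <- function(x, ...) {
  cat("<pnhot_sfs> beam", x$beam, "-", length(x$rounds),
      "rounds, converged at round", x$converged_round, "\n")
  cat("  best F1:", round(x$best_f1, 3), "\n")
  cat("  final set:", paste(x$final_set, collapse = ", "), "\n")
  invisible(x)
}

#' Grid-tuned RBF-SVM on a fixed feature set
#'
#' Selects (G, C) from the grid by leave-one-out cross-validated F1
#' (ties resolved toward smaller C, then smaller G), then fits the final
#' decision function on all rows with a globally fit standardizer.
#'
#' @param x feature matrix with column names.
#' @param y logical hotspot labels.
#' @param features feature names to use (default all columns).
#' @param grid_G kernel-width grid within [0, 2].
#' @param grid_C cost grid within [0, 40].
#' @param per_fold per-fold re-standardization for the tuning scores.
#' @return object of class \code{pnhot_svm}: list with \code{model},
#'   \code{G}, \code{C}, \code{features}, \code{standardizer},
#'   \code{tuning} (grid with LOO F1 per point).
#' @export
tune_and_train <- function(x, y, features = colnames(x),
                           grid_G = c(0.01, 0.05, 0.1, 0.5, 1, 2),
                           grid_C = c(1, 5, 10, 20, 40),
                           per_fold = FALSE) {
  if (length(grid_G) == 0L || length(grid_C) == 0L) {
    stop("empty parameter grid")
  }
  y <- as.logical(y)
  xs <- x[, features, drop = FALSE]
  grid <- expand.grid(G = grid_G, C = grid_C)
  grid$f1 <- vapply(seq_len(nrow(grid)), function(i) {
    dv <- loo_decision_values(xs, y, grid$G[i], grid$C[i],
                              per_fold = per_fold)
    f1_score(dv > 0, y)
  }, numeric(1))
  ord <- order(-grid$f1, grid$C, grid$G)
  G <- grid$G[ord[1]]
  C <- grid$C[ord[1]]
  s <- standardize(xs)
  model <- svm_fit(s$x, y, G, C)
  structure(list(model = model, G = G, C = C, features = features,
                 standardizer = list(mean = s$mean, sd = s$sd),
                 tuning = grid),
            class = "pnhot_svm")
}

predict_pnhot_svm <- function(object, newdata) {
  z <- standardize(newdata[, object$features, drop = FALSE],
                   params = object$standardizer)$x
  svm_decision(object$model, z)
}

#' Cross-validation of an RBF-SVM feature set
#'
#' Per-residue mode is leave-one-out: each row is predicted by a model
#' trained on the remaining rows.  Per-protein (group) mode holds out
#' all residues of one complex per fold.  By default the standardizer is
#' re-fit inside each training fold; metrics are computed from the
#' pooled out-of-fold decision values (threshold 0) together with the
#' ROC and precision-recall areas.
#'
#' @param x feature matrix with column names.
#' @param y logical hotspot labels.
#' @param features feature names to use.
#' @param mode "loo" (per residue) or "group" (per complex).
#' @param groups complex identifiers, required for group mode (>= 2
#'   distinct values).
#' @param G,C RBF-SVM parameters.
#' @param refit_standardize re-fit the standardizer inside each fold
#'   (default TRUE).
#' @return list with \code{scores} (out-of-fold decision values),
#'   \code{pred}, \code{metrics} (a \code{pnhot_metrics}),
#'   \code{auroc}, \code{auprc}, \code{curves}, \code{mode},
#'   \code{fold_of} (fold id per row).
#' @export
crossvalidate <- function(x, y, features = colnames(x),
                          mode = c("loo", "group"), groups = NULL,
                          G = 0.1, C = 40, refit_standardize = TRUE) {
  mode <- match.arg(mode)
  y <- as.logical(y)
  xs <- x[, features, drop = FALSE]
  n <- nrow(xs)
  if (mode == "loo") {
    dv <- loo_decision_values(xs, y, G, C,
                              per_fold = refit_standardize)
    fold_of <- seq_len(n)
  } else {
    if (is.null(groups)) stop("group mode requires groups")
    groups <- as.character(groups)
    ug <- unique(groups)
    if (length(ug) < 2L) stop("group mode requires >= 2 groups")
    dv <- numeric(n)
    for (g in ug) {
      test <- which(groups == g)
      train <- which(groups != g)
      if (refit_standardize) {
        s <- standardize(xs, fit_rows = train)
      } else {
        s <- standardize(xs)
      }
      fit <- svm_fit(s$x[train, , drop = FALSE], y[train], G, C)
      dv[test] <- svm_decision(fit, s$x[test, , drop = FALSE])
    }
    fold_of <- match(groups, ug)
  }
  pred <- dv > 0
  curves <- if (length(unique(y)) == 2L) curve_aucs(dv, y) else NULL
  list(scores = dv, pred = pred,
       metrics = metrics_from_predictions(pred, y),
       auroc = curves$auroc %||% NA_real_,
       auprc = curves$auprc %||% NA_real_,
       curves = curves, mode = mode, fold_of = fold_of,
       G = G, C = C)
}

#' Wilcoxon rank-sum screen of features against the hotspot label
#'
#' Two-sided rank-sum test (normal approximation with tie correction)
#' per feature, comparing hotspot and non-hotspot values.  A constant
#' feature gets p = 1 and is flagged.
#'
#' @param x feature matrix with column names.
#' @param y logical hotspot labels.
#' @param features feature names to test (default all columns).
#' @return data.frame with columns feature, p_value, constant.
#' @export
ranksum_feature_analysis <- function(x, y, features = colnames(x)) {
  y <- as.logical(y)
  stopifnot(any(y), any(!y))
  res <- lapply(features, function(f) {
    v <- x[, f]
    if (length(unique(v)) == 1L) {
      return(data.frame(feature = f, p_value = 1, constant = TRUE))
    }
    p <- stats::wilcox.test(v[y], v[!y], exact = FALSE,
                            correct = TRUE)$p.value
    data.frame(feature = f, p_value = p, constant = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
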