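#' Fit a hot-spot classifier with two-step feature selection
#'
#' The main modelling entry point: given a residue feature matrix and
#' hotspot labels, (1) screens features with a pruned CART decision
#' tree, (2) refines the subset with a beam (width 3) sequential
#' forward search scored by cross-validated F1 of an RBF-SVM at fixed
#' (G, C) = (0.1, 40), and (3) grid-tunes (G in [0, 2], C in [0, 40])
#' and fits the final RBF-SVM decision function on all rows.  The
#' returned object carries the full selection trace and a
#' leave-one-out cross-validation report on the selected features.
#'
#' @param x numeric feature matrix (rows = interface residues, named
#'   columns), e.g. from \code{\link{interface_feature_table}} or
#'   \code{\link{make_planted_dataset}}.
#' @param y hotspot labels (logical, or anything \code{as.logical}
#'   accepts).
#' @param groups optional complex identifiers; when present, a
#'   leave-one-complex-out cross-validation report is added.
#' @param select run the two-step feature selection (default TRUE;
#'   otherwise all columns, or \code{features}, are used as-is).
#' @param features feature names to use when \code{select = FALSE}.
#' @param beam beam width of the forward search.
#' @param grid_G,grid_C SVM tuning grids.
#' @param sel_G,sel_C fixed SVM parameters used by the selection scorer.
#' @param seed integer seed (CART internal cross-validation).
#' @param cv_refit_standardize re-fit the standardizer inside each
#'   cross-validation fold of the final report.
#' @return an object of class \code{pnhot}.
#' @examples
#' d <- make_planted_dataset(n = 120, n_informative = 3, n_noise = 10,
#'                           shift = 2, group_count = 8, seed = 7)
#' fit <- pnhot(d$x, d$y, groups = d$groups, seed = 7)
#' print(fit)
#' head(predict(fit, d$x))
#' @seealso \code{\link{cart_select}}, \code{\link{sfs_beam_select}},
#'   \code{\link{tune_and_train}}, \code{\link{crossvalidate}}
#' @export
pnhot <- function(x, y, groups = NULL, select = TRUE, features = NULL,
                  beam = 3, grid_G = c(0.01, 0.05, 0.1, 0.5, 1, 2),
                  grid_C = c(1, 5, 10, 20, 40), sel_G = 0.1,
                  sel_C = 40, seed = 1, cv_refit_standardize = TRUE) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) {
    colnames(x) <- sprintf("F%02d", seq_len(ncol(x)))
  }
  y <- as.logical(y)
  stopifnot(length(y) == nrow(x))
  if (length(unique(y)) < 2L) stop("labels are single-class")

  cart_features <- NULL
  trace <- NULL
  if (select) {
    cart_features <- cart_select(x, y, seed = seed)
    if (length(cart_features) == 0L) {
      warning("CART selected no features; using all columns")
      cart_features <- colnames(x)
    }
    trace <- sfs_beam_select(x, y, candidates = cart_features,
                             beam = beam, G = sel_G, C = sel_C)
    features <- trace$final_set
  } else if (is.null(features)) {
    features <- colnames(x)
  }

  svmfit <- tune_and_train(x, y, features = features, grid_G = grid_G,
                           grid_C = grid_C)
  cv <- crossvalidate(x, y, features = features, mode = "loo",
                      G = svmfit$G, C = svmfit$C,
                      refit_standardize = cv_refit_standardize)
  cv_group <- NULL
  if (!is.null(groups) && length(unique(groups)) >= 2L) {
    cv_group <- crossvalidate(x, y, features = features,
                              mode = "group", groups = groups,
                              G = svmfit$G, C = svmfit$C,
                              refit_standardize = cv_refit_standardize)
  }
  structure(list(
    features = features, cart_features = cart_features, trace = trace,
    svm = svmfit, G = svmfit$G, C = svmfit$C, cv = cv,
    cv_group = cv_group, y = y, groups = groups, seed = seed,
    n = nrow(x), call = match.call()
  ), class = "pnhot")
}

#' @export
print.pnhot <- function(x, ...) {
  cat("Hot-spot classifier (RBF-SVM after two-step feature",
      "selection)\n")
  cat("  n =", x$n, "residues,", sum(x$y), "hot spots /",
      sum(!x$y), "non-hot spots\n")
  cat("  selected features:", paste(x$features, collapse = ", "), "\n")
  cat("  SVM parameters: G =", x$G, " C =", x$C, "\n")
  m <- x$cv$metrics
  cat(sprintf(
    "  LOO CV: F1 %.3f  REC %.3f  PRE %.3f  SPE %.3f  ACC %.3f  MCC %.3f\n",
    m$F1, m$SEN, m$PRE, m$SPE, m$ACC, m$MCC))
  cat(sprintf("  LOO CV: AUROC %.3f  AUPRC %.3f\n", x$cv$auroc,
              x$cv$auprc))
  invisible(x)
}

#' @export
summary.pnhot <- function(object, ...) {
  out <- list(
    features = object$features,
    cart_features = object$cart_features,
    config = c(G = object$G, C = object$C),
    loo = c(unlist(object$cv$metrics[c("SEN", "SPE", "ACC", "PRE",
                                       "F1", "MCC")]),
            AUROC = object$cv$auroc, AUPRC = object$cv$auprc),
    group = if (!is.null(object$cv_group)) {
      c(unlist(object$cv_group$metrics[c("SEN", "SPE", "ACC", "PRE",
                                         "F1", "MCC")]),
        AUROC = object$cv_group$auroc, AUPRC = object$cv_group$auprc)
    },
    rounds = if (!is.null(object$trace)) {
      data.frame(
        round = seq_along(object$trace$rounds),
        best_f1 = vapply(object$trace$rounds,
                         function(r) r$f1[1], numeric(1)),
        best_set = vapply(object$trace$rounds,
                          function(r) r$set[1], character(1)))
    }
  )
  class(out) <- "summary.pnhot"
  out
}

#' @export
print.summary.pnhot <- function(x, ...) {
  cat("Selected features:", paste(x$features, collapse = ", "), "\n")
  cat("SVM: G =", x$config["G"], " C =", x$config["C"], "\n\n")
  cat("Leave-one-residue-out cross-validation:\n")
  print(round(x$loo, 3))
  if (!is.null(x$group)) {
    cat("\nLeave-one-complex-out cross-validation:\n")
    print(round(x$group, 3))
  }
  if (!is.null(x$rounds)) {
    cat("\nForward-selection rounds:\n")
    print(x$rounds, row.names = FALSE)
  }
  invisible(x)
}

#' Predict hot spots for new residues
#'
#' @param object a fitted \code{pnhot} model.
#' @param newdata feature matrix containing at least the model's
#'   selected feature columns (standardized internally with the
#'   training parameters).
#' @param type "class" for logical hotspot calls, "score" for the SVM
#'   decision values (positive = hotspot).
#' @param ... unused.
#' @return logical or numeric vector, one element per row.
#' @export
predict.pnhot <- function(object, newdata,
                          type = c("class", "score"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  dv <- predict_pnhot_svm(object$svm, newdata)
  if (type == "score") dv else dv > 0
}

#' Plot cross-validated ROC and precision-recall curves
#'
#' @param x a fitted \code{pnhot} model.
#' @param which "roc", "prc" or "both" (default).
#' @param ... passed to \code{plot.default}.
#' @export
plot.pnhot <- function(x, which = c("both", "roc", "prc"), ...) {
  which <- match.arg(which)
  cv <- x$cv
  if (is.null(cv$curves)) stop("no cross-validation curves available")
  if (which == "both") {
    op <- graphics::par(mfrow = c(1, 2))
    on.exit(graphics::par(op))
  }
  if (which %in% c("both", "roc")) {
    plot(cv$curves$roc$fpr, cv$curves$roc$tpr, type = "s",
         xlab = "False positive rate", ylab = "True positive rate",
         main = sprintf("ROC (AUROC %.3f)", cv$auroc), ...)
    graphics::abline(0, 1, lty = 3)
  }
  if (which %in% c("both", "prc")) {
    plot(cv$curves$prc$recall, cv$curves$prc$precision, type = "s",
         xlab = "Recall", ylab = "Precision", ylim = c(0, 1),
         main = sprintf("PRC (AUPRC %.3f)", cv$auprc), ...)
    graphics::abline(h = mean(x$y), lty = 3)
  }
  invisible(x)
}
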