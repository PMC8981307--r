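#' Z-score feature scaling with stored parameters
#'
#' Scales each feature (column) to mean 0 and standard deviation 1, with the
#' parameters computed on a designated fitting subset so that held-out
#' samples can be transformed without leakage. The SD convention is
#' population (divide by n) by default; sample SD (n - 1) is available.
#' Features with zero variance on the fitting set are dropped with a
#' warning.
#'
#' @param features numeric matrix, samples x features.
#' @param fit_on indices (or logical mask) of rows used to estimate centers
#'   and scales; default all rows.
#' @param sd_type \code{"population"} or \code{"sample"}.
#' @return list of class \code{"scaled_features"}: \code{values} (all rows
#'   transformed), \code{center}, \code{scale}, \code{dropped}, \code{fit_on}.
#' @examples
#' scale_features(matrix(c(1, 2, 3), 3, 1))$values  # -1.225, 0, 1.225
#' @export
scale_features <- function(features, fit_on = NULL,
                           sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  x <- as.matrix(features)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  if (is.null(fit_on)) fit_on <- seq_len(nrow(x))
  xf <- x[fit_on, , drop = FALSE]
  n <- nrow(xf)
  center <- colMeans(xf)
  ss <- colSums(sweep(xf, 2L, center)^2)
  scale_ <- sqrt(ss / if (sd_type == "population") n else n - 1L)
  zero <- scale_ <= 0 | !is.finite(scale_)
  if (all(zero)) stop("all features are constant on the fitting set")
  dropped <- colnames(x)[zero]
  if (length(dropped)) {
    warning("dropping constant feature(s): ", paste(dropped, collapse = ", "))
  }
  keep <- !zero
  values <- sweep(sweep(x[, keep, drop = FALSE], 2L, center[keep]), 2L,
                  scale_[keep], "/")
  out <- list(values = values, center = center[keep], scale = scale_[keep],
              dropped = dropped, fit_on = fit_on, sd_type = sd_type)
  class(out) <- "scaled_features"
  out
}

#' Apply stored scaling parameters to new samples
#'
#' @param scaling a \code{scaled_features} object.
#' @param newdata samples x features matrix containing at least the scaled
#'   feature columns.
#' @return matrix of transformed values.
#' @export
apply_scaling <- function(scaling, newdata) {
  stopifnot(inherits(scaling, "scaled_features"))
  x <- as.matrix(newdata)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  feats <- names(scaling$center)
  if (!all(feats %in% colnames(x))) {
    stop("newdata lacks scaled feature(s): ",
         paste(setdiff(feats, colnames(x)), collapse = ", "))
  }
  sweep(sweep(x[, feats, drop = FALSE], 2L, scaling$center), 2L,
        scaling$scale, "/")
}

#' Principal component analysis of scaled features
#'
#' Thin wrapper around [stats::prcomp()] (no re-centering/re-scaling: input
#' is expected to be z-scored already) returning scores, orthonormal
#' loadings and variance fractions ordered by decreasing variance.
#'
#' @param scaled a \code{scaled_features} object or numeric matrix
#'   (samples x features).
#' @return list of class \code{"glyco_pca"}: \code{scores}, \code{loadings},
#'   \code{variance_fraction}, \code{sdev}.
#' @export
pca_transform <- function(scaled) {
  x <- if (inherits(scaled, "scaled_features")) scaled$values else
    as.matrix(scaled)
  if (nrow(x) < 2L) stop("PCA needs at least 2 samples")
  if (ncol(x) < 2L) stop("PCA needs at least 2 features")
  pc <- stats::prcomp(x, center = FALSE, scale. = FALSE)
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  out <- list(scores = pc$x, loadings = pc$rotation,
              variance_fraction = vf, sdev = pc$sdev)
  class(out) <- "glyco_pca"
  out
}

#' @export
print.glyco_pca <- function(x, ...) {
  k <- min(5L, length(x$variance_fraction))
  cat("PCA:", nrow(x$scores), "samples,", ncol(x$loadings), "components\n")
  cat("  variance fractions:",
      paste(sprintf("%.3f", x$variance_fraction[seq_len(k)]), collapse = " "),
      if (length(x$variance_fraction) > k) "...", "\n")
  invisible(x)
}

#' Fit a (possibly LASSO-regularized) logistic classifier
#'
#' Binomial logistic regression for two classes, multinomial for three
#' (probability scores across control/NASH/HCC). With
#' \code{penalty = "lasso"} the L1 strength is chosen by inner k-fold
#' cross-validation (\code{cv.glmnet}) when not supplied, so some
#' coefficients may be exactly zero. Unpenalized fits use [stats::glm()]
#' (binomial) or glmnet at a negligible penalty (multinomial).
#'
#' @param x numeric matrix, samples x features (scale first; see
#'   [scale_features()]).
#' @param y class labels (factor or character); 2 or 3 levels.
#' @param penalty \code{"lasso"} or \code{"none"}.
#' @param lambda optional fixed L1 strength (skips the inner CV).
#' @param nfolds folds of the inner CV choosing lambda.
#' @param seed integer seed for the inner CV fold assignment.
#' @param balance_classes weight observations inversely to class frequency
#'   (default TRUE). Keeps the intercept free of class-imbalance information,
#'   which matters under leave-one-out evaluation: an unweighted
#'   intercept-only model predicts the training class proportion, which is
#'   anti-correlated with the held-out label.
#' @return list of class \code{"glyco_model"}: \code{coefficients} (matrix
#'   features+intercept x classes for multinomial, single column for
#'   binomial), \code{classes}, \code{penalty}, \code{lambda}.
#' @export
fit_logistic <- function(x, y, penalty = c("lasso", "none"), lambda = NULL,
                         nfolds = 5L, seed = 1L, balance_classes = TRUE) {
  penalty <- match.arg(penalty)
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  y <- factor(y)
  if (nlevels(y) < 2L) stop("need at least 2 classes")
  if (any(table(y) < 2L)) stop("every class needs >= 2 samples")
  fam <- if (nlevels(y) == 2L) "binomial" else "multinomial"
  w <- if (balance_classes) {
    tab <- table(y)
    as.numeric(length(y) / (nlevels(y) * tab[y]))
  } else rep(1, length(y))

  if (penalty == "none" && fam == "binomial") {
    fit <- stats::glm.fit(cbind(1, x), as.numeric(y) - 1, weights = w,
                          family = stats::binomial())
    cf <- fit$coefficients
    if (anyNA(cf)) {
      warning(sum(is.na(cf)), " aliased coefficient(s) set to 0 ",
              "(rank-deficient design; consider penalty = \"lasso\")")
      cf[is.na(cf)] <- 0
    }
    co <- matrix(cf, ncol = 1,
                 dimnames = list(c("(Intercept)", colnames(x)), levels(y)[2L]))
    model <- list(coefficients = co, classes = levels(y), penalty = penalty,
                  lambda = 0, family = fam)
  } else {
    if (is.null(lambda)) {
      if (penalty == "none") {
        lambda <- 1e-6
      } else {
        set.seed(seed)
        cv <- suppressWarnings(glmnet::cv.glmnet(x, y, family = fam, alpha = 1,
                                weights = w, nfolds = max(3L, nfolds),
                                type.measure = "deviance"))
        lambda <- cv$lambda.min
      }
    }
    fit <- suppressWarnings(
      glmnet::glmnet(x, y, family = fam, alpha = 1, weights = w,
                     lambda = lambda))
    cf <- glmnet::coef.glmnet(fit)
    if (fam == "binomial") {
      co <- matrix(as.numeric(cf), ncol = 1,
                   dimnames = list(rownames(cf), levels(y)[2L]))
    } else {
      co <- do.call(cbind, lapply(cf, function(m) as.numeric(m)))
      dimnames(co) <- list(rownames(cf[[1L]]), names(cf))
    }
    model <- list(coefficients = co, classes = levels(y), penalty = penalty,
                  lambda = lambda, family = fam)
  }
  class(model) <- "glyco_model"
  model
}

#' @export
print.glyco_model <- function(x, ...) {
  nz <- sum(x$coefficients[-1L, , drop = FALSE] != 0)
  cat("Logistic classifier (", x$family, ", penalty = ", x$penalty,
      ", lambda = ", signif(x$lambda, 3), ")\n", sep = "")
  cat("  classes:", paste(x$classes, collapse = ", "), "\n")
  cat("  nonzero feature coefficients:", nz, "of",
      length(x$coefficients[-1L, , drop = FALSE]), "\n")
  invisible(x)
}

#' @export
coef.glyco_model <- function(object, ...) object$coefficients

#' Predict class probabilities from a fitted classifier
#'
#' @param object a \code{glyco_model}.
#' @param newx samples x features matrix on the scale the model was fit on.
#' @param type \code{"prob"} (class probabilities) or \code{"class"}.
#' @param ... unused.
#' @return matrix of probabilities (samples x classes) or character vector
#'   of predicted classes.
#' @export
predict.glyco_model <- function(object, newx, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  x <- as.matrix(newx)
  feats <- rownames(object$coefficients)[-1L]
  if (!is.null(colnames(x)) && all(feats %in% colnames(x))) {
    x <- x[, feats, drop = FALSE]
  } else if (ncol(x) != length(feats)) {
    stop("newx must carry the model's ", length(feats), " features")
  }
  eta <- cbind(1, x) %*% object$coefficients
  if (object$family == "binomial") {
    p2 <- 1 / (1 + exp(-eta[, 1L]))
    prob <- cbind(1 - p2, p2)
    colnames(prob) <- object$classes
  } else {
    ex <- exp(eta - apply(eta, 1L, max))
    prob <- ex / rowSums(ex)
    colnames(prob) <- object$classes
  }
  rownames(prob) <- rownames(x)
  if (type == "prob") prob
  else object$classes[max.col(prob)]
}

#' Area under the ROC curve via midranks
#'
#' AUROC equals the Mann-Whitney U statistic normalized by
#' \eqn{n_1 n_0}: the probability that a random positive scores above a
#' random negative, with ties counting one half. The returned curve is the
#' full empirical ROC (one point per distinct threshold).
#'
#' @param scores numeric scores, larger = more positive.
#' @param labels binary labels; the positive class is the larger level of
#'   \code{factor(labels)} (or \code{TRUE}/1).
#' @return list of class \code{"roc_curve"}: \code{auc}, \code{curve} (data
#'   frame with \code{threshold}, \code{fpr}, \code{tpr}), \code{n_pos},
#'   \code{n_neg}.
#' @examples
#' roc_auc(c(0.9, 0.8), c(1, 0))$auc  # 1
#' @export
roc_auc <- function(scores, labels) {
  y <- factor(labels)
  if (nlevels(y) != 2L) {
    stop("labels must contain exactly 2 classes, got ", nlevels(y))
  }
  pos <- y == levels(y)[2L]
  n1 <- sum(pos); n0 <- sum(!pos)
  r <- rank(scores)                     # midranks handle ties
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(scores[pos] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[!pos] >= t), numeric(1))
  curve <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr),
                      tpr = c(0, tpr))
  out <- list(auc = auc, curve = curve, n_pos = n1, n_neg = n0)
  class(out) <- "roc_curve"
  out
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC: AUROC = %.3f (%d positives, %d negatives)\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, ...) {
  graphics::plot(x$curve$fpr, x$curve$tpr, type = "s",
                 xlab = "false positive rate", ylab = "true positive rate",
                 xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Leave-one-out cross-validated classifier evaluation
#'
#' For each sample in turn: scaling is refit on the remaining samples, a
#' classifier (LASSO by default, with the L1 strength chosen by inner k-fold
#' CV inside the training fold — nested, so no selection leakage) is trained
#' without the held-out sample, and its probability for that sample is
#' recorded. The out-of-fold probabilities give the test AUROC; the train
#' AUROC comes from one full-data fit.
#'
#' @param features samples x features matrix (unscaled; scaling is refit per
#'   fold).
#' @param labels binary class labels.
#' @param penalty,nfolds passed to [fit_logistic()].
#' @param nested if \code{FALSE}, lambda is chosen once on the full data and
#'   reused in every fold (faster, slightly optimistic).
#' @param seed integer seed controlling inner-CV fold assignment.
#' @return list of class \code{"cv_report"}: \code{prob} (out-of-fold
#'   probability of the positive class per sample), \code{auc_test},
#'   \code{auc_train}, \code{roc_test}, \code{roc_train}, \code{labels},
#'   \code{flagged} (folds whose training set lost a class).
#' @export
loocv_evaluate <- function(features, labels, penalty = "lasso",
                           nfolds = 5L, nested = TRUE, seed = 1L) {
  x <- as.matrix(features)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  y <- factor(labels)
  n <- nrow(x)
  if (n < 4L) stop("LOOCV needs at least 4 samples")
  if (nlevels(y) != 2L || any(table(y) < 2L)) {
    stop("need two classes with >= 2 samples each")
  }

  lambda_fixed <- NULL
  if (!nested && penalty == "lasso") {
    sc_all <- suppressWarnings(scale_features(x))
    set.seed(seed)
    cv <- glmnet::cv.glmnet(sc_all$values, y, family = "binomial", alpha = 1,
                            nfolds = max(3L, nfolds))
    lambda_fixed <- cv$lambda.min
  }

  prob <- stats::setNames(rep(NA_real_, n),
                          rownames(x) %||% as.character(seq_len(n)))
  flagged <- integer(0)
  for (i in seq_len(n)) {
    ytr <- y[-i]
    if (nlevels(droplevels(ytr)) < 2L) {
      flagged <- c(flagged, i)
      next
    }
    sc <- suppressWarnings(scale_features(x[-i, , drop = FALSE]))
    xtr <- sc$values
    model <- fit_logistic(xtr, ytr, penalty = penalty, lambda = lambda_fixed,
                          nfolds = nfolds, seed = seed + i)
    xte <- apply_scaling(sc, x[i, , drop = FALSE])
    prob[i] <- predict(model, xte)[, levels(y)[2L]]
  }

  sc_full <- suppressWarnings(scale_features(x))
  model_full <- fit_logistic(sc_full$values, y, penalty = penalty,
                             lambda = lambda_fixed, nfolds = nfolds,
                             seed = seed)
  prob_train <- predict(model_full, sc_full$values)[, levels(y)[2L]]

  ok <- !is.na(prob)
  if (!any(ok)) stop("no out-of-fold predictions could be produced")
  out <- list(
    prob = prob,
    labels = y,
    auc_test = roc_auc(prob[ok], y[ok])$auc,
    auc_train = roc_auc(prob_train, y)$auc,
    roc_test = roc_auc(prob[ok], y[ok]),
    roc_train = roc_auc(prob_train, y),
    model = model_full,
    flagged = flagged,
    coverage = mean(ok)
  )
  class(out) <- "cv_report"
  out
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("LOOCV: train AUROC = %.3f, test (out-of-fold) AUROC = %.3f\n",
              x$auc_train, x$auc_test))
  cat(sprintf("  %d/%d samples with out-of-fold predictions\n",
              sum(!is.na(x$prob)), length(x$prob)))
  if (length(x$flagged)) cat("  flagged folds:", length(x$flagged), "\n")
  invisible(x)
}

#' @export
plot.cv_report <- function(x, ...) {
  plot(x$roc_test, main = sprintf("LOOCV ROC (test AUROC %.2f)", x$auc_test),
       ...)
  graphics::lines(x$roc_train$curve$fpr, x$roc_train$curve$tpr, type = "s",
                  col = "grey50")
  invisible(x)
}
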