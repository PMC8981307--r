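test_that("z-scaling uses population SD and round-trips held-out samples", {
  sc <- scale_features(matrix(c(1, 2, 3), 3, 1))
  expect_equal(unname(sc$values[, 1]), c(-1, 0, 1) * sqrt(3 / 2),
               tolerance = 1e-6)  # population SD: -1.225, 0, 1.225
  expect_equal(unname(colMeans(sc$values)), 0, tolerance = 1e-9)
  expect_equal(unname(sqrt(colMeans(sc$values^2))), 1, tolerance = 1e-9)

  # scaling an already-scaled column is the identity
  sc2 <- scale_features(sc$values)
  expect_equal(sc2$values, sc$values, tolerance = 1e-9)

  # held-out rows transformed with stored fitting-set parameters
  x <- matrix(c(1, 2, 3, 10), 4, 1)
  sc3 <- scale_features(x, fit_on = 1:3)
  expect_equal(unname(sc3$values[4, 1]), (10 - 2) / sqrt(2 / 3))
  expect_equal(apply_scaling(sc3, x), sc3$values)
})

test_that("constant features are dropped with warning; all-constant is an error", {
  x <- cbind(a = c(1, 1, 1), b = c(1, 2, 3))
  expect_warning(sc <- scale_features(x), "constant feature")
  expect_equal(colnames(sc$values), "b")
  expect_equal(sc$dropped, "a")
  expect_error(suppressWarnings(scale_features(cbind(a = c(2, 2, 2)))),
               "all features are constant")
})

test_that("PCA components are ordered, orthonormal and reconstruct the input", {
  set.seed(5)
  x <- matrix(rnorm(20 * 6), 20, 6)
  sc <- scale_features(x)
  pc <- pca_transform(sc)
  expect_true(all(diff(pc$sdev) <= 1e-12))
  gram <- crossprod(pc$loadings)
  expect_equal(gram, diag(ncol(gram)), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(sum(pc$variance_fraction), 1, tolerance = 1e-9)
  recon <- pc$scores %*% t(pc$loadings)
  expect_equal(recon, sc$values, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("PCA on z-scored features equals eigen-decomposition of the correlation matrix", {
  set.seed(6)
  x <- matrix(rnorm(30 * 4), 30, 4)
  sc <- scale_features(x, sd_type = "sample")
  pc <- pca_transform(sc)
  ev <- eigen(cor(x))$values
  expect_equal(pc$sdev^2, ev, tolerance = 1e-8)
  # perfectly correlated pair: first component captures ~all variance
  y <- cbind(rnorm(15))
  pc2 <- pca_transform(cbind(y, 2 * y))
  expect_gt(pc2$variance_fraction[1], 0.999)
})

test_that("unpenalized logistic separates a separable toy set; heavy lasso zeroes everything", {
  x <- cbind(f1 = c(-2, -1.5, -1, 1, 1.5, 2), f2 = rnorm(6))
  y <- rep(c("a", "b"), each = 3)
  m <- fit_logistic(x, y, penalty = "none")
  expect_equal(unname(predict(m, x, type = "class")), y)

  m2 <- fit_logistic(x, y, penalty = "lasso", lambda = 100)
  expect_true(all(coef(m2)[-1, ] == 0))
  p <- predict(m2, x)
  expect_equal(unname(p[, "b"]), rep(0.5, 6), tolerance = 1e-6)
})

test_that("lasso suppresses most noise features at moderate n", {
  frac_zero <- vapply(1:10, function(s) {
    set.seed(800 + s)
    n <- 60
    informative <- matrix(rnorm(n * 3), n, 3)
    y <- factor(ifelse(rowSums(informative) + rnorm(n, 0, 0.5) > 0, "b", "a"))
    noise <- matrix(rnorm(n * 50), n, 50)
    x <- cbind(informative, noise)
    colnames(x) <- paste0("f", 1:53)
    m <- fit_logistic(scale_features(x)$values, y, penalty = "lasso",
                      seed = s)
    mean(coef(m)[paste0("f", 4:53), ] == 0)
  }, numeric(1))
  expect_true(mean(frac_zero >= 0.5) >= 0.9)
})

test_that("AUROC matches brute-force pair counting and handles ties", {
  expect_equal(roc_auc(c(0.9, 0.8), c(1, 0))$auc, 1)
  expect_equal(roc_auc(rep(0.5, 10), rep(c(0, 1), 5))$auc, 0.5)
  set.seed(7)
  for (i in 1:50) {
    scores <- round(runif(20), 2)  # rounding forces ties
    labels <- sample(c(0, 1), 20, replace = TRUE)
    if (length(unique(labels)) < 2) next
    r <- roc_auc(scores, labels)
    expect_equal(r$auc, auc_oracle(scores, labels), tolerance = 1e-12)
    # complement symmetry
    expect_equal(r$auc + roc_auc(-scores, labels)$auc, 1, tolerance = 1e-12)
  }
  expect_error(roc_auc(1:3, c(1, 1, 1)), "2 classes")
})

test_that("ROC curve starts at (0,0), ends at (1,1) and is monotone", {
  set.seed(8)
  r <- roc_auc(rnorm(30), sample(c(0, 1), 30, replace = TRUE))
  expect_equal(r$curve$fpr[1], 0)
  expect_equal(r$curve$tpr[1], 0)
  expect_equal(r$curve$fpr[nrow(r$curve)], 1)
  expect_equal(r$curve$tpr[nrow(r$curve)], 1)
  expect_true(all(diff(r$curve$fpr) >= 0) && all(diff(r$curve$tpr) >= 0))
})

test_that("LOOCV separates separable classes perfectly and covers every sample", {
  set.seed(9)
  n <- 20
  x <- cbind(f1 = c(rnorm(n / 2, -4), rnorm(n / 2, 4)), f2 = rnorm(n))
  y <- rep(c("a", "b"), each = n / 2)
  cv <- loocv_evaluate(x, y, penalty = "none", seed = 1)
  expect_equal(cv$auc_test, 1)
  expect_equal(cv$auc_train, 1)
  expect_equal(sum(!is.na(cv$prob)), n)
})

test_that("LOOCV holds the test sample fully out of training", {
  set.seed(10)
  n <- 16
  x <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, paste0("f", 1:3)))
  y <- rep(c("a", "b"), each = n / 2)
  cv1 <- loocv_evaluate(x, y, penalty = "none", seed = 3)
  # altering sample 1's features must leave its own fold's training
  # statistics untouched: the fold-1 scaling and model are recomputed from
  # x[-1], which is identical in both datasets
  x2 <- x
  x2[1, ] <- x2[1, ] + 100
  cv2 <- loocv_evaluate(x2, y, penalty = "none", seed = 3)
  sc_wo1 <- scale_features(x[-1, , drop = FALSE])
  expect_identical(sc_wo1$center, scale_features(x2[-1, , drop = FALSE])$center)
  m1 <- fit_logistic(sc_wo1$values, y[-1], penalty = "none")
  # sample 1's out-of-fold probability in both runs is this fold model
  # applied to its (old/new) features — training never saw sample 1
  expect_equal(cv1$prob[[1]],
               unname(predict(m1, apply_scaling(sc_wo1, x[1, , drop = FALSE]))[, "b"]),
               tolerance = 1e-9)
  expect_equal(cv2$prob[[1]],
               unname(predict(m1, apply_scaling(sc_wo1, x2[1, , drop = FALSE]))[, "b"]),
               tolerance = 1e-9)
})

test_that("label permutation gives chance-level out-of-fold AUROC", {
  set.seed(12)
  n <- 40
  x <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("f", 1:5)))
  aucs <- vapply(1:8, function(s) {
    set.seed(1000 + s)
    y <- sample(rep(c("a", "b"), each = n / 2))
    loocv_evaluate(x, y, penalty = "none", seed = s)$auc_test
  }, numeric(1))
  expect_gt(mean(aucs), 0.32)
  expect_lt(mean(aucs), 0.68)
})
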