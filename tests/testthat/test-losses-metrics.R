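test_that("balanced classes get unit weights", {
  cw <- class_weights(c(a = 50, b = 50))
  expect_equal(unname(cw$weights), c(1, 1))
})

test_that("severely imbalanced clinical grade counts reproduce known weights", {
  cw <- class_weights(c(icdr0 = 15210, icdr1 = 162, icdr2 = 310,
                        icdr3 = 190, icdr4 = 394))
  expect_equal(cw$n_total, 16266)
  expect_equal(unname(cw$weights["icdr0"]), 16266 / (5 * 15210))
  expect_equal(unname(cw$weights["icdr0"]), 0.2139, tolerance = 1e-3)
  expect_equal(unname(cw$weights["icdr1"]), 20.082, tolerance = 1e-3)
})

test_that("weights conserve the total count for arbitrary count maps", {
  set.seed(17)
  for (i in 1:100) {
    k <- sample(2:8, 1)
    counts <- stats::setNames(sample(1:5000, k), paste0("c", 1:k))
    cw <- class_weights(counts)
    expect_equal(sum(counts * cw$weights), sum(counts), tolerance = 1e-9)
  }
  expect_error(class_weights(c(a = 10, b = 0)), "'b'")
})

random_probs <- function(n, k) {
  p <- matrix(stats::rexp(n * k), n)
  p <- p / rowSums(p)
  colnames(p) <- paste0("c", seq_len(k))
  p
}

test_that("focal loss at gamma 0 with unit weights is cross-entropy", {
  set.seed(18)
  p <- random_probs(50, 4)
  y <- paste0("c", sample(4, 50, replace = TRUE))
  ce <- -mean(log(p[cbind(seq_len(50), match(y, colnames(p)))]))
  expect_equal(focal_loss(p, y, gamma = 0), ce, tolerance = 1e-10)
})

test_that("focal loss hand-evaluates on a single coin-flip prediction", {
  p <- matrix(c(0.5, 0.5), 1, dimnames = list(NULL, c("a", "b")))
  expect_equal(focal_loss(p, "a", gamma = 0), -log(0.5), tolerance = 1e-12)
  expect_equal(focal_loss(p, "a", gamma = 0), 0.6931, tolerance = 1e-4)
})

test_that("focal loss is non-increasing in gamma", {
  set.seed(19)
  p <- random_probs(30, 3)
  y <- paste0("c", sample(3, 30, replace = TRUE))
  losses <- sapply(seq(0, 5, by = 0.5), function(g) focal_loss(p, y, gamma = g))
  expect_true(all(diff(losses) <= 1e-12))
  expect_error(focal_loss(p, rep("zz", 30)), "zz")
})

test_that("L2 regularisation matches its closed form and bounds", {
  params <- list(w_W = matrix(2), w_b = matrix(10))
  expect_equal(l2_regularized_loss(1.5, params, 0), 1.5)
  expect_equal(l2_regularized_loss(0, params, 1), 2)       # (1/2) * 2^2
  expect_equal(l2_regularized_loss(0, params, 1, include_bias = TRUE), 52)
  set.seed(20)
  for (i in 1:20) {
    p <- list(a_W = matrix(rnorm(4), 2), b_b = matrix(rnorm(2), 1))
    l <- runif(1, 0, 3)
    expect_gte(l2_regularized_loss(l, p, runif(1, 0, 2)), l)
  }
  expect_error(l2_regularized_loss(1, params, -0.1), "strength")
})

test_that("perfect predictions score perfectly on every metric", {
  y <- c("a", "b", "a", "c", "b")
  p <- ddfusion:::onehot(y, c("a", "b", "c"))
  colnames(p) <- c("a", "b", "c")
  m <- classification_metrics(p, y)
  expect_equal(m$accuracy, 1)
  expect_equal(m$f1_macro, 1)
  expect_equal(m$f1_weighted, 1)
  expect_equal(m$auc_macro, 1)
  r <- regression_metrics(1:5, 1:5)
  expect_equal(r$r2, 1)
  expect_equal(r$mae + r$rmse + r$smape, 0)
})

test_that("sMAPE hand-evaluates and stays in its bounds", {
  expect_equal(regression_metrics(50, 100)$smape, 100 * (2 * 50 / 150),
               tolerance = 1e-12)
  expect_equal(regression_metrics(50, 100)$smape, 66.67, tolerance = 1e-2)
  expect_equal(regression_metrics(0, 0)$smape, 0)       # 0/0 point defined as 0
  expect_equal(regression_metrics(5, -5)$smape, 200)    # upper bound
})

test_that("a constant mean predictor has zero R-squared", {
  y <- c(2, 4, 6, 8)
  expect_equal(regression_metrics(rep(mean(y), 4), y)$r2, 0)
  expect_true(is.na(regression_metrics(c(1, 1), c(3, 3))$r2))
})

test_that("metrics agree with independent reference implementations", {
  set.seed(21)
  for (i in 1:100) {
    n <- sample(20:60, 1); k <- sample(2:4, 1)
    p <- random_probs(n, k)
    y <- paste0("c", sample(k, n, replace = TRUE))
    if (length(unique(y)) < k) next
    m <- classification_metrics(p, y)
    pred <- colnames(p)[apply(p, 1, which.max)]
    expect_equal(m$accuracy, sum(pred == y) / n, tolerance = 1e-8)
    f1s <- sapply(colnames(p), function(cl) {
      prec <- sum(pred == cl & y == cl) / max(sum(pred == cl), 1)
      rec <- sum(pred == cl & y == cl) / sum(y == cl)
      if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    })
    expect_equal(m$f1_macro, mean(f1s), tolerance = 1e-8)
    supp <- table(factor(y, colnames(p)))
    expect_equal(m$f1_weighted, sum(f1s * supp) / n, tolerance = 1e-8)
    # rank-statistic AUC, one-vs-rest
    aucs <- sapply(colnames(p), function(cl) {
      pos <- p[y == cl, cl]; neg <- p[y != cl, cl]
      (mean(outer(pos, neg, ">")) + 0.5 * mean(outer(pos, neg, "==")))
    })
    expect_equal(m$auc_macro, mean(aucs), tolerance = 1e-8)
    yy <- rnorm(n); pp <- rnorm(n)
    r <- regression_metrics(pp, yy)
    expect_equal(r$mae, sum(abs(pp - yy)) / n, tolerance = 1e-8)
    expect_equal(r$rmse, sqrt(sum((pp - yy)^2) / n), tolerance = 1e-8)
    expect_equal(r$r2, 1 - sum((pp - yy)^2) / sum((yy - mean(yy))^2),
                 tolerance = 1e-8)
    expect_equal(r$smape, 100 / n * sum(2 * abs(pp - yy) /
                                          (abs(pp) + abs(yy))),
                 tolerance = 1e-8)
  }
})

test_that("AUC is undefined, not zero, when a class is absent", {
  p <- random_probs(10, 3)
  y <- rep(c("c1", "c2"), 5)
  m <- classification_metrics(p, y)
  expect_true(is.na(m$auc_macro))
  expect_false(identical(m$auc_macro, 0))
})
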