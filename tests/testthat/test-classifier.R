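test_that("the 1-D two-point toy recovers the analytic hard-margin solution", {
  x <- matrix(c(-1, 1), ncol = 1)
  m <- linsvm(x, c("neg", "pos"), C = 1000)
  expect_equal(m$weights, 1, tolerance = 1e-6)
  expect_equal(m$bias, 0, tolerance = 1e-6)
  # both margins exactly 1
  expect_equal(decision_values(m, x), c(-1, 1), tolerance = 1e-6)
  # and w.x + b evaluated elsewhere
  expect_equal(decision_values(m, matrix(2)), 2, tolerance = 1e-6)
})

test_that("duplicating every example leaves the decision function unchanged", {
  set.seed(4)
  x <- matrix(rnorm(20), 10, 2)
  y <- rep(c("a", "b"), 5)
  m1 <- linsvm(x, y, C = 1)
  m2 <- linsvm(rbind(x, x), c(y, y), C = 0.5)  # 2n examples at half penalty
  # same objective => same hyperplane
  expect_equal(m2$weights, m1$weights, tolerance = 1e-5)
  expect_equal(m2$bias, m1$bias, tolerance = 1e-5)
})

test_that("decision values are linear and respect the sign convention", {
  m <- structure(list(weights = c(0, 0), bias = 0,
                      class_labels = c("a", "b"), center = NULL,
                      scale = NULL),
                 class = "linsvm")
  x <- matrix(rnorm(6), 3, 2)
  expect_equal(decision_values(m, x), c(0, 0, 0))
  # sign(0) predicts the positive class
  expect_equal(unname(predict(m, x)), rep("b", 3))
  m2 <- m; m2$weights <- c(1, -2); m2$bias <- 0.5
  m3 <- m2; m3$weights <- -m2$weights; m3$bias <- -m2$bias
  expect_equal(decision_values(m3, x), -decision_values(m2, x))
  expect_error(decision_values(m2, matrix(0, 2, 3)), "match")
})

test_that("degenerate training inputs are rejected", {
  x <- matrix(rnorm(10), 5, 2)
  expect_error(linsvm(x, rep("a", 5)), "two classes")
  x[2, 1] <- NA
  expect_error(linsvm(x, c("a", "b", "a", "b", "a")), "finite")
  expect_error(linsvm(matrix(rnorm(10), 5, 2), c("a", "b", "a", "b", "a"),
                      C = -1), "C must be")
})

test_that("C selection maximizes inner balanced accuracy with low-C tie-break", {
  # a single candidate is returned without any fold computation
  expect_equal(select_C(matrix(0, 2, 1), c("a", "b"), c_grid = 5), 5)
  # perfectly separable data: every C is perfect, smallest wins the tie
  set.seed(8)
  x <- cbind(c(rnorm(20, -5), rnorm(20, 5)), rnorm(40))
  y <- rep(c("lo", "hi"), each = 20)
  expect_equal(select_C(x, y, c_grid = c(0.1, 1, 10), inner_folds = 5,
                        seed = 2), 0.1)
  # selection agrees with an independent re-evaluation of the inner folds
  set.seed(9)
  x <- matrix(rnorm(60 * 3), 60, 3)
  y <- factor(ifelse(x[, 1] + rnorm(60, sd = 2) > 0, "b", "a"),
              levels = c("a", "b"))
  grid <- c(0.01, 1)
  fold <- gmpool:::stratified_folds(y, 4L, seed = 31)
  balacc <- vapply(grid, function(C) {
    mean(vapply(1:4, function(f) {
      m <- linsvm(x[fold != f, ], y[fold != f], C = C)
      pred <- predict(m, x[fold == f, ])
      yt <- as.character(y[fold == f])
      mean(vapply(levels(y), function(cl)
        sum(pred == cl & yt == cl) / sum(yt == cl), numeric(1L)),
        na.rm = TRUE)
    }, numeric(1L)))
  }, numeric(1L))
  want <- grid[which.max(balacc)]
  expect_equal(select_C(x, y, c_grid = grid, inner_folds = 4L, seed = 31),
               want)
  expect_error(select_C(x[1:6, ], y[c(1, 1, 1, 1, 1, 31)], c_grid = grid,
                        inner_folds = 5L, seed = 1), "class size")
})

test_that("accuracy is invariant to a consistent feature permutation", {
  set.seed(12)
  x <- matrix(rnorm(30 * 4), 30, 4)
  y <- ifelse(x[, 2] > 0, "p", "n")
  if (length(unique(y)) == 2L) {
    xt <- matrix(rnorm(40), 10, 4)
    m <- linsvm(x, y, C = 1)
    perm <- c(3, 1, 4, 2)
    mp <- linsvm(x[, perm], y, C = 1)
    expect_equal(predict(mp, xt[, perm]), predict(m, xt))
  }
})

test_that("the Gram-space fast path equals the explicit-feature fit", {
  set.seed(19)
  X <- matrix(rnorm(18 * 40), 18, 40)
  y <- factor(rep(c("a", "b"), 9), levels = c("a", "b"))
  m <- linsvm(X, y, C = 2)
  dvf <- gmpool:::gram_linsvm(tcrossprod(X), y, C = 2)
  expect_equal(dvf(tcrossprod(X, X)), decision_values(m, X),
               tolerance = 1e-8)
})
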