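test_that("fitting stores exemplars verbatim with class bookkeeping", {
  set.seed(1)
  x <- matrix(stats::rnorm(10 * 22), 10, 22,
              dimnames = list(NULL, ecg_feature_names()))
  labels <- rep(c(0L, 1L), each = 5L)
  m <- pnn_fit(x, delta = 0.7, labels = labels)
  expect_identical(m$d, 22L)
  expect_identical(m$class_counts, c(5L, 5L))
  expect_identical(m$classes, c(0L, 1L))
  expect_equal(m$x, x)
  m2 <- pnn_fit(x, delta = 0.7, labels = labels)
  expect_identical(m, m2)
  expect_error(pnn_fit(x, delta = 0, labels = labels), "positive")
  expect_error(pnn_fit(x, delta = 1, labels = labels[1:5]), "differ")
})

test_that("the 1-D score ratio matches the hand-evaluated kernel", {
  m <- pnn_fit(matrix(c(0, 1), 2, 1), delta = 0.5, labels = c(0L, 1L))
  g <- pnn_class_scores(m, 0.25)
  # exp(-(0.25^2)/0.25) / exp(-(0.75^2)/0.25) = exp(2)
  expect_equal(unname(g["0"] / g["1"]), exp(2), tolerance = 1e-10)
  expect_equal(pnn_classify(m, 0.25), 0L)
  expect_error(pnn_class_scores(m, c(1, 2)), "attributes")
})

test_that("exact ties go to the earliest class", {
  m <- pnn_fit(matrix(c(0, 1), 2, 1), delta = 0.5, labels = c(1L, 0L))
  # classes sorted ascending: midpoint 0.5 is equidistant -> class 0
  expect_equal(pnn_classify(m, 0.5), 0L)
})

test_that("classification ignores the kernel normalisation constant", {
  set.seed(4)
  x <- matrix(stats::rnorm(30 * 3), 30, 3)
  labels <- sample(letters[1:3], 30, replace = TRUE)
  m <- pnn_fit(x, delta = 0.8, labels = labels)
  pts <- matrix(stats::rnorm(20 * 3), 20, 3)
  for (k in seq_len(nrow(pts))) {
    with_const <- pnn_class_scores(m, pts[k, ], normalized = TRUE)
    without <- pnn_class_scores(m, pts[k, ], normalized = FALSE)
    expect_equal(names(which.max(with_const)), names(which.max(without)))
    expect_equal(pnn_classify(m, pts[k, ]),
                 m$classes[which.max(with_const)])
  }
})

test_that("delta -> 0 reduces the PNN to 1-nearest-neighbour", {
  set.seed(12)
  train_x <- matrix(stats::rnorm(50 * 2), 50, 2)
  train_y <- sample(0:4, 50, replace = TRUE)
  test_x <- matrix(stats::rnorm(50 * 2), 50, 2)
  m <- pnn_fit(train_x, delta = 1e-4, labels = train_y)
  expect_identical(pnn_classify(m, test_x),
                   as.integer(nn_oracle(train_x, train_y, test_x)))
})

test_that("delta -> Inf predicts the class of smallest mean squared distance", {
  # the summation layer averages within a class, so the wide-kernel limit
  # selects the class whose exemplars are closest on average, regardless of
  # how many exemplars it holds
  set.seed(13)
  train_x <- matrix(c(stats::rnorm(20, 0), stats::rnorm(4, 3)), ncol = 1)
  train_y <- rep(c("far", "near"), c(20, 4))
  m <- pnn_fit(train_x, delta = 1e6, labels = train_y)
  test_x <- matrix(seq(2, 4, by = 0.5), ncol = 1)
  oracle <- apply(test_x, 1, function(p) {
    msd <- tapply(as.numeric((train_x - p)^2), train_y, mean)
    names(msd)[which.min(msd)]
  })
  expect_identical(pnn_classify(m, test_x), unname(oracle))
})

test_that("well-separated Gaussian classes are classified almost perfectly", {
  set.seed(21)
  centers <- rbind(c(0, 0), c(4, 0))
  gen <- function(n) {
    cls <- rep(1:2, each = n / 2)
    list(x = centers[cls, ] + matrix(stats::rnorm(n * 2, sd = 0.5), n, 2),
         y = cls)
  }
  train <- gen(200)
  test <- gen(200)
  for (delta in c(0.1, 0.5, 2)) {
    m <- pnn_fit(train$x, delta = delta, labels = train$y)
    acc <- mean(pnn_classify(m, test$x) == test$y)
    expect_gte(acc, 0.99)
  }
})

test_that("evaluation metrics follow their definitions", {
  # exemplars placed on the test points force predictions (0, 1, 0)
  m <- pnn_fit(matrix(c(1, 2, 3), 3, 1), delta = 1e-3,
               labels = c(0L, 1L, 0L))
  test <- data.frame(v = c(1, 2, 3), label = c(0L, 1L, 2L))
  names(test)[1] <- "v"
  ev_mse <- pnn_evaluate(m, test, metric = "eq4_mse")
  ev_mis <- pnn_evaluate(m, test, metric = "misclassification")
  expect_equal(ev_mse$error, 4 / 3)
  expect_equal(ev_mis$error, 1 / 3)
  expect_equal(ev_mse$n, 3L)
  perfect <- data.frame(v = c(1, 2), label = c(0L, 1L))
  expect_equal(pnn_evaluate(m, perfect, metric = "eq4_mse")$error, 0)
  expect_error(pnn_evaluate(m, perfect[0, ]), "empty")
})

test_that("squared-label error dominates the misclassification rate", {
  set.seed(31)
  x <- matrix(stats::rnorm(40), 40, 1)
  m <- pnn_fit(x, delta = 0.5, labels = sample(0:3, 40, replace = TRUE))
  test <- data.frame(v = stats::rnorm(25),
                     label = sample(0:3, 25, replace = TRUE))
  mse <- pnn_evaluate(m, test, metric = "eq4_mse")$error
  mis <- pnn_evaluate(m, test, metric = "misclassification")$error
  expect_gte(mse, mis)
})

test_that("smoothing-factor tuning is elitist and beats nothing on trivial data", {
  set.seed(41)
  train <- data.frame(v = stats::rnorm(10), label = rep(0L, 10))
  val <- data.frame(v = stats::rnorm(5), label = rep(0L, 5))
  res <- tune_smoothing_factor(train, val,
                               woa_config(bounds = c(0.01, 10), pop_size = 4,
                                          t_max = 5, seed = 2))
  expect_equal(res$fitness, 0)
  expect_gte(res$delta, 0.01)
  expect_lte(res$delta, 10)
  expect_true(all(diff(res$history) <= 0))
})
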