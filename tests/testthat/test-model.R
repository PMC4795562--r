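test_that("scores follow the closed-form logistic", {
  X <- Matrix::sparseMatrix(i = 1, j = 1, x = 1, dims = c(1, 1),
                            dimnames = list(NULL, "t1"))
  zero <- structure(list(weights = 0, intercept = 0, terms = "t1",
                         meta = list()), class = "rob_model")
  expect_equal(predict_score(zero, X), 0.5)

  m <- structure(list(weights = log(2), intercept = 0, terms = "t1",
                      meta = list()), class = "rob_model")
  expect_equal(predict_score(m, X), 2 / 3)

  # adding log(3) to the intercept multiplies the odds by 3
  withr::with_seed(2, {
    Xr <- Matrix::Matrix(matrix(rpois(50, 1), 10, 5), sparse = TRUE)
    w <- rnorm(5)
    m1 <- structure(list(weights = w, intercept = 0.3,
                         terms = paste0("t", 1:5), meta = list()),
                    class = "rob_model")
    m2 <- m1; m2$intercept <- m1$intercept + log(3)
    s1 <- predict_score(m1, Xr); s2 <- predict_score(m2, Xr)
    expect_equal(s2 / (1 - s2), 3 * s1 / (1 - s1), tolerance = 1e-12)
  })
})

test_that("zero epochs gives the all-zero model and 0.5 scores", {
  d <- random_counts(20, 5, seed = 3)
  m <- sgd_train(d$X, d$y, train_config("sentence", epochs = 0), seed = 1)
  expect_true(all(m$weights == 0))
  expect_equal(m$intercept, 0)
  expect_true(all(predict_score(m, d$X) == 0.5))
})

test_that("training is bitwise deterministic given the seed", {
  d <- random_counts(30, 8, seed = 4)
  cfg <- train_config("sentence", epochs = 50)
  m1 <- sgd_train(d$X, d$y, cfg, seed = 11)
  m2 <- sgd_train(d$X, d$y, cfg, seed = 11)
  expect_identical(m1$weights, m2$weights)
  expect_identical(m1$intercept, m2$intercept)
  m3 <- sgd_train(d$X, d$y, cfg, seed = 12)
  expect_false(identical(m1$weights, m3$weights))
})

test_that("separable one-feature data is learned with positive weight and AUC 1", {
  X <- Matrix::sparseMatrix(i = 1:20, j = rep(1, 20),
                            x = c(rep(1, 10), rep(0, 10)),
                            dims = c(20, 1), dimnames = list(NULL, "sig"))
  y <- c(rep(1, 10), rep(0, 10))
  m <- sgd_train(X, y, train_config("sentence", epochs = 500), seed = 5)
  expect_gt(m$weights[1], 0)
  expect_equal(auc(predict_score(m, X), y), 1.0)
  # direction agrees with the maximum-likelihood fit
  glm_fit <- suppressWarnings(
    stats::glm(y ~ as.numeric(X[, 1]), family = stats::binomial()))
  expect_equal(sign(m$weights[1]), unname(sign(stats::coef(glm_fit)[2])))
})

test_that("SGD approaches the glm solution on well-conditioned data", {
  d <- random_counts(400, 4, seed = 9)
  beta <- c(1.2, -1, 0.5, 0)
  y <- withr::with_seed(10,
    rbinom(400, 1, plogis(as.numeric(d$X %*% beta) - 0.3)))
  m <- sgd_train(d$X, y, train_config("sentence", epochs = 800), seed = 6)
  glm_fit <- suppressWarnings(
    stats::glm(y ~ as.matrix(d$X), family = stats::binomial()))
  expect_equal(sign(m$weights[1:2]), sign(unname(coef(glm_fit)[2:3])))
  expect_lt(max(abs(m$weights - unname(coef(glm_fit)[-1]))), 0.35)
})

test_that("single-class input is rejected", {
  d <- random_counts(10, 3, seed = 7)
  expect_error(sgd_train(d$X, rep(1, 10), train_config("sentence")),
               "single-class")
})

test_that("analytic update direction matches the numerical log-loss gradient", {
  withr::with_seed(13, {
    for (rep in 1:5) {
      w <- rnorm(4); b <- rnorm(1)
      x <- rpois(4, 1); y <- rbinom(1, 1, 0.5)
      s <- 1 / (1 + exp(-(sum(w * x) + b)))
      analytic_gw <- -(y - s) * x   # gradient of the loss
      analytic_gb <- -(y - s)
      num <- numeric_logloss_grad(w, b, x, y)
      expect_lt(max(abs(num$gw - analytic_gw)), 1e-6)
      expect_lt(abs(num$gb - analytic_gb), 1e-6)
    }
  })
})

test_that("score increases strictly with the count of a positive-weight term", {
  m <- structure(list(weights = c(0.7, -0.2), intercept = 0.1,
                      terms = c("random", "patient"), meta = list()),
                 class = "rob_model")
  counts <- function(k) Matrix::sparseMatrix(i = c(1, 1), j = c(1, 2),
                                             x = c(k, 2), dims = c(1, 2))
  s <- vapply(0:4, function(k) predict_score(m, counts(k)), 0)
  expect_true(all(diff(s) > 0))
})

test_that("top terms are ordered by absolute weight with stable ties", {
  m <- structure(list(weights = c(2, -0.1, -2), intercept = 0,
                      terms = c("random", "patient", "open"),
                      meta = list()), class = "rob_model")
  tt <- top_terms(m, 1)
  expect_equal(tt$term, "random")  # tie with "open" broken by term order
  expect_equal(tt$weight, 2)
  expect_equal(nrow(top_terms(m, 0)), 0L)
  expect_equal(nrow(top_terms(m, 10)), 3L)
})

test_that("models round-trip through JSON", {
  d <- random_counts(25, 6, seed = 8)
  m <- sgd_train(d$X, d$y, train_config("article", epochs = 30), seed = 2,
                 property = "blind")
  path <- withr::local_tempfile(fileext = ".json")
  write_model(m, path)
  back <- read_model(path)
  expect_equal(back$weights, m$weights)
  expect_equal(back$intercept, m$intercept)
  expect_equal(predict_score(back, d$X), predict_score(m, d$X))
})
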