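test_that("the modified Huber loss matches its closed form and is smooth", {
  expect_equal(huber_loss(c(-2, -1, 0, 1, 2)), c(8, 4, 1, 0, 0))
  # continuous with continuous first derivative at the branch points
  eps <- 1e-7
  slope <- function(z) (huber_loss(z + eps) - huber_loss(z - eps)) / (2 * eps)
  expect_equal(slope(-1), -4, tolerance = 1e-5)
  expect_equal(slope(1), 0, tolerance = 1e-5)
  expect_equal(huber_loss(-1 - 1e-12), huber_loss(-1 + 1e-12),
               tolerance = 1e-9)
})

test_that("lambda scales with the squared mean Euclidean norm", {
  unit <- Matrix::sparseMatrix(i = 1:4, j = 1:4, x = 1)   # all norms 1
  expect_equal(compute_lambda(unit, 1e-7), 1e-7)
  four <- Matrix::Matrix(matrix(1, 3, 4), sparse = TRUE)  # 4 active -> norm 2
  expect_equal(compute_lambda(four, 1e-7), 4e-7)
  mixed <- Matrix::sparseMatrix(i = c(1, rep(2, 9)), j = c(1, 2:10), x = 1,
                                dims = c(2, 10))          # norms 1 and 3
  expect_equal(compute_lambda(mixed, 2), 2 * 4)           # mean 2, squared
  expect_error(compute_lambda(unit[0, ], 1e-7), "empty")
})

test_that("the analytic gradient matches central differences", {
  set.seed(17)
  X <- Matrix::Matrix(matrix(rbinom(10 * 8, 1, 0.4), 10, 8), sparse = TRUE)
  y <- rep(c(1L, -1L), 5)
  w <- stats::rnorm(8) * 0.3
  theta <- 0.2
  lambda <- 0.05
  for (loss in c("huber")) {
    g <- svm_gradient(w, theta, X, y, lambda, loss)
    h <- 1e-6
    for (j in seq_along(w)) {
      e <- replace(numeric(8), j, h)
      num <- (svm_cost(w + e, theta, X, y, lambda, loss) -
                svm_cost(w - e, theta, X, y, lambda, loss)) / (2 * h)
      expect_equal(g$w[j], num, tolerance = 1e-6)
    }
    num_t <- (svm_cost(w, theta + h, X, y, lambda, loss) -
                svm_cost(w, theta - h, X, y, lambda, loss)) / (2 * h)
    expect_equal(g$theta, num_t, tolerance = 1e-6)
  }
})

test_that("training solves separable problems and never increases the cost", {
  # positives carry feature A (col 1), negatives feature B (col 2)
  X <- Matrix::sparseMatrix(i = 1:20, j = rep(c(1, 2), each = 10), x = 1,
                            dims = c(20, 2),
                            dimnames = list(NULL, c("A", "B")))
  y <- rep(c(1L, -1L), each = 10)
  model <- svm_train(X, y)
  expect_equal(classify(model, X), y)
  expect_lte(model$final_cost, model$initial_cost)
  expect_error(svm_train(X, rep(1L, 20)), "both classes")
})

test_that("duplicating every example leaves the optimum unchanged", {
  set.seed(23)
  X <- Matrix::Matrix(matrix(rbinom(30 * 12, 1, 0.3), 30, 12),
                      sparse = TRUE)
  colnames(X) <- paste0("f", 1:12)
  y <- rep(c(1L, -1L), 15)
  m1 <- svm_train(X, y, epochs = 100)
  m2 <- svm_train(rbind(X, X), c(y, y), epochs = 100)
  expect_equal(m1$w, m2$w)
  expect_equal(m1$theta, m2$theta)
})

test_that("decision values and class predictions are consistent", {
  X <- Matrix::sparseMatrix(i = 1, j = 1, x = 1, dims = c(1, 2),
                            dimnames = list(NULL, c("A", "B")))
  zero <- structure(list(w = c(A = 0, B = 0), theta = 0,
                         feature_index = c("A", "B")),
                    class = "model_params")
  expect_equal(decision(zero, X), 0)
  expect_equal(classify(zero, X), -1L)               # ties -> negative
  off <- structure(list(w = c(A = 0, B = 0), theta = 0.7,
                        feature_index = c("A", "B")),
                   class = "model_params")
  expect_equal(decision(off, X), 0.7)                # unseen-only vector

  set.seed(29)
  model <- structure(list(w = setNames(stats::rnorm(5), paste0("f", 1:5)),
                          theta = -0.1, feature_index = paste0("f", 1:5)),
                     class = "model_params")
  R <- Matrix::Matrix(matrix(rbinom(1000 * 5, 1, 0.4), 1000, 5),
                      sparse = TRUE, dimnames = list(NULL, paste0("f", 1:5)))
  d <- decision(model, R)
  expect_equal(classify(model, R), ifelse(d > 0, 1L, -1L))
})

test_that("metrics match a hand-computed confusion table", {
  truth <- c(rep(1L, 8), rep(-1L, 12))
  pred <- c(rep(1L, 6), -1L, -1L,          # 6 TP, 2 FN
            rep(1L, 3), rep(-1L, 9))       # 3 FP, 9 TN
  m <- prf_metrics(truth, pred)
  expect_equal(c(m$tp, m$fp, m$fn, m$tn), c(6, 3, 2, 9))
  expect_equal(m$precision, 6 / 9)
  expect_equal(m$recall, 6 / 8)
  expect_equal(m$f1, 2 * (6 / 9) * (6 / 8) / ((6 / 9) + (6 / 8)))
  # all-negative predictions: recall 0, precision flagged undefined
  m0 <- prf_metrics(truth, rep(-1L, 20))
  expect_equal(m0$recall, 0)
  expect_equal(m0$precision, 0)
  expect_false(m0$precision_defined)
})

test_that("cross-validation is stratified, pooled and deterministic", {
  X <- Matrix::sparseMatrix(i = 1:40, j = rep(c(1, 2), each = 20), x = 1,
                            dims = c(40, 2),
                            dimnames = list(NULL, c("A", "B")))
  y <- rep(c(1L, -1L), each = 20)
  m <- cross_validate(X, y, folds = 10, seed = 4)
  expect_equal(c(m$precision, m$recall, m$f1), c(1, 1, 1))
  m2 <- cross_validate(X, y, folds = 10, seed = 4)
  expect_identical(m[c("tp", "fp", "fn", "tn")],
                   m2[c("tp", "fp", "fn", "tn")])
})

test_that("models survive a JSON round trip", {
  X <- Matrix::sparseMatrix(i = 1:10, j = rep(c(1, 2), 5), x = 1,
                            dims = c(10, 2),
                            dimnames = list(NULL, c("A", "B")))
  y <- rep(c(1L, -1L), 5)
  model <- svm_train(X, y, epochs = 50)
  path <- withr::local_tempfile(fileext = ".json")
  write_model(model, path)
  back <- read_model(path)
  expect_equal(back$w, model$w)
  expect_equal(back$theta, model$theta)
  expect_equal(back$lambda_prime, model$lambda_prime)
  expect_identical(back$feature_index, model$feature_index)
})
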