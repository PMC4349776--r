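# Linear classifier with the modified Huber loss.
#
# The objective over a training set of size T with binary feature vectors
# X_i and labels y_i in {-1, +1} is
#
#   C(w, theta) = (lambda / 2) |w|^2 + (1/T) sum_i h(y_i (theta + w . X_i))
#
# where h is the modified Huber loss:
#
#   h(z) = -4 z        for z <= -1
#        = (1 - z)^2   for -1 < z < 1
#        = 0           for z >= 1
#
# h is continuous with continuous first derivative (slope -4 at z = -1 and
# 0 at z = +1), which is why plain gradient descent on C is well behaved.
# The regularization strength is tied to the data scale:
#
#   lambda = lambda' * (mean Euclidean norm of the X_i)^2
#
# with lambda' defaulting to 1e-7.  The objective is convex, so training
# starts from w = 0, theta = 0 and needs no random initialization.

#' Modified Huber loss
#'
#' @param z Margin values \code{y * (theta + w . x)} (vectorized).
#' @return Loss values: \code{-4z} for \code{z <= -1}, \code{(1-z)^2} on
#'   \code{(-1, 1)}, \code{0} for \code{z >= 1}.
#' @export
huber_loss <- function(z) {
  ifelse(z <= -1, -4 * z, ifelse(z < 1, (1 - z)^2, 0))
}

# First derivative h'(z); used by the gradient.
.huber_grad <- function(z) {
  ifelse(z <= -1, -4, ifelse(z < 1, -2 * (1 - z), 0))
}

.hinge_loss <- function(z) pmax(0, 1 - z)
.hinge_grad <- function(z) ifelse(z < 1, -1, 0)

#' Data-scaled regularization parameter
#'
#' \code{lambda = lambda_prime * (mean Euclidean norm of the training
#' vectors)^2}.  For binary features the norm of a vector is the square
#' root of its number of active features.
#'
#' @param X Sparse binary matrix of training vectors (rows = examples).
#' @param lambda_prime Scale-free regularization constant; default
#'   \code{1e-7}.
#' @return The scaled regularization parameter \code{lambda}.
#' @export
compute_lambda <- function(X, lambda_prime = 1e-7) {
  if (nrow(X) == 0) stop("empty training set")
  norms <- sqrt(Matrix::rowSums(X^2))
  lambda_prime * mean(norms)^2
}

# Cost and gradient of the full objective.  Exported for testing against
# numerical differentiation; not part of the everyday surface.
#' Objective value of the regularized loss
#' @param w Weight vector.
#' @param theta Threshold.
#' @param X Sparse matrix.
#' @param y Labels in \code{c(-1, 1)}.
#' @param lambda Regularization parameter.
#' @param loss \code{"huber"} or \code{"hinge"}.
#' @return Scalar cost.
#' @keywords internal
#' @export
svm_cost <- function(w, theta, X, y, lambda, loss = "huber") {
  lf <- if (loss == "huber") huber_loss else .hinge_loss
  z <- y * (theta + as.vector(X %*% w))
  0.5 * lambda * sum(w^2) + mean(lf(z))
}

#' Gradient of the regularized loss
#' @inheritParams svm_cost
#' @return List with \code{w} (gradient in the weights) and \code{theta}.
#' @keywords internal
#' @export
svm_gradient <- function(w, theta, X, y, lambda, loss = "huber") {
  gf <- if (loss == "huber") .huber_grad else .hinge_grad
  z <- y * (theta + as.vector(X %*% w))
  g <- gf(z) * y
  list(w = lambda * w + as.vector(Matrix::crossprod(X, g)) / nrow(X),
       theta = mean(g))
}

#' Train the modified-Huber SVM by gradient descent
#'
#' Full-batch gradient descent on the regularized objective, starting from
#' \code{w = 0, theta = 0}.  The learning rate is fixed; if a step would
#' increase the cost it is rejected and the rate halved, so the recorded
#' cost sequence is non-increasing and the final cost never exceeds the
#' initial one.  Training is deterministic: the objective is convex and the
#' start point is fixed, so no randomness is involved.
#'
#' @param X Sparse binary training matrix (rows = examples, columns named
#'   by feature).
#' @param y Integer labels in \code{\{-1, +1\}}; both classes must be
#'   present.
#' @param lambda_prime Regularization constant, see
#'   \code{\link{compute_lambda}}.
#' @param lr Initial learning rate.
#' @param epochs Number of gradient steps.
#' @param loss \code{"huber"} (default) or \code{"hinge"}.
#' @return A \code{model_params} object: list with \code{w} (named weight
#'   vector), \code{theta}, \code{lambda}, \code{lambda_prime}, training
#'   metadata, and the initial/final cost.
#' @export
svm_train <- function(X, y, lambda_prime = 1e-7, lr = 0.5, epochs = 200L,
                      loss = c("huber", "hinge")) {
  loss <- match.arg(loss)
  y <- as.integer(y)
  stopifnot(nrow(X) == length(y), all(y %in% c(-1L, 1L)))
  if (length(unique(y)) < 2) {
    stop("training requires both classes to be present")
  }
  lambda <- compute_lambda(X, lambda_prime)
  w <- numeric(ncol(X))
  theta <- 0
  cost0 <- svm_cost(w, theta, X, y, lambda, loss)
  cost <- cost0
  rate <- lr
  for (e in seq_len(epochs)) {
    g <- svm_gradient(w, theta, X, y, lambda, loss)
    w_new <- w - rate * g$w
    theta_new <- theta - rate * g$theta
    cost_new <- svm_cost(w_new, theta_new, X, y, lambda, loss)
    if (!is.finite(cost_new)) {
      stop("non-finite cost at epoch ", e, " (lr = ", rate,
           "); reduce the learning rate")
    }
    if (cost_new > cost) {
      rate <- rate / 2            # reject the step, try a smaller rate
      next
    }
    w <- w_new; theta <- theta_new; cost <- cost_new
  }
  structure(
    list(w = setNames(w, colnames(X)), theta = theta,
         lambda = lambda, lambda_prime = lambda_prime,
         lr = lr, epochs = as.integer(epochs), loss = loss,
         feature_index = colnames(X),
         initial_cost = cost0, final_cost = cost,
         lemmatizer = "rule"),
    class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("<model_params> ", length(x$w), " features, loss = ", x$loss,
      ", lambda' = ", format(x$lambda_prime),
      "\n  cost ", format(x$initial_cost), " -> ", format(x$final_cost),
      " over ", x$epochs, " epochs\n", sep = "")
  invisible(x)
}

#' Decision value and class prediction
#'
#' The decision value is \code{theta + w . x}; the predicted class is
#' \code{+1} when the decision value is strictly positive and \code{-1}
#' otherwise (ties go to the negative class, the conservative choice for a
#' precision-oriented filter).
#'
#' @param model A \code{model_params} object.
#' @param X Sparse matrix of feature vectors with columns matching the
#'   model's feature index (build with
#'   \code{vectorize(sets, index = model$feature_index)}).
#' @return \code{decision}: numeric decision values; \code{classify}:
#'   integer labels in \code{\{-1, +1\}}.
#' @export
decision <- function(model, X) {
  stopifnot(inherits(model, "model_params"), ncol(X) == length(model$w))
  model$theta + as.vector(X %*% model$w)
}

#' @rdname decision
#' @export
classify <- function(model, X) {
  ifelse(decision(model, X) > 0, 1L, -1L)
}

#' Precision, recall and F1 from predictions
#'
#' @param truth Integer labels in \code{\{-1, +1\}}.
#' @param predicted Integer labels in \code{\{-1, +1\}}.
#' @return List with \code{precision}, \code{recall}, \code{f1}, the
#'   2x2 confusion counts, and \code{precision_defined} (FALSE when
#'   nothing was predicted positive; precision is then reported as 0).
#' @export
prf_metrics <- function(truth, predicted) {
  tp <- sum(predicted == 1 & truth == 1)
  fp <- sum(predicted == 1 & truth == -1)
  fn <- sum(predicted == -1 & truth == 1)
  tn <- sum(predicted == -1 & truth == -1)
  p_def <- (tp + fp) > 0
  precision <- if (p_def) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  list(precision = precision, recall = recall, f1 = f1,
       tp = tp, fp = fp, fn = fn, tn = tn, precision_defined = p_def)
}

#' Stratified k-fold cross-validation
#'
#' Splits positives and negatives separately into \code{folds} shuffled
#' groups (stratification keeps the class ratio stable across folds),
#' trains on each complement and predicts the held-out fold, then pools all
#' held-out predictions into a single confusion table for precision, recall
#' and F1.  Deterministic given \code{seed}.
#'
#' @param X Sparse binary matrix.
#' @param y Labels in \code{c(-1, 1)}.
#' @param folds Number of folds (default 10).
#' @param seed Integer seed for fold shuffling.
#' @param ... Passed to \code{\link{svm_train}} (e.g. \code{lambda_prime},
#'   \code{lr}, \code{epochs}, \code{loss}).
#' @return List with \code{precision}, \code{recall}, \code{f1}, pooled
#'   confusion counts, \code{folds}, and \code{fold_warnings} (number of
#'   folds without a positive prediction).
#' @export
cross_validate <- function(X, y, folds = 10L, seed = 1L, ...) {
  y <- as.integer(y)
  stopifnot(folds >= 2, nrow(X) >= folds, nrow(X) == length(y))
  set.seed(seed)
  fold_of <- integer(length(y))
  pos <- sample(which(y == 1L))
  neg <- sample(which(y == -1L))
  fold_of[pos] <- rep_len(seq_len(folds), length(pos))
  fold_of[neg] <- rep_len(seq_len(folds), length(neg))
  predicted <- integer(length(y))
  no_pos <- 0L
  for (k in seq_len(folds)) {
    hold <- fold_of == k
    model <- svm_train(X[!hold, , drop = FALSE], y[!hold], ...)
    predicted[hold] <- classify(model, X[hold, , drop = FALSE])
    if (!any(predicted[hold] == 1L)) no_pos <- no_pos + 1L
  }
  if (no_pos > 0) {
    warning(no_pos, " fold(s) produced no positive predictions")
  }
  m <- prf_metrics(y, predicted)
  c(m, list(folds = as.integer(folds), fold_warnings = no_pos))
}

#' Serialize a trained model to JSON text
#'
#' @param model A \code{model_params} object.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "model_params"))
  obj <- list(
    weights = as.list(model$w), theta = model$theta,
    lambda = model$lambda, lambda_prime = model$lambda_prime,
    lr = model$lr, epochs = model$epochs, loss = model$loss,
    feature_index = model$feature_index,
    initial_cost = model$initial_cost, final_cost = model$final_cost,
    lemmatizer = model$lemmatizer,
    feature_index_hash = .index_hash(model$feature_index))
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' Read a serialized model
#' @param path Path to a model JSON file written by \code{\link{write_model}}.
#' @return A \code{model_params} object.
#' @export
read_model <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!identical(.index_hash(obj$feature_index),
                 obj$feature_index_hash)) {
    stop("feature index hash mismatch in ", path)
  }
  structure(
    list(w = setNames(as.numeric(obj$weights), names(obj$weights)),
         theta = obj$theta, lambda = obj$lambda,
         lambda_prime = obj$lambda_prime, lr = obj$lr,
         epochs = as.integer(obj$epochs), loss = obj$loss,
         feature_index = obj$feature_index,
         initial_cost = obj$initial_cost, final_cost = obj$final_cost,
         lemmatizer = obj$lemmatizer),
    class = "model_params")
}

# Cheap order-sensitive checksum of the feature index (no digest dep).
.index_hash <- function(index) {
  v <- utf8ToInt(paste(index, collapse = ""))
  sprintf("%08x", sum(v * (seq_along(v) %% 97 + 1)) %% 2^31)
}
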