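#' Train the single-hidden-layer classifier
#'
#' The classifier at the heart of both the discovery search and the
#' validation vote: inputs are standardized by the learner set's mean and
#' sd (zero-variance features get scale 1), weights start
#' Uniform(-init_scale, init_scale) from `config$seed`, and training is
#' full-batch gradient descent with momentum on multinomial cross-entropy
#' with an L2 weight penalty, for a fixed epoch budget. Training is
#' deterministic given `(X, y, config)`; rows are canonically pre-sorted by
#' sample id so the sample order cannot influence the fit.
#'
#' @param X numeric matrix (samples x features) with rownames; no missing
#'   values.
#' @param y character/factor class labels, one per row of X.
#' @param config an [nn_config()].
#' @return object of class `nn_model`: scaler, weight matrices, class list.
#' @export
train_nn <- function(X, y, config = nn_config()) {
  stopifnot(is.matrix(X), nrow(X) == length(y), !anyNA(X))
  y <- as.character(y)
  classes <- sort(unique(y))
  if (length(classes) < 2L) {
    stop("training labels contain a single class", call. = FALSE)
  }
  if (!is.null(rownames(X))) {
    ord <- order(rownames(X))
    X <- X[ord, , drop = FALSE]
    y <- y[ord]
  }
  center <- colMeans(X)
  scale <- apply(X, 2L, stats::sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  Xs <- sweep(sweep(X, 2L, center), 2L, scale, "/")

  p <- ncol(X); h <- config$hidden_units; k <- length(classes)
  set.seed(config$seed)
  W1 <- matrix(stats::runif((p + 1L) * h, -config$init_scale,
                            config$init_scale), p + 1L, h)
  W2 <- matrix(stats::runif((h + 1L) * k, -config$init_scale,
                            config$init_scale), h + 1L, k)
  Y <- matrix(0, nrow(X), k)
  Y[cbind(seq_along(y), match(y, classes))] <- 1

  fit <- nn_fit_cpp(Xs, Y, W1, W2, config$weight_decay,
                    config$learning_rate, 0.9, config$max_epochs)
  structure(list(center = center, scale = scale,
                 W1 = fit$W1, W2 = fit$W2, loss = fit$loss,
                 classes = classes, features = colnames(X)),
            class = "nn_model")
}

#' Predict class probabilities from a trained network
#'
#' Applies the model's learner-set scaler, the logistic hidden layer and
#' the softmax output; the predicted class is the probability argmax.
#'
#' @param model an `nn_model` from [train_nn()].
#' @param x numeric vector (one sample) or matrix (samples x features) with
#'   the model's feature arity.
#' @return matrix of class probabilities (rows sum to 1), columns named by
#'   class.
#' @export
predict_nn <- function(model, x) {
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  if (ncol(x) != length(model$center)) {
    stop(sprintf("feature arity mismatch: model expects %d, got %d",
                 length(model$center), ncol(x)), call. = FALSE)
  }
  xs <- sweep(sweep(x, 2L, model$center), 2L, model$scale, "/")
  p <- nn_predict_cpp(xs, model$W1, model$W2)
  colnames(p) <- model$classes
  rownames(p) <- rownames(x)
  p
}

#' Predicted class labels
#' @param model an `nn_model`.
#' @param x sample matrix or vector.
#' @return character vector of argmax classes.
#' @export
predict_nn_class <- function(model, x) {
  p <- predict_nn(model, x)
  model$classes[max.col(p, ties.method = "first")]
}

# Draw one initial weight slice per iteration, reproducing exactly the
# weights train_nn would generate from the same per-iteration seed.
draw_init_weights <- function(seeds, p, h, k, init_scale) {
  n_iter <- length(seeds)
  W1 <- array(0, c(p + 1L, h, n_iter))
  W2 <- array(0, c(h + 1L, k, n_iter))
  for (i in seq_len(n_iter)) {
    set.seed(seeds[i])
    W1[, , i] <- stats::runif((p + 1L) * h, -init_scale, init_scale)
    W2[, , i] <- stats::runif((h + 1L) * k, -init_scale, init_scale)
  }
  list(W1 = W1, W2 = W2)
}

# Batched train/predict over pre-drawn row splits (see nn_batch_cpp):
# learner rows are canonically sorted so results match train_nn on the same
# subset with the same seed. Returns a (n_iter x n_test) matrix of
# predicted labels.
nn_batch_predict <- function(X, y, classes, learn, test, seeds, config) {
  stopifnot(is.matrix(learn), is.matrix(test),
            nrow(learn) == length(seeds), nrow(test) == length(seeds))
  init <- draw_init_weights(seeds, ncol(X), config$hidden_units,
                            length(classes), config$init_scale)
  yi <- match(y, classes) - 1L
  yi[is.na(yi)] <- 0L  # rows never used as learners (e.g. the unknown)
  pred <- nn_batch_cpp(X, yi, length(classes), learn - 1L, test - 1L,
                       init$W1, init$W2, config$weight_decay,
                       config$learning_rate, 0.9, config$max_epochs)
  matrix(classes[pred + 1L], nrow(pred), ncol(pred))
}
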