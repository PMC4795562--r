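# Unregularized logistic regression fitted by stochastic gradient descent.
# Probability model: s = sigmoid(beta . x + beta0); a one-unit increase in
# x_i shifts the log odds of the positive class by beta_i. No penalty
# (lambda = 0), constant learning rate, no averaging, raw counts unscaled.

#' Training configuration for the SGD logistic model
#'
#' Defaults follow the published settings: sentence-level models use
#' learning rate 0.001 with 2000 epochs; article-level models use learning
#' rate 0.0001 with 4000 epochs (far fewer examples, so more epochs at a
#' smaller rate). Lambda is fixed at 0 — the models are unregularized.
#'
#' @param level `"sentence"` or `"article"`.
#' @param learning_rate Constant SGD step size; default by level.
#' @param epochs Number of full passes; default by level.
#' @return A list of class `rob_train_config`.
#' @export
train_config <- function(level = c("sentence", "article"),
                         learning_rate = NULL, epochs = NULL) {
  level <- match.arg(level)
  if (is.null(learning_rate))
    learning_rate <- if (level == "sentence") 0.001 else 0.0001
  if (is.null(epochs))
    epochs <- if (level == "sentence") 2000L else 4000L
  structure(list(level = level, learning_rate = learning_rate,
                 epochs = as.integer(epochs), lambda = 0),
            class = "rob_train_config")
}

.as_csr <- function(X) {
  # column-compressed transpose gives row-compressed original
  Xt <- Matrix::t(methods::as(X, "CsparseMatrix"))
  list(xp = Xt@p, xi = Xt@i, xv = Xt@x)
}

#' Fit a logistic model by stochastic gradient descent
#'
#' Weights are initialized at zero; each epoch visits the examples in a
#' seed-determined shuffled order; the per-example update is the log-loss
#' gradient step `w <- w + lr * (y - sigmoid(w.x + b)) * x` with the
#' intercept updated as an implicit always-one feature. Deterministic given
#' `seed`.
#'
#' @param X Sparse count matrix (rows = examples), e.g. from
#'   [vectorize()].
#' @param y Binary labels (0/1), length `nrow(X)`.
#' @param config A `rob_train_config`.
#' @param seed Integer seed controlling the epoch shuffles.
#' @param property,terms Optional metadata stored on the model.
#' @return An object of class `rob_model` with fields `weights`,
#'   `intercept`, `terms`, `meta`.
#' @export
sgd_train <- function(X, y, config = train_config("sentence"), seed = 1L,
                      property = NA_character_, terms = colnames(X)) {
  stopifnot(inherits(config, "rob_train_config"),
            nrow(X) == length(y), all(y %in% c(0, 1)))
  if (!any(y == 1) || !any(y == 0))
    stop("single-class input: need both positive and negative examples")
  csr <- .as_csr(X)
  w <- withr::with_seed(seed,
    sgd_fit_cpp(csr$xp, csr$xi, csr$xv, as.numeric(y), ncol(X),
                config$learning_rate, config$epochs))
  structure(list(weights = w[seq_len(ncol(X))],
                 intercept = w[ncol(X) + 1L],
                 terms = terms,
                 meta = list(learning_rate = config$learning_rate,
                             epochs = config$epochs, lambda = 0,
                             seed = as.integer(seed),
                             level = config$level, property = property,
                             n_examples = nrow(X))),
            class = "rob_model")
}

#' @export
print.rob_model <- function(x, ...) {
  cat(sprintf("<rob_model> level=%s property=%s, %d weights, intercept=%.4f\n",
              x$meta$level, x$meta$property, length(x$weights), x$intercept))
  invisible(x)
}

#' Predict calibrated probability scores
#'
#' `s = 1 / (1 + exp(-(beta . x + beta0)))`; higher scores mean more likely
#' positive (relevant sentence, or low-risk article).
#'
#' @param model A `rob_model`.
#' @param X Sparse count matrix with `length(model$weights)` columns.
#' @return Numeric vector of scores in (0, 1).
#' @export
predict_score <- function(model, X) {
  stopifnot(inherits(model, "rob_model"), ncol(X) == length(model$weights))
  z <- as.numeric(X %*% model$weights) + model$intercept
  stats::plogis(z)
}

#' Largest-magnitude model terms
#'
#' @param model A `rob_model` with term names.
#' @param k Number of terms to return (all if `k` exceeds the vocabulary).
#' @return Data frame with columns `term` and `weight`, sorted by
#'   decreasing `|weight|`, ties broken by term order.
#' @export
top_terms <- function(model, k = 10L) {
  stopifnot(inherits(model, "rob_model"))
  k <- min(as.integer(k), length(model$weights))
  if (k <= 0L)
    return(data.frame(term = character(), weight = numeric(),
                      stringsAsFactors = FALSE))
  ord <- order(-abs(model$weights), seq_along(model$weights))[seq_len(k)]
  data.frame(term = model$terms[ord], weight = model$weights[ord],
             stringsAsFactors = FALSE)
}

#' Save a model as JSON (sparse weights + metadata)
#' @param model A `rob_model`.
#' @param path Output path.
#' @export
write_model <- function(model, path) {
  nz <- which(model$weights != 0)
  obj <- list(terms = model$terms, nonzero_index = nz,
              nonzero_weight = model$weights[nz],
              n_terms = length(model$weights),
              intercept = model$intercept, meta = model$meta)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model saved by [write_model()]
#' @param path Path to the JSON model file.
#' @return A `rob_model`.
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  w <- numeric(obj$n_terms)
  w[obj$nonzero_index] <- obj$nonzero_weight
  structure(list(weights = w, intercept = obj$intercept,
                 terms = obj$terms, meta = obj$meta),
            class = "rob_model")
}
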