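# One-hot design encoding shared by ELM (and available to other learners).
# Stores factor levels at training time so prediction frames encode identically.
encode_design <- function(X, template = NULL) {
  X <- as.data.frame(X)
  if (is.null(template)) {
    template <- purrr::map(X, function(col) if (is.factor(col)) levels(col) else NULL)
  }
  cols <- purrr::imap(X, function(col, nm) {
    lev <- template[[nm]]
    if (is.null(lev)) {
      m <- matrix(as.numeric(col), ncol = 1, dimnames = list(NULL, nm))
    } else {
      chr <- as.character(col)
      m <- vapply(lev, function(l) as.numeric(chr == l), numeric(length(chr)))
      if (!is.matrix(m)) m <- matrix(m, nrow = length(chr))
      colnames(m) <- paste(nm, lev, sep = ".")
    }
    m
  })
  list(mat = do.call(cbind, unname(cols)), template = template)
}

#' Train an extreme learning machine regressor
#'
#' A single-hidden-layer feedforward network whose hidden weights and biases
#' are drawn once from a seeded Uniform(-1, 1) on standardized inputs and
#' never trained; only the linear read-out is fitted, in closed form, as the
#' ridge solution `argmin ||H beta - y||^2 + lambda ||beta||^2` (intercept
#' unpenalized, solved stably via SVD of the centered activation matrix).
#'
#' @param X Predictor frame or matrix; factor columns are one-hot encoded.
#' @param y Numeric response.
#' @param hidden Number of hidden units (default 100).
#' @param activation `"sigmoid"` (default) or `"tanh"`.
#' @param ridge_lambda Ridge penalty on the read-out weights (default 1e-3).
#' @param seed Seed for the random hidden layer.
#'
#' @return An object of class `fohem_elm`.
#' @export
#' @examples
#' d <- simulate_yield_data(generator_config(n_records = 60, seed = 1))
#' m <- elm_train(d[, c("total_biomass", "LAI")], d$yield, hidden = 40, seed = 1)
#' head(predict(m, d[, c("total_biomass", "LAI")]))
elm_train <- function(X, y, hidden = 100, activation = c("sigmoid", "tanh"),
                      ridge_lambda = 1e-3, seed = 1) {
  activation <- match.arg(activation)
  if (hidden < 1) abort("elm_train: hidden must be >= 1")
  if (ridge_lambda < 0) abort("elm_train: ridge_lambda must be >= 0")
  enc <- encode_design(X)
  Z <- enc$mat
  if (!all(is.finite(Z)) || !all(is.finite(y))) {
    abort("elm_train: non-finite values in X or y")
  }
  n <- nrow(Z)
  if (n < 2) abort("elm_train: need at least 2 samples")
  if (length(y) != n) abort("elm_train: length(y) must match nrow(X)")
  mu <- colMeans(Z)
  sds <- apply(Z, 2, stats::sd)
  sds[sds == 0] <- 1
  Zs <- sweep(sweep(Z, 2, mu, "-"), 2, sds, "/")
  p <- ncol(Zs)
  W <- with_seed(seed, {
    w <- matrix(stats::runif(hidden * p, -1, 1), nrow = hidden)
    b <- stats::runif(hidden, -1, 1)
    list(w = w, b = b)
  })
  H <- elm_activations(Zs, W$w, W$b, activation)
  # unpenalized intercept via centering; penalized hidden weights via SVD ridge
  h_mu <- colMeans(H)
  y_mu <- mean(y)
  Hc <- sweep(H, 2, h_mu, "-")
  sv <- svd(Hc)
  d <- sv$d
  shrink <- d / (d^2 + ridge_lambda)
  beta <- sv$v %*% (shrink * crossprod(sv$u, y - y_mu))
  intercept <- y_mu - sum(h_mu * beta)
  structure(list(input_weights = W$w, biases = W$b,
                 output_weights = c(intercept = intercept, as.numeric(beta)),
                 activation = activation, ridge_lambda = ridge_lambda,
                 feature_means = mu, feature_sds = sds,
                 template = enc$template, hidden = as.integer(hidden),
                 seed = as.integer(seed)),
            class = "fohem_elm")
}

elm_activations <- function(Zs, W, b, activation) {
  A <- tcrossprod(Zs, W)
  A <- sweep(A, 2, b, "+")
  switch(activation,
         sigmoid = 1 / (1 + exp(-A)),
         tanh = tanh(A))
}

#' Predict from a trained ELM
#'
#' @param object A `fohem_elm` model.
#' @param newdata Predictor frame/matrix with the training columns.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.fohem_elm <- function(object, newdata, ...) {
  enc <- encode_design(newdata, object$template)
  Z <- enc$mat
  if (ncol(Z) != length(object$feature_means)) {
    abort(sprintf("predict.fohem_elm: expected %d encoded columns, got %d",
                  length(object$feature_means), ncol(Z)))
  }
  Zs <- sweep(sweep(Z, 2, object$feature_means, "-"), 2, object$feature_sds, "/")
  H <- elm_activations(Zs, object$input_weights, object$biases, object$activation)
  as.numeric(object$output_weights[1] + H %*% object$output_weights[-1])
}
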