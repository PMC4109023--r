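#' @name pls
#' @title Partial least-squares models for thrombus type
#'
#' @description
#' NIPALS partial least-squares regression of a numeric thrombus-type
#' response (1/2/3) on a predictor matrix — either measured thrombus
#' parameters or the binary receptor assignment matrix — with 2-3 component
#' models, ordinal prediction by rounding, confusion matrices and
#' leave-one-out cross-validation. With as many components as the predictor
#' rank, PLS coefficients coincide with the ordinary least-squares solution,
#' which anchors the implementation's correctness.
NULL

#' Fit a PLS regression model (NIPALS, single response)
#'
#' Sequential component extraction on mean-centered (optionally unit-scaled)
#' predictors: each component's weight vector is the normalized covariance of
#' the deflated predictors with the response, followed by score, loading and
#' deflation steps. Coefficients are reported on the raw predictor scale with
#' an explicit intercept.
#'
#' @param X numeric predictor matrix, no missing values.
#' @param y numeric response (thrombus type codes 1-3, or any numeric).
#' @param n_components number of latent components (>= 1, at most the rank
#'   of the centered predictors).
#' @param scale unit-variance scale the predictor columns (default FALSE:
#'   inputs are already on a common 0-10 or 0/1 scale).
#' @return A `pls_model`: `coefficients` (named, raw scale), `intercept`,
#'   `weights`, `loadings`, `q` (response loadings), `scores`,
#'   `var_explained` (fraction of predictor variance per component),
#'   centering/scaling vectors, `dropped` (zero-variance columns removed,
#'   with a warning), `columns` (training layout).
#' @export
fit_pls <- function(X, y, n_components = 2L, scale = FALSE) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y))
  if (anyNA(X) || anyNA(y)) stop("missing values in X or y", call. = FALSE)
  if (n_components < 1L) stop("n_components must be >= 1", call. = FALSE)
  if (is.null(colnames(X))) colnames(X) <- paste0("X", seq_len(ncol(X)))
  keep <- apply(X, 2, function(v) var(v) > 0)
  dropped <- colnames(X)[!keep]
  if (length(dropped)) {
    warning("dropping zero-variance predictor column(s): ",
            paste(dropped, collapse = ", "), call. = FALSE)
    X <- X[, keep, drop = FALSE]
  }
  x_center <- colMeans(X)
  Xc <- sweep(X, 2, x_center)
  x_scale <- rep(1, ncol(X))
  if (scale) {
    x_scale <- apply(Xc, 2, sd)
    Xc <- sweep(Xc, 2, x_scale, `/`)
  }
  rk <- qr(Xc)$rank
  if (n_components > rk)
    stop("n_components (", n_components, ") exceeds predictor rank (", rk,
         ")", call. = FALSE)
  y_center <- mean(y)
  yc <- y - y_center
  ssx <- sum(Xc^2)
  p <- ncol(Xc)
  W <- P <- matrix(0, p, n_components)
  Tm <- matrix(0, nrow(Xc), n_components)
  q <- varex <- numeric(n_components)
  E <- Xc; f <- yc
  for (a in seq_len(n_components)) {
    w <- drop(crossprod(E, f))
    w <- w / sqrt(sum(w^2))
    t_a <- drop(E %*% w)
    tt <- sum(t_a^2)
    p_a <- drop(crossprod(E, t_a)) / tt
    q[a] <- sum(f * t_a) / tt
    E <- E - tcrossprod(t_a, p_a)
    f <- f - q[a] * t_a
    W[, a] <- w; P[, a] <- p_a; Tm[, a] <- t_a
    varex[a] <- tt * sum(p_a^2) / ssx
  }
  Bstar <- W %*% solve(crossprod(P, W), q)      # centered/scaled scale
  coefs <- drop(Bstar) / x_scale                # raw predictor scale
  names(coefs) <- colnames(X)
  structure(list(coefficients = coefs,
                 intercept = y_center - sum(x_center * coefs),
                 weights = W, loadings = P, q = q, scores = Tm,
                 x_center = x_center, x_scale = x_scale,
                 y_center = y_center, var_explained = varex,
                 n_components = n_components, scale = scale,
                 dropped = dropped, columns = colnames(X)),
            class = "pls_model")
}

#' Predict the continuous response from a PLS model
#'
#' @param object a `pls_model`.
#' @param newdata matrix whose columns match the training layout (columns
#'   dropped at training time are ignored if present).
#' @param ... unused.
#' @return Numeric predictions.
#' @export
predict.pls_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (is.null(colnames(newdata)) && ncol(newdata) == length(object$columns))
    colnames(newdata) <- object$columns
  if (!all(object$columns %in% colnames(newdata)))
    stop("newdata columns do not match the training layout", call. = FALSE)
  X <- newdata[, object$columns, drop = FALSE]
  drop(object$intercept + X %*% object$coefficients)
}

#' Round a continuous prediction to a thrombus type
#'
#' Nearest integer with halves rounding up, clamped to the type range 1-3.
#'
#' @param x numeric predictions.
#' @return Integer classes in `{1, 2, 3}`.
#' @export
round_type <- function(x) as.integer(pmin(3, pmax(1, floor(x + 0.5))))

#' Predict thrombus type classes
#'
#' @param model a `pls_model`.
#' @param X predictor matrix.
#' @return Integer classes in `{1, 2, 3}`.
#' @export
predict_type <- function(model, X) round_type(predict(model, X))

#' Confusion matrix of true versus predicted thrombus types
#'
#' @param true,predicted integer classes in `{1, 2, 3}`.
#' @param source provenance tag (`"fit"` or `"cross-validation"`).
#' @return A `confusion_report`: `table` (3x3, true in rows), `misassigned`
#'   (off-diagonal total), `per_class_errors`, `n`, `source`.
#' @export
confusion <- function(true, predicted, source = "fit") {
  stopifnot(length(true) == length(predicted))
  if (!all(c(true, predicted) %in% 1:3))
    stop("class labels must be in {1, 2, 3}", call. = FALSE)
  tab <- table(factor(true, 1:3), factor(predicted, 1:3),
               dnn = c("true", "predicted"))
  structure(list(table = unclass(tab),
                 misassigned = sum(tab) - sum(diag(tab)),
                 per_class_errors = rowSums(tab) - diag(tab),
                 n = length(true), source = source),
            class = "confusion_report")
}

#' @export
print.confusion_report <- function(x, ...) {
  cat("Confusion matrix (", x$source, "): ", x$misassigned, " of ", x$n,
      " misassigned\n", sep = "")
  print(x$table)
  invisible(x)
}

#' Cross-validated type predictions
#'
#' Refits the PLS model with each unit (or fold) held out and predicts only
#' the held-out units; leave-one-out is the deterministic default for panels
#' of ~52 surfaces.
#'
#' @param X,y as in [fit_pls()].
#' @param n_components latent components per refit.
#' @param scheme `"loo"` (default) or an integer vector of fold labels.
#' @param scale passed to [fit_pls()].
#' @return A `confusion_report` (source `"cross-validation"`) with the
#'   held-out continuous predictions in `$predictions`.
#' @export
crossval <- function(X, y, n_components = 2L, scheme = "loo", scale = FALSE) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  if (n < 3L) stop("need at least three units for cross-validation",
                   call. = FALSE)
  folds <- if (identical(scheme, "loo")) seq_len(n) else as.integer(scheme)
  stopifnot(length(folds) == n)
  pred <- numeric(n)
  for (f in unique(folds)) {
    hold <- which(folds == f)
    fit <- suppressWarnings(
      fit_pls(X[-hold, , drop = FALSE], y[-hold], n_components, scale = scale))
    pred[hold] <- predict(fit, X[hold, , drop = FALSE])
  }
  rep <- confusion(round_type(y), round_type(pred), source = "cross-validation")
  rep$predictions <- pred
  rep
}
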