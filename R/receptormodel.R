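#' @name receptormodel
#' @title Receptor contribution models and subtraction heatmaps
#'
#' @description
#' Links the binary surface-by-receptor assignment matrix to the thrombus
#' type each surface produces: a PLS regression of type on receptor
#' engagement yields a beta-weight matrix attributing type III thrombus
#' formation to individual receptors (negative weights mark receptors unable
#' to contribute). Companion tools rebuild the model for low-shear data —
#' separately scaled or with a named receptor excluded — and compare two
#' matched condition matrices cell by cell with subtraction heatmaps and
#' two-tailed Student's t-tests.
NULL

check_assignment <- function(A) {
  A <- as.matrix(A)
  if (!all(A %in% c(0, 1)))
    stop("assignment matrix must be binary (0/1)", call. = FALSE)
  if (any(rowSums(A) == 0))
    stop("every surface must engage at least one receptor", call. = FALSE)
  if (is.null(colnames(A))) colnames(A) <- RECEPTOR_PANEL[seq_len(ncol(A))]
  A
}

#' Receptor beta-weight matrix from the assignment matrix
#'
#' PLS regression of thrombus type (1/2/3) on binary receptor engagement.
#' The fitted coefficient vector — an intercept plus one weight per receptor
#' — is the beta-weight matrix predicting the contribution of each receptor
#' to type III thrombus formation; receptors never engaged on the panel
#' (all-zero columns) are dropped with a warning and carry no weight.
#'
#' @param A binary surfaces-by-receptors assignment matrix.
#' @param y thrombus type per surface (1/2/3).
#' @param n_components latent components (default 3, the published
#'   high-shear choice; use 2 for the low-shear refit).
#' @param shear optional shear-rate tag stored in the result (s^-1).
#' @param scale passed to [fit_pls()].
#' @return A `beta_weights` object: `beta` (data frame `term`, `weight`,
#'   intercept first), `model` (the `pls_model`), `confusion`
#'   (resubstitution [confusion()] report), `var_explained` (cumulative
#'   predictor variance), `shear`, `n_surfaces`.
#' @export
receptor_beta <- function(A, y, n_components = 3L, shear = NA, scale = FALSE) {
  A <- check_assignment(A)
  y <- as.numeric(y)
  if (any(y < 1 | y > 3))
    stop("y must code thrombus types 1-3", call. = FALSE)
  keep <- colSums(A) > 0
  rk <- qr(sweep(A[, keep, drop = FALSE], 2,
                 colMeans(A[, keep, drop = FALSE])))$rank
  if (n_components > rk)
    stop("assignment matrix rank (", rk, ") cannot support ", n_components,
         " components; try n_components = ", rk, call. = FALSE)
  model <- fit_pls(A, y, n_components, scale = scale)
  beta <- data.frame(term = c("intercept", model$columns),
                     weight = c(model$intercept, unname(model$coefficients)))
  conf <- confusion(round_type(y), predict_type(model, A))
  structure(list(beta = beta, model = model, confusion = conf,
                 var_explained = sum(model$var_explained),
                 shear = shear, n_surfaces = nrow(A)),
            class = "beta_weights")
}

#' @export
print.beta_weights <- function(x, ...) {
  cat("Receptor beta-weight matrix",
      if (!is.na(x$shear)) paste0(" (shear ", x$shear, " s-1)"), ": ",
      x$n_surfaces, " surfaces, ", x$model$n_components,
      " components (", round(100 * x$var_explained), "% of variance)\n",
      sep = "")
  print(x$beta, row.names = FALSE)
  invisible(x)
}

#' Rebuild the receptor model for low-shear data
#'
#' Two published variants: `"separate_scaled"` refits the model on the
#' low-shear surfaces with their own centering and scaling;
#' `"exclude_receptor"` removes a named receptor's column (e.g. GPIb, whose
#' contribution vanishes at venous shear) before refitting.
#'
#' @param A low-shear assignment matrix.
#' @param y low-shear thrombus types.
#' @param mode `"separate_scaled"` or `"exclude_receptor"`.
#' @param receptor receptor name to exclude (for `"exclude_receptor"`).
#' @param n_components latent components (default 2, the published
#'   low-shear choice).
#' @param shear shear tag (default 150).
#' @param ... passed to [receptor_beta()].
#' @return A `beta_weights` object.
#' @export
refit_lowshear <- function(A, y, mode = c("separate_scaled",
                                          "exclude_receptor"),
                           receptor = NULL, n_components = 2L, shear = 150,
                           ...) {
  mode <- match.arg(mode)
  A <- check_assignment(A)
  if (mode == "exclude_receptor") {
    if (is.null(receptor) || !receptor %in% colnames(A))
      stop("unknown receptor: ", receptor %||% "<missing>", call. = FALSE)
    A <- A[, colnames(A) != receptor, drop = FALSE]
  }
  receptor_beta(A, y, n_components = n_components, shear = shear, ...)
}

# per-cell pooled (or Welch) two-sided t-test between two replicate groups
cell_t_test <- function(a, b, welch = FALSE) {
  if (length(a) < 2L || length(b) < 2L) return(NA_real_)
  if (sd(a) == 0 && sd(b) == 0)
    return(if (mean(a) == mean(b)) 1 else 0)
  t.test(a, b, var.equal = !welch)$p.value
}

tidy_cells <- function(reps, what) {
  need <- c("surface", "parameter", "value")
  if (!all(need %in% names(reps)))
    stop(what, " must have columns surface, parameter, value", call. = FALSE)
  split(reps$value, list(factor(reps$parameter, unique(reps$parameter)),
                         factor(reps$surface, unique(reps$surface))),
        drop = FALSE)
}

#' Subtraction heatmap of two matched condition matrices
#'
#' Per-cell differences between two surfaces-by-parameters conditions (e.g.
#' with versus without vWF co-coating, or high versus low wall shear rate),
#' with a two-tailed Student's t-test per cell on the replicate values and a
#' significance mask at `alpha`.
#'
#' @param reps_a,reps_b tidy replicate tables (columns `surface`,
#'   `parameter`, `value`, plus any replicate identifier) for conditions A
#'   and B; both must cover the same surface x parameter layout.
#' @param alpha significance level (default 0.05).
#' @param welch use Welch's unequal-variance t-test instead of the pooled
#'   Student's test (default FALSE).
#' @return A `subtraction_heatmap`: `difference` (mean A - mean B),
#'   `p_value`, `significant` (logical, `NA` where untestable), `alpha`.
#' @export
subtraction_heatmap <- function(reps_a, reps_b, alpha = 0.05, welch = FALSE) {
  surfaces <- unique(reps_a$surface)
  params <- unique(reps_a$parameter)
  if (!setequal(surfaces, unique(reps_b$surface)) ||
      !setequal(params, unique(reps_b$parameter)))
    stop("condition layouts do not match (surfaces/parameters differ)",
         call. = FALSE)
  dims <- list(surfaces, params)
  diff_m <- p_m <- matrix(NA_real_, length(surfaces), length(params),
                          dimnames = dims)
  for (s in surfaces) for (p in params) {
    a <- reps_a$value[reps_a$surface == s & reps_a$parameter == p]
    b <- reps_b$value[reps_b$surface == s & reps_b$parameter == p]
    if (!length(a) || !length(b))
      stop("missing cell (", s, ", ", p, ") in one condition", call. = FALSE)
    diff_m[s, p] <- mean(a) - mean(b)
    p_m[s, p] <- cell_t_test(a, b, welch)
  }
  structure(list(difference = diff_m, p_value = p_m,
                 significant = p_m < alpha, alpha = alpha, welch = welch),
            class = "subtraction_heatmap")
}
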