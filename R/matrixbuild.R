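#' @name matrixbuild
#' @title Parameter-matrix assembly, 0-10 normalization and variability
#'
#' @description
#' Assembles per-surface parameter matrices from replicate flow runs,
#' linearly normalizes every parameter to the common 0-10 scale used for
#' clustering and heatmaps, quantifies intra- versus inter-individual
#' variability (coefficients of variation), and measures how strongly each
#' parameter determines the thrombus type.
NULL

#' Aggregate replicate runs into a surfaces-by-parameters matrix
#'
#' @param runs tidy data frame with columns `surface`, `parameter`, `run`,
#'   `value` (additional columns are ignored). Each (surface, parameter, run)
#'   key must be unique.
#' @return A `parameter_matrix`: matrices `mean`, `sd` (`NA` for single-run
#'   cells) and `n` over surfaces (rows, in order of first appearance) and
#'   parameters (columns).
#' @export
aggregate_replicates <- function(runs) {
  need <- c("surface", "parameter", "run", "value")
  if (!all(need %in% names(runs)))
    stop("runs must have columns surface, parameter, run, value", call. = FALSE)
  key <- paste(runs$surface, runs$parameter, runs$run, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (surface, parameter, run) keys in replicate table",
         call. = FALSE)
  surfaces <- unique(runs$surface)
  params <- unique(runs$parameter)
  cell <- function(f) {
    m <- matrix(NA_real_, length(surfaces), length(params),
                dimnames = list(surfaces, params))
    agg <- aggregate(runs$value,
                     list(surface = runs$surface, parameter = runs$parameter), f)
    m[cbind(match(agg$surface, surfaces), match(agg$parameter, params))] <- agg$x
    m
  }
  structure(list(mean = cell(mean),
                 sd = cell(function(v) if (length(v) > 1L) sd(v) else NA_real_),
                 n = cell(length)),
            class = "parameter_matrix")
}

#' Linearly normalize parameters to the 0-10 scale
#'
#' Column-wise min-max scaling across surfaces: `x -> 10 * (x - min) /
#' (max - min)`, so within each parameter the least active surface maps to 0
#' and the most active to 10. A degenerate column (no dynamic range) maps to
#' all zeros with a warning. Frozen `bounds` from a reference panel may be
#' supplied to place new (e.g. patient) data on the reference scale, in which
#' case values may legitimately fall outside `[0, 10]`.
#'
#' @param x numeric matrix (surfaces x parameters) or a `parameter_matrix`
#'   (its `mean` slot is used).
#' @param bounds optional frozen bounds: a list with numeric vectors `min`
#'   and `max` per parameter, as produced by a previous call (stored in
#'   `attr(, "bounds")`).
#' @return Normalized matrix with the bounds used in `attr(, "bounds")`.
#' @export
normalize_matrix <- function(x, bounds = NULL) {
  if (inherits(x, "parameter_matrix")) x <- x$mean
  if (!is.matrix(x) || !is.numeric(x))
    stop("x must be a numeric matrix", call. = FALSE)
  if (anyNA(x)) stop("missing cells in parameter matrix", call. = FALSE)
  intrinsic <- is.null(bounds)
  if (intrinsic) {
    bounds <- list(min = apply(x, 2, min), max = apply(x, 2, max))
  } else {
    stopifnot(length(bounds$min) == ncol(x), length(bounds$max) == ncol(x))
  }
  out <- x
  for (j in seq_len(ncol(x))) {
    rng <- bounds$max[j] - bounds$min[j]
    if (rng <= 0) {
      warning("parameter ", colnames(x)[j] %||% j,
              " has no dynamic range; normalized to 0", call. = FALSE)
      out[, j] <- 0
    } else {
      v <- 10 * (x[, j] - bounds$min[j]) / rng
      # with intrinsic bounds the range is [0, 10] by construction; guard
      # against floating-point overshoot at the column extremes
      if (intrinsic) v <- pmin(10, pmax(0, v))
      out[, j] <- v
    }
  }
  attr(out, "bounds") <- bounds
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Intra- versus inter-individual variability
#'
#' For each parameter, the intra-individual CV is the within-subject
#' between-day coefficient of variation, averaged over subjects and pooled
#' over surfaces by unweighted mean; the inter-individual CV is the
#' between-subject s.d. of subject means relative to the grand mean, pooled
#' over surfaces the same way. Their ratio summarizes assay reproducibility
#' relative to biological variation.
#'
#' @param cohort tidy data frame with columns `subject`, `day`, `surface`,
#'   `parameter`, `value`; at least 2 subjects and 2 days per subject.
#' @return A `variability_report` data frame: `parameter`, `intra_cv`,
#'   `inter_cv`, `ratio` (inter/intra, `NA` when intra is 0).
#' @export
compute_cv <- function(cohort) {
  need <- c("subject", "day", "surface", "parameter", "value")
  if (!all(need %in% names(cohort)))
    stop("cohort must have columns subject, day, surface, parameter, value",
         call. = FALSE)
  if (length(unique(cohort$subject)) < 2L)
    stop("need at least two subjects", call. = FALSE)
  if (length(unique(cohort$day)) < 2L)
    stop("need at least two days", call. = FALSE)
  out <- lapply(split(cohort, cohort$parameter), function(d) {
    if (abs(mean(d$value)) < .Machine$double.eps)
      stop("zero grand mean for parameter '", d$parameter[1],
           "'; CV undefined", call. = FALSE)
    # within-subject CV per (surface, subject), then averaged
    sub_mean <- aggregate(value ~ surface + subject, d, mean)
    sub_sd <- aggregate(value ~ surface + subject, d, sd)
    intra_cells <- 100 * sub_sd$value / sub_mean$value
    intra_surf <- tapply(intra_cells, sub_mean$surface, mean)
    # between-subject CV per surface over subject means
    inter_surf <- tapply(seq_len(nrow(sub_mean)), sub_mean$surface, function(i)
      100 * sd(sub_mean$value[i]) / mean(sub_mean$value[i]))
    data.frame(parameter = d$parameter[1L],
               intra_cv = mean(intra_surf), inter_cv = mean(inter_surf))
  })
  rep <- do.call(rbind, out)
  rownames(rep) <- NULL
  rep$ratio <- ifelse(rep$intra_cv > 0, rep$inter_cv / rep$intra_cv, NA_real_)
  class(rep) <- c("variability_report", "data.frame")
  rep
}

#' Per-parameter determination of thrombus type
#'
#' Simple linear regression of the type code (1/2/3) on each normalized
#' parameter across surfaces, reporting R-squared and the two-sided p-value
#' of the slope; the joint multiple regression of type on all parameters is
#' reported alongside.
#'
#' @param m normalized surfaces-by-parameters matrix.
#' @param types integer type labels (1, 2, 3), one per surface.
#' @return Data frame `parameter`, `r_squared`, `p_value`, with the joint
#'   model's R-squared in `attr(, "joint_r_squared")`.
#' @export
parameter_determination <- function(m, types) {
  if (inherits(m, "parameter_matrix")) m <- m$mean
  stopifnot(is.matrix(m), length(types) == nrow(m))
  if (nrow(m) < 3L) stop("need at least three surfaces", call. = FALSE)
  y <- as.numeric(types)
  per <- lapply(seq_len(ncol(m)), function(j) {
    fit <- summary(lm(y ~ m[, j]))
    data.frame(parameter = colnames(m)[j] %||% paste0("param", j),
               r_squared = fit$r.squared,
               p_value = fit$coefficients[2L, 4L])
  })
  out <- do.call(rbind, per)
  joint <- summary(lm(y ~ m))
  attr(out, "joint_r_squared") <- joint$r.squared
  out
}
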