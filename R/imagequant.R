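#' @name imagequant
#' @title Standardized image quantification of thrombus formation
#'
#' @description
#' The image-analysis operators that turn end-stage phase-contrast images,
#' fluorescence time series and confocal z-stacks into the eight
#' thrombus-formation parameters: platelet deposition (% surface area
#' coverage), integrated feature size, morphological score, stable platelet
#' adhesion, fibrinogen binding, P-selectin expression (with non-specific
#' label correction), thrombus volume per unit area, and procoagulant
#' activity. The segmentation pipeline is fixed: contrast auto-enhancement,
#' separable horizontal/vertical median filtering, thresholding (Otsu by
#' default), then a binary close-and-open filter.
NULL

# linear percentile stretch (1st-99th) to the full 8-bit range; skipped when
# the percentiles coincide (no dynamic range)
stretch_percentile <- function(x, lower = 0.01, upper = 0.99) {
  q <- quantile(x, c(lower, upper), names = FALSE, type = 7)
  if (q[2] <= q[1]) return(x)
  pmin(pmax((x - q[1]) / (q[2] - q[1]) * 255, 0), 255)
}

# separable 1-D running-median filter (length 3), rows then columns
median_filter_hv <- function(x, k = 3L) {
  if (nrow(x) > k) x <- apply(x, 2, runmed, k = k, endrule = "median")
  if (ncol(x) > k) x <- t(apply(x, 1, runmed, k = k, endrule = "median"))
  x
}

otsu_threshold <- function(x) {
  rng <- range(x)
  if (rng[1] == rng[2]) return(NA_real_)
  255 * EBImage::otsu(EBImage::Image(x / 255), range = c(0, 1), levels = 256L)
}

close_open <- function(mask, brush_size = 3L) {
  kern <- EBImage::makeBrush(brush_size, shape = "box")
  y <- EBImage::opening(EBImage::closing(EBImage::Image(mask), kern), kern)
  m <- (EBImage::imageData(y) > 0.5) + 0L
  dim(m) <- dim(mask)
  m
}

#' Segment platelet deposition and measure surface area coverage
#'
#' Fixed pipeline: contrast auto-enhancement (linear 1st-99th percentile
#' stretch), separable horizontal and vertical median filtering (length 3),
#' thresholding, and a binary close-then-open filter (3x3 box). With
#' `method = "fixed"` the threshold refers to raw intensities, so the
#' enhancement step is skipped. A constant image under Otsu has no foreground
#' by convention (coverage 0).
#'
#' @param image single-channel intensity matrix (8-bit scale).
#' @param method `"otsu"` (default) or `"fixed"`.
#' @param threshold fixed intensity cut-off, required when `method = "fixed"`.
#' @param enhance,median_filter,morphology logical switches for the
#'   individual pipeline stages (all on by default).
#' @param brush_size structuring-element size for close/open (default 3).
#' @return A list: `mask` (0/1 integer matrix), `coverage` (percent of the
#'   field), `threshold` (the cut actually applied, `NA` for a constant
#'   image).
#' @export
segment_coverage <- function(image, method = c("otsu", "fixed"),
                             threshold = NULL, enhance = TRUE,
                             median_filter = TRUE, morphology = TRUE,
                             brush_size = 3L) {
  method <- match.arg(method)
  check_image(image)
  x <- image
  if (method == "otsu" && enhance) x <- stretch_percentile(x)
  if (median_filter) x <- median_filter_hv(x)
  if (method == "fixed") {
    if (is.null(threshold)) stop("method 'fixed' needs a threshold", call. = FALSE)
    t_used <- threshold
  } else {
    t_used <- otsu_threshold(x)
  }
  mask <- if (is.na(t_used)) matrix(0L, nrow(x), ncol(x)) else (x > t_used) + 0L
  if (morphology && any(mask == 1L)) mask <- close_open(mask, brush_size)
  list(mask = mask, coverage = 100 * sum(mask) / length(mask),
       threshold = t_used)
}

#' Connected-component feature areas
#'
#' Labels regions of single or clustered adhered platelets in a binary mask
#' and returns their pixel areas ranked from small to large.
#'
#' @param mask 0/1 matrix.
#' @param connectivity 4 or 8 (default 8).
#' @param pixel_size optional pixel edge length in micrometres; when given,
#'   areas are reported in um^2.
#' @return A `feature_set`: `areas` (ascending), `N`, `total`, `unit`.
#' @export
feature_areas <- function(mask, connectivity = 8L, pixel_size = NULL) {
  check_image(mask, "mask")
  if (!all(mask %in% c(0, 1))) stop("mask must be binary", call. = FALSE)
  lab <- .label_components(matrix(as.integer(mask), nrow(mask)),
                           as.integer(connectivity))
  areas <- if (max(lab) > 0) sort(as.numeric(tabulate(lab[lab > 0]))) else numeric(0)
  unit <- "px"
  if (!is.null(pixel_size)) {
    areas <- areas * pixel_size^2
    unit <- "um2"
  }
  structure(list(areas = areas, N = length(areas), total = sum(areas),
                 unit = unit),
            class = "feature_set")
}

#' Integrated feature size
#'
#' Size-weighted mean feature area: the cumulative contribution of squared
#' feature areas, ranked from small to large, to the total feature area —
#' `sum(f^2) / sum(f)`. Large aggregates dominate; a field of equal-size
#' features of area A has IFS exactly A. Empty fields return 0 by convention.
#'
#' @param fs a [feature_areas()] result, or a bare numeric vector of areas.
#' @return The integrated feature size, in the unit of the input areas.
#' @export
integrated_feature_size <- function(fs) {
  areas <- if (inherits(fs, "feature_set")) fs$areas else as.numeric(fs)
  if (length(areas) == 0) return(0)
  if (any(areas < 0)) stop("feature areas must be positive", call. = FALSE)
  sum(areas^2) / sum(areas)
}

#' Calibration for the morphological score rubric
#'
#' Cut-offs for the 0-5 rubric: `min_coverage_pct` below which a field counts
#' as empty (score 0), `extensive_coverage_pct` separating sparse from
#' extensive single-platelet coverage (scores 1 vs 2), and feature-area cuts
#' (pixels) separating single platelets from small, intermediate and large
#' aggregates (scores 3/4/5).
#'
#' @param min_coverage_pct,extensive_coverage_pct coverage cut-offs (%).
#' @param single_platelet_px,small_aggregate_px,large_aggregate_px
#'   largest-feature area cut-offs (pixels), strictly increasing.
#' @return A `score_calibration` list.
#' @export
score_calibration <- function(min_coverage_pct = 0.5,
                              extensive_coverage_pct = 10,
                              single_platelet_px = 50,
                              small_aggregate_px = 500,
                              large_aggregate_px = 2000) {
  cuts <- c(single_platelet_px, small_aggregate_px, large_aggregate_px)
  if (any(diff(cuts) <= 0) || min_coverage_pct >= extensive_coverage_pct)
    stop("score calibration cut-offs must be strictly increasing",
         call. = FALSE)
  structure(list(min_coverage_pct = min_coverage_pct,
                 extensive_coverage_pct = extensive_coverage_pct,
                 single_platelet_px = single_platelet_px,
                 small_aggregate_px = small_aggregate_px,
                 large_aggregate_px = large_aggregate_px),
            class = "score_calibration")
}

#' Morphological score (0-5)
#'
#' Deterministic proxy for the visual rubric: 0, no or hardly any adhered
#' platelets; 1, multiple single platelets; 2, extensive coverage of single
#' platelets; 3, small aggregates; 4, intermediate aggregates; 5, full
#' thrombi with large aggregates. Scores 0-2 are decided by coverage with all
#' features below the single-platelet area cut; 3-5 by the largest feature's
#' area.
#'
#' @param mask binary platelet-deposition mask.
#' @param fs feature set (default computed from `mask` at 8-connectivity).
#' @param calibration a [score_calibration()].
#' @return Integer score in 0..5.
#' @export
morphological_score <- function(mask, fs = feature_areas(mask),
                                calibration = score_calibration()) {
  check_image(mask, "mask")
  stopifnot(inherits(calibration, "score_calibration"))
  coverage <- 100 * sum(mask != 0) / length(mask)
  if (coverage < calibration$min_coverage_pct || fs$N == 0L) return(0L)
  largest <- max(fs$areas)
  if (largest <= calibration$single_platelet_px)
    return(if (coverage < calibration$extensive_coverage_pct) 1L else 2L)
  if (largest <= calibration$small_aggregate_px) return(3L)
  if (largest <= calibration$large_aggregate_px) return(4L)
  5L
}

#' Stable platelet adhesion from a fluorescence time series
#'
#' Frame-to-frame differential images identify pixels whose intensity changes
#' during flow; a pixel counts as stably adhered when it is above background
#' in at least `persistence` of the frames and its mean absolute differential
#' stays below `change_threshold`. The value is the stable pixel fraction of
#' the field, in percent.
#'
#' @param series a `synthetic_series` or a list of equally-shaped frames.
#' @param background intensity cut separating platelet signal from
#'   background; default is the Otsu threshold of the temporal mean frame.
#' @param persistence required fraction of frames above background
#'   (default 1: all frames).
#' @param change_threshold maximum mean absolute frame-to-frame change for a
#'   stable pixel; default a quarter of the series' dynamic range.
#' @return Stable adhesion in percent of the field area.
#' @export
stable_adhesion <- function(series, background = NULL, persistence = 1,
                            change_threshold = NULL) {
  frames <- if (inherits(series, "synthetic_series")) series$frames else series
  if (length(frames) < 2L) stop("need at least two frames", call. = FALSE)
  dims <- dim(frames[[1L]])
  if (!all(vapply(frames, function(f) identical(dim(f), dims), logical(1))))
    stop("all frames must have identical dimensions", call. = FALSE)
  arr <- simplify2array(frames)
  if (is.null(background)) {
    background <- otsu_threshold(rowMeans(arr, dims = 2L))
    if (is.na(background)) return(0)
  }
  if (is.null(change_threshold))
    change_threshold <- 0.25 * (max(arr) - min(arr))
  nf <- length(frames)
  above <- arr > background
  n_above <- rowSums(above, dims = 2L)
  dmean <- rowMeans(abs(arr[, , -1L, drop = FALSE] -
                          arr[, , -nf, drop = FALSE]), dims = 2L)
  stable <- n_above >= persistence * nf & dmean <= change_threshold
  100 * sum(stable) / prod(dims)
}

#' Thrombus volume per unit surface area from a confocal z-stack
#'
#' Thresholds each optical section and counts occupied voxels; the summed
#' volume is normalized by the field area, giving um^3 per um^2 (equivalently
#' the mean occupied height in um). Under the automatic policy a single Otsu
#' threshold is computed on the bottom slice — where all thrombi are present —
#' and applied to every slice, so empty top slices cannot be
#' over-thresholded.
#'
#' @param stack a `synthetic_stack` or list of slice matrices, bottom first.
#' @param slice_spacing stack distance in micrometres (taken from a
#'   `synthetic_stack` when omitted).
#' @param pixel_size pixel edge length in micrometres (idem).
#' @param threshold fixed intensity cut; default Otsu on the bottom slice.
#' @param median_filter apply the separable median filter per slice.
#' @return Volume per unit area in um^3/um^2.
#' @export
thrombus_volume <- function(stack, slice_spacing = NULL, pixel_size = NULL,
                            threshold = NULL, median_filter = FALSE) {
  if (inherits(stack, "synthetic_stack")) {
    if (is.null(slice_spacing)) slice_spacing <- stack$slice_spacing
    if (is.null(pixel_size)) pixel_size <- stack$pixel_size
    stack <- stack$slices
  }
  if (length(stack) < 2L) stop("need at least two slices", call. = FALSE)
  if (is.null(slice_spacing) || slice_spacing <= 0)
    stop("slice_spacing must be positive", call. = FALSE)
  if (!is.null(pixel_size) && pixel_size <= 0)
    stop("pixel_size must be positive", call. = FALSE)
  slices <- if (median_filter) lapply(stack, median_filter_hv) else stack
  if (is.null(threshold)) threshold <- otsu_threshold(slices[[1L]])
  if (is.na(threshold)) return(0)
  occupied <- vapply(slices, function(s) sum(s > threshold), numeric(1))
  sum(occupied) * slice_spacing / length(slices[[1L]])
}

#' Fluorescence marker coverage with non-specific label correction
#'
#' Thresholded surface-area coverage of an activation marker (fibrinogen
#' binding, P-selectin expression, annexin A5 binding), optionally corrected
#' by subtracting the coverage of a non-specific labelling control, floored
#' at zero.
#'
#' @param image fluorescence intensity matrix.
#' @param nonspecific_control a control image, or a scalar control coverage
#'   in percent.
#' @param ... passed to [segment_coverage()].
#' @return Marker coverage in percent.
#' @export
marker_coverage <- function(image, nonspecific_control = NULL, ...) {
  cov <- segment_coverage(image, ...)$coverage
  if (!is.null(nonspecific_control)) {
    ctrl <- if (is.matrix(nonspecific_control))
      segment_coverage(nonspecific_control, ...)$coverage
    else as.numeric(nonspecific_control)
    if (ctrl > 100)
      stop("control coverage cannot exceed 100%", call. = FALSE)
    cov <- max(0, cov - ctrl)
  }
  cov
}
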