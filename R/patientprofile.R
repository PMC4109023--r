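#' @name patientprofile
#' @title Patient deviation profiling against healthy reference ranges
#'
#' @description
#' Compares a patient's surface-by-parameter thrombus profile with reference
#' ranges from healthy control subjects: per-cell means and between-subject
#' standard deviations define a normal band, a significance map flags patient
#' cells outside mean +/- 2 s.d. (reduced = -1, increased = +1), per-cell
#' t-tests compare patient and control replicates, and deviation summaries
#' count reduced/increased parameters per patient.
NULL

#' Reference ranges from a healthy-control cohort
#'
#' Aggregates to subject level first (mean over a subject's days/runs per
#' cell), then takes the mean and between-subject s.d. over subjects, so the
#' reference band reflects inter-individual variation in the healthy
#' population rather than replicate noise.
#'
#' @param controls tidy data frame with columns `subject`, `surface`,
#'   `parameter`, `value` (day/run columns are averaged out per subject).
#' @return A `reference_range`: matrices `mean`, `sd` (`NA` where fewer than
#'   2 subjects), `n` (subjects per cell), over surfaces x parameters.
#' @export
reference_ranges <- function(controls) {
  need <- c("subject", "surface", "parameter", "value")
  if (!all(need %in% names(controls)))
    stop("controls must have columns subject, surface, parameter, value",
         call. = FALSE)
  if (length(unique(controls$subject)) < 2L)
    stop("need at least two control subjects", call. = FALSE)
  sub <- aggregate(value ~ subject + surface + parameter, controls, mean)
  surfaces <- unique(controls$surface)
  params <- unique(controls$parameter)
  shape <- function(f) {
    m <- matrix(NA_real_, length(surfaces), length(params),
                dimnames = list(surfaces, params))
    agg <- aggregate(sub$value,
                     list(surface = sub$surface, parameter = sub$parameter), f)
    m[cbind(match(agg$surface, surfaces), match(agg$parameter, params))] <- agg$x
    m
  }
  structure(list(mean = shape(mean),
                 sd = shape(function(v) if (length(v) > 1L) sd(v) else NA_real_),
                 n = shape(length)),
            class = "reference_range")
}

# accept a patient value matrix, or a tidy run table aggregated to cell means
patient_matrix <- function(patient, ref) {
  if (is.matrix(patient)) {
    if (!identical(dim(patient), dim(ref$mean)))
      stop("patient layout does not match the reference layout", call. = FALSE)
    dimnames(patient) <- dimnames(ref$mean)
    return(patient)
  }
  agg <- aggregate(value ~ surface + parameter, patient, mean)
  m <- matrix(NA_real_, nrow(ref$mean), ncol(ref$mean),
              dimnames = dimnames(ref$mean))
  i <- match(agg$surface, rownames(m)); j <- match(agg$parameter, colnames(m))
  if (anyNA(i) || anyNA(j) || nrow(agg) != length(m))
    stop("patient layout does not match the reference layout", call. = FALSE)
  m[cbind(i, j)] <- agg$value
  m
}

#' Significance map of a patient against the reference band
#'
#' Flags each surface x parameter cell -1 when the patient value lies below
#' the control mean minus `sd_multiplier` between-subject s.d., +1 when above
#' the mean plus `sd_multiplier` s.d., 0 otherwise. Cells whose reference
#' s.d. is unavailable are `NA` (untestable) and excluded from the counts.
#'
#' @param patient patient cell-value matrix matching the reference layout,
#'   or a tidy run table (`surface`, `parameter`, `value`) averaged per cell.
#' @param ref a [reference_ranges()] result.
#' @param sd_multiplier width of the normal band in s.d. units (default 2).
#' @param subject label stored with the map.
#' @return A `significance_map`: `flags` (-1/0/+1/NA matrix), `n_reduced`,
#'   `n_increased`, `n_tested`, `sd_multiplier`, `subject`.
#' @export
significance_map <- function(patient, ref, sd_multiplier = 2,
                             subject = "patient") {
  stopifnot(inherits(ref, "reference_range"), sd_multiplier > 0)
  pm <- patient_matrix(patient, ref)
  lower <- ref$mean - sd_multiplier * ref$sd
  upper <- ref$mean + sd_multiplier * ref$sd
  flags <- matrix(0L, nrow(pm), ncol(pm), dimnames = dimnames(pm))
  flags[pm < lower] <- -1L
  flags[pm > upper] <- 1L
  flags[is.na(ref$sd)] <- NA_integer_
  structure(list(flags = flags,
                 n_reduced = sum(flags == -1L, na.rm = TRUE),
                 n_increased = sum(flags == 1L, na.rm = TRUE),
                 n_tested = sum(!is.na(flags)),
                 sd_multiplier = sd_multiplier, subject = subject),
            class = "significance_map")
}

#' @export
print.significance_map <- function(x, ...) {
  cat("Significance map for ", x$subject, " (mean +/- ", x$sd_multiplier,
      " s.d.): ", x$n_reduced, " reduced, ", x$n_increased, " increased of ",
      x$n_tested, " tested cells\n", sep = "")
  invisible(x)
}

#' Patient-versus-control subtraction heatmap
#'
#' Per-cell difference between patient and control replicate values with a
#' two-tailed Student's t-test (pooled variance; Welch optional) and a
#' significance mask at `alpha`. Cells with fewer than two replicates on
#' either side are untestable (`NA` p-value).
#'
#' @param patient_reps,control_reps tidy replicate tables (`surface`,
#'   `parameter`, `value`).
#' @param alpha significance level (default 0.05, per-cell, uncorrected).
#' @param welch use Welch's t-test (default FALSE).
#' @return A `subtraction_heatmap` (difference = patient - control).
#' @export
patient_subtraction <- function(patient_reps, control_reps, alpha = 0.05,
                                welch = FALSE) {
  subtraction_heatmap(patient_reps, control_reps, alpha = alpha, welch = welch)
}

#' Deviation counts for a patient profile
#'
#' Tallies reduced and increased cells from a [significance_map()] or from a
#' [subtraction_heatmap()] (where reduced/increased means a significantly
#' negative/positive difference).
#'
#' @param map a `significance_map` or `subtraction_heatmap`.
#' @return A list: `reduced`, `increased`, `tested`.
#' @export
deviation_summary <- function(map) {
  if (inherits(map, "significance_map")) {
    return(list(reduced = map$n_reduced, increased = map$n_increased,
                tested = map$n_tested))
  }
  if (inherits(map, "subtraction_heatmap")) {
    sig <- map$significant
    return(list(reduced = sum(sig & map$difference < 0, na.rm = TRUE),
                increased = sum(sig & map$difference > 0, na.rm = TRUE),
                tested = sum(!is.na(sig))))
  }
  stop("map must be a significance_map or subtraction_heatmap", call. = FALSE)
}
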