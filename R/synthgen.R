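#' @name synthgen
#' @title Synthetic flow-assay data with known ground truth
#'
#' @description
#' Generators for every input the thrombus-formation pipeline consumes:
#' microscopy scenes of adhered-platelet fields, time series with stable and
#' transient platelet populations, confocal z-stacks with known summed
#' heights, multi-surface parameter matrices with a planted three-type
#' structure, binary receptor designs with planted regression weights, and
#' control/patient cohorts with separate intra- and inter-individual variance
#' components. Each generator is a pure function of its arguments plus a
#' mandatory seed, and records the ground truth it planted so downstream
#' measurements can be checked against it.
NULL

# run expr under a local RNG stream; the caller's RNG state is untouched
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(check_seed(seed))
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, globalenv())
  })
  expr
}

# render an 8-bit intensity grid: background level plus shared Gaussian noise
# field; foreground pixels lifted by (foreground - background)
render_scene <- function(mask, background, foreground, noise_sd) {
  dims <- dim(mask)
  noise <- matrix(if (noise_sd > 0) rnorm(prod(dims), 0, noise_sd) else 0,
                  dims[1], dims[2])
  bg <- background + noise
  grid <- bg + (foreground - background) * mask
  list(pixel_grid = pmin(pmax(round(grid), 0), 255),
       background_grid = pmin(pmax(round(bg), 0), 255))
}

#' Generate a synthetic platelet-field scene
#'
#' Places rectangular "platelet features" (single platelets to aggregates) on
#' an 8-bit intensity grid without overlap, records the exact binary truth
#' mask and the per-feature pixel areas, and renders foreground/background
#' intensities with optional Gaussian noise. In `mode = "aggregate"` features
#' may overlap and the truth areas are those of the merged connected
#' components.
#'
#' Features are kept at least two pixels apart (in `"separate"` mode) so that
#' the segmentation pipeline's 3x3 morphology and length-3 median filtering
#' can never merge distinct features.
#'
#' @param n_features number of features to place.
#' @param dim image dimensions in pixels, default `c(512, 512)`.
#' @param area_meanlog,area_sdlog lognormal parameters of the feature-area
#'   distribution (pixels); sides are clamped to >= 3 px.
#' @param background,foreground mean intensities on the 8-bit scale.
#' @param noise_sd Gaussian noise s.d. (intensity units); 0 gives a noise-free
#'   scene on which Otsu segmentation is exact.
#' @param pixel_size physical pixel size in micrometres (106/512 um default,
#'   matching a 106x106 um confocal field at 512x512).
#' @param mode `"separate"` (non-overlapping, default) or `"aggregate"`
#'   (overlaps allowed, merged components recorded as truth).
#' @param max_tries rejection-sampling budget for feature placement.
#' @param seed integer seed (required).
#'
#' @return An object of class `synthetic_scene`: `pixel_grid`,
#'   `background_grid`, `truth_mask` (0/1 integer matrix), `truth_features`
#'   (component pixel areas, ascending), `truth_coverage`, `pixel_size`,
#'   `seed`, and the rendering parameters.
#' @export
gen_scene <- function(n_features, dim = c(512L, 512L),
                      area_meanlog = log(150), area_sdlog = 0.6,
                      background = 20, foreground = 80, noise_sd = 5,
                      pixel_size = 106 / 512,
                      mode = c("separate", "aggregate"),
                      max_tries = 10000L, seed) {
  mode <- match.arg(mode)
  seed <- check_seed(seed)
  stopifnot(length(dim) == 2L, all(dim >= 8L), n_features >= 0L)
  with_seed(seed, {
    nr <- dim[1]; nc <- dim[2]
    mask <- matrix(0L, nr, nc)
    if (n_features > 0) {
      areas <- pmax(9, round(stats::rlnorm(n_features, area_meanlog, area_sdlog)))
      if (sum(areas) > 0.7 * nr * nc)
        stop("requested total foreground exceeds 70% of the grid; ",
             "reduce n_features or feature areas", call. = FALSE)
      aspect <- exp(runif(n_features, log(0.5), log(2)))
      h <- pmax(3L, pmin(nr - 6L, round(sqrt(areas * aspect))))
      w <- pmax(3L, pmin(nc - 6L, round(areas / h)))
      occupied <- matrix(FALSE, nr, nc)  # features dilated by the 2-px margin
      tries <- 0L
      for (i in seq_len(n_features)) {
        placed <- FALSE
        while (!placed) {
          tries <- tries + 1L
          if (tries > max_tries)
            stop("could not place ", n_features, " non-overlapping features ",
                 "within ", max_tries, " tries (non-overlap constraint ",
                 "infeasible at this density)", call. = FALSE)
          # keep a 2-px margin from the image border so border-handling in
          # morphological filtering can never clip a feature
          r0 <- 2L + sample.int(nr - h[i] - 3L, 1L)
          c0 <- 2L + sample.int(nc - w[i] - 3L, 1L)
          rr <- r0:(r0 + h[i] - 1L); cc <- c0:(c0 + w[i] - 1L)
          if (mode == "aggregate" || !any(occupied[rr, cc])) {
            mask[rr, cc] <- 1L
            # 3-px separation: a 3x3 closing bridges gaps of up to 2 px, so
            # distinct features must sit at least 3 px apart to stay distinct
            gr <- max(1L, r0 - 3L):min(nr, r0 + h[i] + 2L)
            gc <- max(1L, c0 - 3L):min(nc, c0 + w[i] + 2L)
            occupied[gr, gc] <- TRUE
            placed <- TRUE
          }
        }
      }
    }
    comp <- .label_components(mask, 8L)
    areas_out <- if (max(comp) > 0) sort(as.integer(tabulate(comp[comp > 0]))) else integer(0)
    rend <- render_scene(mask, background, foreground, noise_sd)
    structure(list(pixel_grid = rend$pixel_grid,
                   background_grid = rend$background_grid,
                   truth_mask = mask,
                   truth_features = areas_out,
                   truth_coverage = sum(areas_out) / (nr * nc),
                   pixel_size = pixel_size,
                   background = background, foreground = foreground,
                   noise_sd = noise_sd, mode = mode, seed = seed),
              class = "synthetic_scene")
  })
}

#' Generate a fluorescence time series with stable and transient platelets
#'
#' Splits the features of a scene into a stable population, present in every
#' frame, and transient features that appear and disappear during the run
#' (emulating platelets that detach or embolize under flow). The stable
#' population is chosen greedily so its pixel area is as close as possible to
#' `stable_fraction` of the total foreground — exact up to one feature's
#' granularity.
#'
#' @param scene a `synthetic_scene`.
#' @param stable_fraction target fraction of foreground pixels present in all
#'   frames, in `[0, 1]`.
#' @param duration_s,interval_s run length and frame spacing in seconds
#'   (defaults 60 s at 2-s intervals); `duration_s` must be a multiple of
#'   `interval_s`.
#' @param seed integer seed (required).
#'
#' @return An object of class `synthetic_series`: `frames` (list of 8-bit
#'   grids), `frame_interval`, `stable_mask`, `transient_events` (list of
#'   `pixels`/`appear`/`disappear` records), and the achieved
#'   `truth_stable_fraction`.
#' @export
gen_series <- function(scene, stable_fraction, duration_s = 60,
                       interval_s = 2, seed) {
  stopifnot(inherits(scene, "synthetic_scene"))
  if (stable_fraction < 0 || stable_fraction > 1)
    stop("stable_fraction must be in [0, 1]", call. = FALSE)
  if (duration_s %% interval_s != 0)
    stop("duration_s must be a multiple of interval_s", call. = FALSE)
  seed <- check_seed(seed)
  n_frames <- as.integer(duration_s / interval_s)
  comp <- .label_components(scene$truth_mask, 8L)
  n_feat <- max(comp)
  with_seed(seed, {
    areas <- if (n_feat > 0) tabulate(comp[comp > 0]) else integer(0)
    total <- sum(areas)
    ord <- if (n_feat > 0) sample.int(n_feat) else integer(0)
    stable_ids <- integer(0)
    if (total > 0 && stable_fraction > 0) {
      cum <- 0
      target <- stable_fraction * total
      for (i in ord) {
        if (abs(cum + areas[i] - target) <= abs(cum - target)) {
          stable_ids <- c(stable_ids, i); cum <- cum + areas[i]
        }
      }
    }
    stable_mask <- matrix(0L, nrow(comp), ncol(comp))
    stable_mask[comp %in% stable_ids & comp > 0] <- 1L
    transient_ids <- setdiff(seq_len(n_feat), stable_ids)
    events <- lapply(transient_ids, function(i) {
      appear <- sample.int(n_frames, 1L)
      disappear <- sample(appear:n_frames, 1L)
      if (appear == 1L && disappear == n_frames) {
        if (n_frames > 1L) disappear <- n_frames - 1L else appear <- 2L
      }
      list(feature = i, pixels = which(comp == i),
           appear = appear, disappear = disappear)
    })
    frames <- lapply(seq_len(n_frames), function(f) {
      frame <- scene$background_grid
      idx <- which(stable_mask == 1L)
      frame[idx] <- scene$pixel_grid[idx]
      for (ev in events)
        if (f >= ev$appear && f <= ev$disappear)
          frame[ev$pixels] <- scene$pixel_grid[ev$pixels]
      frame
    })
    structure(list(frames = frames, frame_interval = interval_s,
                   stable_mask = stable_mask, transient_events = events,
                   truth_stable_fraction = if (total > 0) sum(stable_mask) / total else 0,
                   scene = scene, seed = seed),
              class = "synthetic_series")
  })
}

#' Generate a confocal z-stack with a known height map
#'
#' Each feature of the scene is given a thrombus height drawn uniformly from
#' 1 to `n_slices` optical sections; a pixel column is occupied contiguously
#' from the bottom slice up to its feature's height, mimicking a
#' DiOC6-labelled thrombus imaged at fixed stack spacing.
#'
#' @param scene a `synthetic_scene`.
#' @param n_slices number of optical sections (default 12).
#' @param slice_spacing stack distance in micrometres (default 0.5).
#' @param seed integer seed (required).
#'
#' @return An object of class `synthetic_stack`: `slices` (bottom-to-top list
#'   of 8-bit grids), `slice_spacing`, `pixel_size`, `truth_height_map` (um)
#'   and `truth_volume_per_area` (um^3 per um^2, the mean of the height map).
#' @export
gen_stack <- function(scene, n_slices = 12L, slice_spacing = 0.5, seed) {
  stopifnot(inherits(scene, "synthetic_scene"), n_slices >= 2L,
            slice_spacing > 0)
  seed <- check_seed(seed)
  comp <- .label_components(scene$truth_mask, 8L)
  n_feat <- max(comp)
  with_seed(seed, {
    feat_h <- if (n_feat > 0) sample.int(n_slices, n_feat, replace = TRUE) else integer(0)
    height_slices <- matrix(0L, nrow(comp), ncol(comp))
    if (n_feat > 0) height_slices[comp > 0] <- feat_h[comp[comp > 0]]
    slices <- lapply(seq_len(n_slices), function(k) {
      m <- (height_slices >= k) + 0L
      render_scene(m, scene$background, scene$foreground, scene$noise_sd)$pixel_grid
    })
    hmap <- height_slices * slice_spacing
    structure(list(slices = slices, slice_spacing = slice_spacing,
                   pixel_size = scene$pixel_size,
                   truth_height_map = hmap,
                   truth_volume_per_area = mean(hmap), seed = seed),
              class = "synthetic_stack")
  })
}

#' Planted truth for a multi-surface parameter matrix
#'
#' Describes a surface panel whose rows fall into three thrombus types with
#' type-specific parameter means. Defaults mirror the study design the
#' pipeline targets: 52 surfaces, 8 parameters, three types whose overall
#' activation is ordered I < II < III, adjacent type means separated by four
#' noise standard deviations.
#'
#' @param n_surfaces,n_parameters panel dimensions (defaults 52 x 8).
#' @param type_means 3 x `n_parameters` matrix of type-level means, rows
#'   ordered type I, II, III; default rows are constant 2, 5 and 8.
#' @param noise_sd per-parameter replicate s.d. (recycled); default 0.75 so
#'   the planted between-type separation is 4x the noise s.d.
#' @param n_replicates replicate runs per surface (default 2, as in
#'   duplicate flow assays).
#' @param type_sizes surfaces per type; default splits as evenly as possible.
#' @param seed integer seed (required).
#' @return A `planted_matrix_truth` list.
#' @export
planted_matrix_truth <- function(n_surfaces = 52L, n_parameters = 8L,
                                 type_means = NULL, noise_sd = 0.75,
                                 n_replicates = 2L, type_sizes = NULL, seed) {
  seed <- check_seed(seed)
  if (is.null(type_means))
    type_means <- matrix(rep(c(2, 5, 8), n_parameters), 3, n_parameters)
  stopifnot(nrow(type_means) == 3L, ncol(type_means) == n_parameters)
  if (!all(diff(rowMeans(type_means)) > 0))
    stop("type means must be ordered so overall activation I < II < III",
         call. = FALSE)
  noise_sd <- rep_len(noise_sd, n_parameters)
  if (any(noise_sd < 0)) stop("noise_sd must be >= 0", call. = FALSE)
  if (is.null(type_sizes)) {
    base <- n_surfaces %/% 3L
    type_sizes <- c(base, base, n_surfaces - 2L * base)
  }
  stopifnot(sum(type_sizes) == n_surfaces, all(type_sizes >= 2L))
  pnames <- if (n_parameters == 8L) THROMBUS_PARAMETERS
            else paste0("param", seq_len(n_parameters))
  structure(list(n_surfaces = n_surfaces, n_parameters = n_parameters,
                 surface_ids = sprintf("S%02d", seq_len(n_surfaces)),
                 parameter_names = pnames,
                 true_type = rep(1:3, type_sizes),
                 type_means = type_means, noise_sd = noise_sd,
                 n_replicates = as.integer(n_replicates), seed = seed),
            class = "planted_matrix_truth")
}

#' Generate a surfaces-by-parameters matrix with planted type structure
#'
#' Draws replicate measurements i.i.d. around each surface's type mean and
#' returns both the tidy replicate table and the per-surface means matrix.
#'
#' @param truth a [planted_matrix_truth()].
#' @return A list: `replicates` (tidy data frame with columns surface,
#'   parameter, run, value), `means` (surfaces x parameters matrix),
#'   `true_type`, `truth`.
#' @export
gen_parameter_matrix <- function(truth) {
  stopifnot(inherits(truth, "planted_matrix_truth"))
  if (truth$n_replicates < 1L) stop("need at least one replicate", call. = FALSE)
  with_seed(truth$seed, {
    S <- truth$n_surfaces; P <- truth$n_parameters; R <- truth$n_replicates
    reps <- expand.grid(run = seq_len(R), parameter = truth$parameter_names,
                        surface = truth$surface_ids, stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)[, c("surface", "parameter", "run")]
    mu <- truth$type_means[truth$true_type, , drop = FALSE]  # S x P
    sd_rep <- rep(rep(truth$noise_sd, each = R), times = S)
    mu_rep <- rep(t(mu), each = R)  # surface-major, parameter, run order
    reps$value <- mu_rep + rnorm(nrow(reps), 0, sd_rep)
    means <- matrix(colMeans(matrix(reps$value, nrow = R)), S, P, byrow = TRUE,
                    dimnames = list(truth$surface_ids, truth$parameter_names))
    list(replicates = reps, means = means, true_type = truth$true_type,
         truth = truth)
  })
}

#' Planted truth for a receptor-design regression problem
#'
#' A binary surface-by-receptor engagement matrix together with planted
#' regression weights. The default weight pattern follows the published
#' receptor hierarchy for type III thrombus formation at high shear (strong
#' positive weights for GPIb, GPVI, CLEC-2, alpha6beta1 and alphaIIbbeta3, a
#' weak alpha2beta1 and negative alpha5beta1/alphavbeta3/CD36), scaled so the
#' noise-free responses stay inside the type range 1-3 for almost all
#' engagement patterns.
#'
#' @param receptors receptor names; default [RECEPTOR_PANEL].
#' @param beta_true named numeric: `intercept` plus one weight per receptor.
#' @param noise_sd response noise s.d. (default 0.1).
#' @param engage_prob probability a receptor is engaged by a surface when the
#'   assignment matrix is sampled (default 0.4).
#' @param seed integer seed (required).
#' @return A `planted_receptor_truth` list.
#' @export
planted_receptor_truth <- function(receptors = RECEPTOR_PANEL,
                                   beta_true = NULL, noise_sd = 0.1,
                                   engage_prob = 0.4, seed) {
  seed <- check_seed(seed)
  if (is.null(beta_true)) {
    w <- c(0.687, 0.858, 0.763, 0.193, -0.102, 0.653, 0.527, -0.159, -0.262)
    beta_true <- c(intercept = 1.05, setNames(0.5 * w, RECEPTOR_PANEL))
    if (!identical(receptors, RECEPTOR_PANEL))
      stop("supply beta_true when using a non-default receptor set",
           call. = FALSE)
  }
  if (length(beta_true) != length(receptors) + 1L)
    stop("beta_true must have one intercept plus one weight per receptor",
         call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  structure(list(receptors = receptors, beta_true = beta_true,
                 noise_sd = noise_sd, engage_prob = engage_prob, seed = seed),
            class = "planted_receptor_truth")
}

#' Generate a binary receptor design and its planted type response
#'
#' Samples a binary assignment matrix (every surface engages at least one
#' receptor), computes `intercept + A %*% beta + noise`, and clamps the
#' result to the type range `[1, 3]`.
#'
#' @param truth a [planted_receptor_truth()].
#' @param n_surfaces number of surfaces (default 52).
#' @param assignment optional pre-specified binary matrix (surfaces x
#'   receptors) used instead of sampling one.
#' @param round_response also return the response rounded to type classes
#'   1/2/3 (default TRUE).
#' @return A list: `assignment`, `response` (clamped continuous),
#'   `response_class`, `noise` (the drawn errors), `truth`.
#' @export
gen_receptor_design <- function(truth, n_surfaces = 52L, assignment = NULL,
                                round_response = TRUE) {
  stopifnot(inherits(truth, "planted_receptor_truth"))
  R <- length(truth$receptors)
  with_seed(truth$seed, {
    if (is.null(assignment)) {
      assignment <- matrix(as.integer(runif(n_surfaces * R) < truth$engage_prob),
                           n_surfaces, R)
      for (i in seq_len(n_surfaces))
        if (all(assignment[i, ] == 0L))
          assignment[i, sample.int(R, 1L)] <- 1L
    } else {
      assignment <- as.matrix(assignment)
      n_surfaces <- nrow(assignment)
    }
    if (!all(assignment %in% c(0L, 1L)))
      stop("assignment matrix must be binary", call. = FALSE)
    if (any(rowSums(assignment) == 0))
      stop("every surface must engage at least one receptor", call. = FALSE)
    dimnames(assignment) <- list(sprintf("S%02d", seq_len(n_surfaces)),
                                 truth$receptors)
    eps <- rnorm(n_surfaces, 0, truth$noise_sd)
    y <- truth$beta_true[1L] + drop(assignment %*% truth$beta_true[-1L]) + eps
    y <- pmin(pmax(y, 1), 3)
    out <- list(assignment = assignment, response = unname(y), noise = eps,
                truth = truth)
    if (round_response) out$response_class <- round_type(y)
    out
  })
}

# default healthy-control cell means for the reference panel: deterministic,
# spread over the working range of the normalized 0-10 scale
default_cell_means <- function(n_surfaces, n_parameters) {
  s <- seq(2.5, 8, length.out = n_surfaces)
  p <- seq(-0.8, 0.8, length.out = n_parameters)
  m <- outer(s, p, `+`)
  dimnames(m) <- list(sprintf("S%02d", seq_len(n_surfaces)),
                      if (n_parameters == 6L) THROMBUS_PARAMETERS[1:6]
                      else paste0("param", seq_len(n_parameters)))
  m
}

#' Planted truth for a control/patient cohort
#'
#' Two-level variance model for repeated flow assays: a control observation
#' in cell (surface, parameter) is `cell mean + subject effect + day effect`,
#' with subject effects drawn at `inter_sd` (between-individual) and day
#' effects at `intra_sd` (within-individual, between-day). A patient's
#' expected value is shifted from the cell mean by `patient_shift` units of
#' the inter-individual s.d. Defaults mirror a reference-range study design
#' of 9 surfaces x 6 parameters with 6 control subjects sampled on 4 days,
#' intra-individual CVs near 6% and an inter/intra s.d. ratio of 3.
#'
#' @param cell_means surfaces x parameters matrix of population means.
#' @param inter_sd,intra_sd between- and within-individual s.d. per cell
#'   (matrix or scalar); defaults 18% and 6% of the cell mean.
#' @param n_controls,n_days control subjects and sampling days (6 and 4).
#' @param patient_shift surfaces x parameters matrix of shifts in units of
#'   `inter_sd` (default all zero: a healthy "patient").
#' @param n_patient_runs replicate runs for the patient sample (default 3).
#' @param patient_subject_effect give the patient an own between-individual
#'   random effect on top of the planted shift (default FALSE: the patient's
#'   expected value is exactly `cell mean + shift * inter_sd`, which makes
#'   planted deviations exact; set TRUE to draw a null patient from the
#'   healthy population).
#' @param seed integer seed (required).
#' @return A `cohort_truth` list.
#' @export
cohort_truth <- function(cell_means = default_cell_means(9L, 6L),
                         inter_sd = 0.18 * cell_means,
                         intra_sd = 0.06 * cell_means,
                         n_controls = 6L, n_days = 4L,
                         patient_shift = 0 * cell_means,
                         n_patient_runs = 3L,
                         patient_subject_effect = FALSE, seed) {
  seed <- check_seed(seed)
  cell_means <- as.matrix(cell_means)
  if (is.null(rownames(cell_means)))
    rownames(cell_means) <- sprintf("S%02d", seq_len(nrow(cell_means)))
  if (is.null(colnames(cell_means)))
    colnames(cell_means) <- paste0("param", seq_len(ncol(cell_means)))
  expand <- function(x) {
    x <- if (length(x) == 1L) matrix(x, nrow(cell_means), ncol(cell_means)) else as.matrix(x)
    stopifnot(all(dim(x) == dim(cell_means)))
    x
  }
  inter_sd <- expand(inter_sd); intra_sd <- expand(intra_sd)
  patient_shift <- expand(patient_shift)
  if (any(inter_sd < 0) || any(intra_sd < 0))
    stop("variance components must be >= 0", call. = FALSE)
  if (n_controls < 2L || n_days < 1L)
    stop("need n_controls >= 2 and n_days >= 1", call. = FALSE)
  structure(list(cell_means = cell_means, inter_sd = inter_sd,
                 intra_sd = intra_sd, n_controls = as.integer(n_controls),
                 n_days = as.integer(n_days), patient_shift = patient_shift,
                 n_patient_runs = as.integer(n_patient_runs),
                 patient_subject_effect = isTRUE(patient_subject_effect),
                 seed = seed),
            class = "cohort_truth")
}

#' Generate control and patient cohort tables
#'
#' @param truth a [cohort_truth()].
#' @return A list: `controls` (tidy data frame: subject, day, surface,
#'   parameter, value), `patient` (tidy data frame: run, surface, parameter,
#'   value), `subject_effects` (subjects x surfaces x parameters array of the
#'   drawn between-individual effects), `truth`.
#' @export
gen_cohort <- function(truth) {
  stopifnot(inherits(truth, "cohort_truth"))
  with_seed(truth$seed, {
    S <- nrow(truth$cell_means); P <- ncol(truth$cell_means)
    surfaces <- rownames(truth$cell_means)
    params <- colnames(truth$cell_means)
    nsub <- truth$n_controls; nday <- truth$n_days
    subj_eff <- array(rnorm(nsub * S * P) * rep(truth$inter_sd, each = nsub),
                      c(nsub, S, P))
    grid <- expand.grid(day = seq_len(nday), subject = sprintf("C%02d", seq_len(nsub)),
                        parameter = params, surface = surfaces,
                        stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
    grid <- grid[, c("subject", "day", "surface", "parameter")]
    si <- match(grid$surface, surfaces); pj <- match(grid$parameter, params)
    ki <- match(grid$subject, sprintf("C%02d", seq_len(nsub)))
    mu <- truth$cell_means[cbind(si, pj)] + subj_eff[cbind(ki, si, pj)]
    grid$value <- mu + rnorm(nrow(grid)) * truth$intra_sd[cbind(si, pj)]
    pat <- expand.grid(run = seq_len(truth$n_patient_runs), parameter = params,
                       surface = surfaces, stringsAsFactors = FALSE,
                       KEEP.OUT.ATTRS = FALSE)[, c("run", "surface", "parameter")]
    psi <- match(pat$surface, surfaces); ppi <- match(pat$parameter, params)
    pat_eff <- if (truth$patient_subject_effect)
      matrix(rnorm(S * P), S, P) * truth$inter_sd else matrix(0, S, P)
    pmu <- truth$cell_means[cbind(psi, ppi)] + pat_eff[cbind(psi, ppi)] +
      truth$patient_shift[cbind(psi, ppi)] * truth$inter_sd[cbind(psi, ppi)]
    pat$value <- pmu + rnorm(nrow(pat)) * truth$intra_sd[cbind(psi, ppi)]
    list(controls = grid, patient = pat, subject_effects = subj_eff,
         truth = truth)
  })
}
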