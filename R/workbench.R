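#' @name workbench
#' @title Pipeline plumbing: configuration, I/O, end-to-end demo run
#'
#' @description
#' Ties the stages together: a validated configuration object, TIFF/CSV/JSON
#' readers and writers, an input validator, a deterministic end-to-end
#' pipeline (`simulate -> quantify -> build-matrix -> cluster -> receptor
#' model -> patient profile`) writing every artifact plus a manifest, and
#' figure export (heatmap, dendrogram, significance map).
NULL

#' Write 8-bit image data as (multi-page) TIFF with a truth sidecar
#'
#' Scenes, series and stacks are written as 8-bit TIFF (one page per
#' frame/slice); recorded ground truth goes to a JSON sidecar next to the
#' image.
#'
#' @param x a `synthetic_scene`, `synthetic_series`, `synthetic_stack`, or a
#'   matrix/list of matrices on the 0-255 scale.
#' @param path output `.tif` path.
#' @param sidecar write the truth JSON sidecar (default TRUE for synthetic
#'   objects).
#' @return `path`, invisibly.
#' @export
write_tiff8 <- function(x, path, sidecar = TRUE) {
  truth <- NULL
  if (inherits(x, "synthetic_scene")) {
    truth <- list(kind = "scene", truth_coverage = x$truth_coverage,
                  truth_features = x$truth_features,
                  pixel_size = x$pixel_size, seed = x$seed)
    pages <- list(x$pixel_grid)
  } else if (inherits(x, "synthetic_series")) {
    truth <- list(kind = "series", frame_interval = x$frame_interval,
                  truth_stable_fraction = x$truth_stable_fraction,
                  seed = x$seed)
    pages <- x$frames
  } else if (inherits(x, "synthetic_stack")) {
    truth <- list(kind = "stack", slice_spacing = x$slice_spacing,
                  truth_volume_per_area = x$truth_volume_per_area,
                  pixel_size = x$pixel_size, seed = x$seed)
    pages <- x$slices
  } else {
    pages <- if (is.matrix(x)) list(x) else x
    sidecar <- FALSE
  }
  tiff::writeTIFF(lapply(pages, function(p) p / 255), path,
                  bits.per.sample = 8L)
  if (sidecar)
    jsonlite::write_json(truth, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  invisible(path)
}

#' Read a (multi-page) TIFF as 0-255 intensity matrices
#'
#' @param path `.tif` path.
#' @return A list of numeric matrices on the 0-255 scale.
#' @export
read_tiff8 <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, info = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1L]  # first channel
    round(p * 255)
  })
}

#' Pipeline configuration
#'
#' Validated settings for [run_pipeline()]. The single `seed` fans out into
#' independent per-stage child seeds (drawn from a seeded stream), so every
#' stage is reproducible in isolation.
#'
#' @param out_dir output directory (created if missing).
#' @param seed master integer seed.
#' @param shear wall shear rate tag in s^-1 (150, 1000 or 1600).
#' @param n_surfaces,n_parameters planted panel size for the clustering
#'   stages (defaults 52 x 8).
#' @param n_boot,scales,k multiscale-bootstrap and tree-cut settings.
#' @param n_components PLS components for the receptor model.
#' @param alpha,sd_multiplier patient-profiling test level and band width.
#' @param ref_surfaces,ref_parameters,n_controls,n_days reference-panel
#'   design for the patient stage (defaults 9 x 6, 6 controls, 4 days).
#' @param n_deficits number of cells in which the demo patient is planted
#'   deficient at `deficit_sd` inter-individual s.d. below the mean.
#' @param deficit_sd planted deficit depth (default -3).
#' @param figures also export figures (default TRUE).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, seed, shear = 1600,
                            n_surfaces = 52L, n_parameters = 8L,
                            n_boot = 200L,
                            scales = seq(0.5, 1.4, length.out = 10),
                            k = 3L, n_components = 3L, alpha = 0.05,
                            sd_multiplier = 2, ref_surfaces = 9L,
                            ref_parameters = 6L, n_controls = 6L,
                            n_days = 4L, n_deficits = 12L, deficit_sd = -3,
                            figures = TRUE) {
  stopifnot(shear %in% c(150, 1000, 1600), n_boot >= 1L, k >= 2L,
            n_components >= 1L, alpha > 0, alpha < 1, sd_multiplier > 0,
            n_controls >= 2L, n_days >= 1L,
            n_deficits >= 0L, n_deficits <= ref_surfaces * ref_parameters)
  structure(list(out_dir = out_dir, seed = check_seed(seed), shear = shear,
                 n_surfaces = as.integer(n_surfaces),
                 n_parameters = as.integer(n_parameters),
                 n_boot = as.integer(n_boot), scales = scales,
                 k = as.integer(k), n_components = as.integer(n_components),
                 alpha = alpha, sd_multiplier = sd_multiplier,
                 ref_surfaces = as.integer(ref_surfaces),
                 ref_parameters = as.integer(ref_parameters),
                 n_controls = as.integer(n_controls),
                 n_days = as.integer(n_days),
                 n_deficits = as.integer(n_deficits),
                 deficit_sd = deficit_sd, figures = isTRUE(figures)),
            class = "pipeline_config")
}

# fixed-precision CSV so reruns under the same seed are byte-identical
write_csv_fixed <- function(x, path, digits = 10L) {
  df <- as.data.frame(x)
  if (!is.null(rownames(x)) && is.matrix(x))
    df <- cbind(id = rownames(x), df)
  for (j in seq_along(df))
    if (is.numeric(df[[j]]) && !is.integer(df[[j]]))
      df[[j]] <- formatC(df[[j]], digits = digits, format = "g")
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

#' Validate pipeline input files
#'
#' Report-only schema check: replicate CSVs must carry the tidy columns,
#' assignment CSVs must be binary, TIFFs should be 8-bit (16-bit inputs pass
#' with an auto-rescale note).
#'
#' @param replicates,assignment,tiffs file paths (each optional).
#' @return Data frame `file`, `role`, `pass`, `note`.
#' @export
validate_inputs <- function(replicates = NULL, assignment = NULL,
                            tiffs = NULL) {
  rows <- list()
  add <- function(file, role, pass, note = "")
    rows[[length(rows) + 1L]] <<- data.frame(file = file, role = role,
                                             pass = pass, note = note)
  for (f in replicates) {
    ok <- tryCatch({
      d <- read.csv(f)
      miss <- setdiff(c("surface", "parameter", "run", "value"), names(d))
      if (length(miss)) add(f, "replicates", FALSE,
                            paste("missing columns:", paste(miss, collapse = ", ")))
      else add(f, "replicates", TRUE)
      TRUE
    }, error = function(e) FALSE)
    if (!ok) add(f, "replicates", FALSE, "unreadable")
  }
  for (f in assignment) {
    ok <- tryCatch({
      d <- read.csv(f, row.names = 1L, check.names = FALSE)
      bad <- which(!(as.matrix(d) %in% c(0, 1)))
      if (length(bad)) {
        i <- ((bad[1L] - 1L) %% nrow(d)) + 1L
        j <- ((bad[1L] - 1L) %/% nrow(d)) + 1L
        add(f, "assignment", FALSE,
            sprintf("non-binary entry at row '%s', column '%s'",
                    rownames(d)[i], colnames(d)[j]))
      } else add(f, "assignment", TRUE)
      TRUE
    }, error = function(e) FALSE)
    if (!ok) add(f, "assignment", FALSE, "unreadable")
  }
  for (f in tiffs) {
    ok <- tryCatch({
      info <- attr(tiff::readTIFF(f, info = TRUE), "bits.per.sample")
      if (!is.null(info) && info != 8L)
        add(f, "tiff", TRUE, sprintf("%d-bit input; auto-rescaled to 8-bit", info))
      else add(f, "tiff", TRUE)
      TRUE
    }, error = function(e) FALSE)
    if (!ok) add(f, "tiff", FALSE, "unreadable")
  }
  if (!length(rows))
    return(data.frame(file = character(), role = character(),
                      pass = logical(), note = character()))
  do.call(rbind, rows)
}

#' Run the end-to-end demo pipeline on simulated data
#'
#' Executes all stages in order on synthetic inputs with known ground truth:
#' image quantification on generated scenes, assembly and 0-10 normalization
#' of a planted 52 x 8 parameter matrix, clustering with bootstrap support
#' and typing, the receptor beta-weight model with leave-one-out cross
#' validation, and patient profiling of a planted-deficit patient against a
#' simulated healthy cohort. Every output is written under
#' `config$out_dir` and listed in `manifest.json` together with the seed and
#' a hash of the configuration; reruns under the same configuration are
#' byte-identical. Any stage failure halts with the stage name.
#'
#' @param config a [pipeline_config()].
#' @param replicates optional externally supplied tidy replicate table used
#'   instead of the simulated one in the build-matrix stage.
#' @return Invisibly, the report bundle: all in-memory stage results plus
#'   `manifest`.
#' @export
run_pipeline <- function(config, replicates = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- derive_seeds(config$seed, 6L)
  files <- character()
  emit <- function(path) files <<- c(files, path)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  out <- function(...) file.path(config$out_dir, ...)

  # -- simulate + quantify: image-derived parameters on a few demo scenes
  quant <- stage("quantify", {
    scene_seeds <- derive_seeds(seeds[1L], 3L)
    rows <- lapply(seq_along(scene_seeds), function(i) {
      sc <- gen_scene(n_features = c(5L, 15L, 30L)[i], dim = c(128L, 128L),
                      area_meanlog = log(c(40, 60, 80)[i]),
                      seed = scene_seeds[i])
      seg <- segment_coverage(sc$pixel_grid)
      fs <- feature_areas(seg$mask)
      se <- gen_series(sc, stable_fraction = 0.6, duration_s = 20,
                       interval_s = 2, seed = scene_seeds[i] + 1L)
      st <- gen_stack(sc, n_slices = 6L, seed = scene_seeds[i] + 2L)
      data.frame(scene = i,
                 platelet_deposition = seg$coverage,
                 integrated_feature_size = integrated_feature_size(fs),
                 morphological_score = morphological_score(seg$mask, fs),
                 stable_adhesion = stable_adhesion(se),
                 thrombus_volume = thrombus_volume(st))
    })
    do.call(rbind, rows)
  })
  emit(write_csv_fixed(quant, out("quantified.csv")))

  # -- build-matrix
  mstage <- stage("build-matrix", {
    pm_truth <- planted_matrix_truth(config$n_surfaces, config$n_parameters,
                                     seed = seeds[2L])
    gen <- gen_parameter_matrix(pm_truth)
    reps <- if (is.null(replicates)) gen$replicates else replicates
    if (anyNA(reps$value)) {
      bad <- which(is.na(reps$value))[1L]
      stop("non-finite value in cell (surface ", reps$surface[bad],
           ", parameter ", reps$parameter[bad], ")")
    }
    agg <- aggregate_replicates(reps)
    norm <- normalize_matrix(agg)
    list(gen = gen, agg = agg, norm = norm)
  })
  emit(write_csv_fixed(mstage$agg$mean, out("matrix_raw.csv")))
  emit(write_csv_fixed(mstage$norm, out("matrix_normalized.csv")))
  jsonlite::write_json(attr(mstage$norm, "bounds"),
                       out("normalization_bounds.json"),
                       auto_unbox = FALSE, digits = NA)
  emit(out("normalization_bounds.json"))

  # -- cluster + type
  cstage <- stage("cluster", {
    tree <- hcluster(mstage$norm)
    support <- multiscale_bootstrap(mstage$norm, tree,
                                    scales = config$scales,
                                    n_boot = config$n_boot, seed = seeds[3L])
    types <- cut_types(tree, mstage$norm, k = config$k)
    list(tree = tree, support = support, types = types)
  })
  emit(write_csv_fixed(cstage$support[, c("node", "members", "bp", "au", "flag")],
                       out("cluster_support.csv")))
  newick_export(cstage$tree, cstage$support, file = out("dendrogram.nwk"))
  emit(out("dendrogram.nwk"))
  emit(write_csv_fixed(data.frame(surface = names(cstage$types$type),
                                  type = cstage$types$type),
                       out("thrombus_types.csv")))

  # -- receptor model
  rstage <- stage("receptor-model", {
    rt <- planted_receptor_truth(seed = seeds[4L])
    des <- gen_receptor_design(rt, n_surfaces = config$n_surfaces)
    bw <- receptor_beta(des$assignment, des$response_class,
                        n_components = config$n_components,
                        shear = config$shear)
    cv <- crossval(des$assignment, des$response_class,
                   n_components = config$n_components)
    list(design = des, beta = bw, cv = cv)
  })
  emit(write_csv_fixed(rstage$beta$beta, out("beta_weights.csv")))
  jsonlite::write_json(list(resubstitution = unname(rstage$beta$confusion$misassigned),
                            cross_validation = unname(rstage$cv$misassigned),
                            n = rstage$cv$n),
                       out("confusion.json"), auto_unbox = TRUE, digits = NA)
  emit(out("confusion.json"))

  # -- patient profile
  pstage <- stage("patient-profile", {
    means <- default_cell_means(config$ref_surfaces, config$ref_parameters)
    shift <- 0 * means
    cells <- with_seed(seeds[5L],
                       sample.int(length(means), config$n_deficits))
    shift[cells] <- config$deficit_sd
    ct <- cohort_truth(cell_means = means, n_controls = config$n_controls,
                       n_days = config$n_days, patient_shift = shift,
                       seed = seeds[6L])
    cohort <- gen_cohort(ct)
    ref <- reference_ranges(cohort$controls)
    sm <- significance_map(cohort$patient, ref,
                           sd_multiplier = config$sd_multiplier)
    ctrl_reps <- cohort$controls
    sub <- patient_subtraction(cohort$patient, ctrl_reps,
                               alpha = config$alpha)
    list(cohort = cohort, ref = ref, map = sm, subtraction = sub,
         deviations = deviation_summary(sm),
         planted_deficits = config$n_deficits)
  })
  emit(write_csv_fixed(pstage$ref$mean, out("reference_mean.csv")))
  emit(write_csv_fixed(pstage$ref$sd, out("reference_sd.csv")))
  emit(write_csv_fixed(pstage$map$flags, out("significance_map.csv")))
  jsonlite::write_json(pstage$deviations, out("deviation_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  emit(out("deviation_summary.json"))

  bundle <- list(quantified = quant, matrix = mstage, cluster = cstage,
                 receptor = rstage, patient = pstage, config = config)
  if (config$figures) {
    figs <- export_figures(bundle, config$out_dir)
    files <- c(files, figs)
  }

  cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  cfg_file <- out("config.json")
  writeLines(cfg_json, cfg_file)
  manifest <- list(seed = config$seed,
                   config_hash = unname(tools::md5sum(cfg_file)),
                   files = basename(c(files, cfg_file)))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  bundle$manifest <- manifest
  invisible(bundle)
}

#' Export heatmap, dendrogram and significance-map figures
#'
#' Deterministic base-graphics renderings: the normalized matrix as a
#' white-to-black heatmap in dendrogram leaf order, the surface dendrogram
#' with AU support, and the patient significance map in the red (reduced) /
#' green (increased) convention.
#'
#' @param bundle a [run_pipeline()] report bundle (or a list with the same
#'   `matrix`, `cluster`, `patient` slots).
#' @param out_dir output directory.
#' @return Paths of the written PNG files.
#' @export
export_figures <- function(bundle, out_dir) {
  paths <- character()
  png_of <- function(name, expr, width = 900, height = 600) {
    path <- file.path(out_dir, name)
    grDevices::png(path, width = width, height = height)
    on.exit(grDevices::dev.off())
    expr
    paths <<- c(paths, path)
    path
  }
  if (!is.null(bundle$matrix)) png_of("heatmap.png", {
    m <- bundle$matrix$norm[bundle$cluster$tree$order, , drop = FALSE]
    graphics::par(mar = c(8, 6, 2, 1))
    graphics::image(seq_len(nrow(m)), seq_len(ncol(m)), m,
                    col = grDevices::gray(seq(1, 0, length.out = 64)),
                    zlim = c(0, 10), axes = FALSE, xlab = "", ylab = "")
    graphics::axis(1, seq_len(nrow(m)), rownames(m), las = 2, cex.axis = 0.6)
    graphics::axis(2, seq_len(ncol(m)), colnames(m), las = 2, cex.axis = 0.7)
  })
  if (!is.null(bundle$cluster)) png_of("dendrogram.png", {
    graphics::plot(bundle$cluster$tree, cex = 0.6,
                   main = "Surface clustering (complete linkage)")
  })
  if (!is.null(bundle$patient)) png_of("significance_map.png", {
    f <- bundle$patient$map$flags
    img <- f; img[is.na(img)] <- 0L
    graphics::par(mar = c(8, 6, 2, 1))
    graphics::image(seq_len(nrow(f)), seq_len(ncol(f)), img,
                    col = c("#d62728", "white", "#2ca02c"), zlim = c(-1, 1),
                    axes = FALSE, xlab = "", ylab = "")
    graphics::axis(1, seq_len(nrow(f)), rownames(f), las = 2, cex.axis = 0.7)
    graphics::axis(2, seq_len(ncol(f)), colnames(f), las = 2, cex.axis = 0.7)
  })
  paths
}
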