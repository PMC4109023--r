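test_that("scene generator records exact ground truth and is deterministic", {
  # empty field
  sc0 <- gen_scene(0, dim = c(64L, 64L), seed = 1)
  expect_identical(sc0$truth_features, integer(0))
  expect_identical(sc0$truth_coverage, 0)

  # a single ~100x100-px-area feature on the default 512x512 grid
  sc1 <- gen_scene(1, area_meanlog = log(10000), area_sdlog = 0,
                   noise_sd = 0, seed = 2)
  expect_equal(sc1$truth_coverage, 10000 / (512 * 512), tolerance = 0.02)
  # recorded truth is exactly recomputable from the emitted mask
  expect_identical(sum(sc1$truth_features), sum(sc1$truth_mask == 1L))
  expect_equal(sc1$truth_coverage, sum(sc1$truth_mask) / length(sc1$truth_mask))

  # determinism under a fixed seed; a different seed differs
  a <- gen_scene(50, seed = 7)
  b <- gen_scene(50, seed = 7)
  expect_identical(a, b)
  expect_false(identical(a$pixel_grid, gen_scene(50, seed = 8)$pixel_grid))

  # foreground intensities exceed background before noise
  nf <- gen_scene(10, dim = c(128L, 128L), area_meanlog = log(50),
                  noise_sd = 0, seed = 3)
  expect_true(all(nf$pixel_grid[nf$truth_mask == 1L] == nf$foreground))
  expect_true(all(nf$pixel_grid[nf$truth_mask == 0L] == nf$background))

  # every truth feature is one 8-connected component
  lab <- flood_fill_label(nf$truth_mask, 8L)
  expect_identical(sort(as.integer(tabulate(lab[lab > 0]))), nf$truth_features)

  # infeasible packing fails loudly, naming the constraint
  expect_error(gen_scene(80, dim = c(64L, 64L), area_meanlog = log(200),
                         seed = 4),
               "non-overlap|70%")
  # over-budget total foreground is rejected up front
  expect_error(gen_scene(3, dim = c(64L, 64L), area_meanlog = log(2000),
                         area_sdlog = 0, seed = 4), "70%")
})

test_that("aggregate mode records merged component areas as truth", {
  sc <- gen_scene(40, dim = c(96L, 96L), area_meanlog = log(60),
                  mode = "aggregate", noise_sd = 0, seed = 11)
  lab <- flood_fill_label(sc$truth_mask, 8L)
  expect_identical(sort(as.integer(tabulate(lab[lab > 0]))), sc$truth_features)
  expect_lte(length(sc$truth_features), 40L)
})

test_that("series honours the stable fraction and its truth is recomputable", {
  sc <- gen_scene(40, dim = c(128L, 128L), area_meanlog = log(40),
                  noise_sd = 0, seed = 5)

  s1 <- gen_series(sc, stable_fraction = 1, seed = 6)
  for (f in s1$frames) expect_identical(f, sc$pixel_grid)

  s0 <- gen_series(sc, stable_fraction = 0, seed = 6)
  expect_identical(sum(s0$stable_mask), 0L)

  sh <- gen_series(sc, stable_fraction = 0.5, duration_s = 60, interval_s = 2,
                   seed = 6)
  expect_length(sh$frames, 30L)
  expect_equal(sh$truth_stable_fraction, 0.5, tolerance = 0.025)
  # pixels above background in every frame are exactly the stable mask
  persist <- Reduce(`&`, lapply(sh$frames, function(f) f > 50))
  expect_identical(which(persist), which(sh$stable_mask == 1L))
  # stable mask is a subset of every frame's foreground
  for (f in sh$frames) expect_true(all(f[sh$stable_mask == 1L] > 50))

  expect_error(gen_series(sc, 0.5, duration_s = 61, interval_s = 2, seed = 1),
               "multiple")
  expect_error(gen_series(sc, 1.2, seed = 1), "\\[0, 1\\]")
})

test_that("z-stack truth is self-consistent with contiguous columns", {
  sc <- gen_scene(25, dim = c(128L, 128L), area_meanlog = log(50),
                  noise_sd = 0, seed = 8)
  st <- gen_stack(sc, n_slices = 10L, slice_spacing = 0.5, seed = 9)
  expect_equal(st$truth_volume_per_area, mean(st$truth_height_map))
  # occupancy of slice k implies occupancy of slice k-1 (contiguous from base)
  occ <- lapply(st$slices, function(s) s > 50)
  for (k in 2:10) expect_true(all(occ[[k - 1L]][occ[[k]]]))
  # height map matches the emitted slices
  expect_equal(Reduce(`+`, occ) * 0.5, st$truth_height_map)
  expect_identical(gen_stack(sc, seed = 9), gen_stack(sc, seed = 9))
})

test_that("parameter-matrix generator plants the ordered type structure", {
  tr0 <- planted_matrix_truth(noise_sd = 0, seed = 1)
  g0 <- gen_parameter_matrix(tr0)
  for (i in seq_len(52)) {
    expect_equal(unname(g0$means[i, ]),
                 unname(tr0$type_means[tr0$true_type[i], ]))
  }

  g <- planted_panel(seed = 2)
  expect_identical(g$replicates, planted_panel(seed = 2)$replicates)

  # between-type / within-type variance decomposition exceeds the planted 4x
  for (j in 1:8) {
    fit <- anova(lm(g$means[, j] ~ factor(g$true_type)))
    between <- fit$`Mean Sq`[1L]; within <- fit$`Mean Sq`[2L]
    expect_gt(between / within, 16)  # (4 x noise sd)^2 separation
  }
  expect_error(planted_matrix_truth(type_means = matrix(c(5, 2, 8), 3, 8),
                                    seed = 1),
               "ordered")
})

test_that("receptor design reproduces its planted linear responses", {
  # zero weights, intercept 2, no noise: all responses exactly 2
  bt <- c(intercept = 2, setNames(rep(0, 9), RECEPTOR_PANEL))
  d0 <- gen_receptor_design(planted_receptor_truth(beta_true = bt,
                                                   noise_sd = 0, seed = 3))
  expect_true(all(d0$response == 2))

  # identity design: response differences reproduce beta exactly
  bt2 <- c(intercept = 2, setNames(seq(-0.3, 0.3, length.out = 9),
                                   RECEPTOR_PANEL))
  di <- gen_receptor_design(planted_receptor_truth(beta_true = bt2,
                                                   noise_sd = 0, seed = 4),
                            assignment = diag(9L))
  expect_equal(unname(di$response - 2), unname(bt2[-1L]))

  # responses recomputable from stored assignment, beta and noise draws
  dn <- gen_receptor_design(planted_receptor_truth(noise_sd = 0.1, seed = 5))
  rebuilt <- dn$truth$beta_true[1L] +
    drop(dn$assignment %*% dn$truth$beta_true[-1L]) + dn$noise
  expect_equal(dn$response, unname(pmin(pmax(rebuilt, 1), 3)))
  expect_true(all(dn$response >= 1 & dn$response <= 3))

  expect_error(gen_receptor_design(planted_receptor_truth(seed = 1),
                                   assignment = matrix(0L, 4, 9)),
               "at least one receptor")
})

test_that("cohort generator follows the two-level variance model", {
  means <- matrix(c(4, 6, 8, 5), 2, 2)
  # degenerate: no variance, no shift -> patient identical to every control
  ct0 <- cohort_truth(cell_means = means, inter_sd = 0, intra_sd = 0,
                      seed = 1)
  c0 <- gen_cohort(ct0)
  expect_true(all(c0$controls$value ==
                    means[cbind(match(c0$controls$surface, rownames(ct0$cell_means)),
                                match(c0$controls$parameter, colnames(ct0$cell_means)))]))
  expect_true(all(c0$patient$value ==
                    means[cbind(match(c0$patient$surface, rownames(ct0$cell_means)),
                                match(c0$patient$parameter, colnames(ct0$cell_means)))]))

  # planted +3 inter-sd shift is exact before measurement noise
  shift <- matrix(0, 2, 2); shift[2, 1] <- 3
  ct3 <- cohort_truth(cell_means = means, inter_sd = 0.5, intra_sd = 0,
                      patient_shift = shift, seed = 2)
  p3 <- gen_cohort(ct3)$patient
  v <- p3$value[p3$surface == "S02" & p3$parameter == "param1"]
  expect_true(all(v == means[2, 1] + 3 * 0.5))

  expect_error(cohort_truth(cell_means = means, inter_sd = -1, seed = 1),
               ">= 0")
  expect_error(cohort_truth(cell_means = means, n_controls = 1, seed = 1),
               "n_controls")

  # method-of-moments variance components converge at n = 50 subjects
  big <- cohort_truth(cell_means = matrix(5, 9, 6), inter_sd = 0.6,
                      intra_sd = 0.2, n_controls = 50L, n_days = 4L, seed = 3)
  coh <- gen_cohort(big)$controls
  key <- paste(coh$surface, coh$parameter)
  est <- vapply(split(coh, key), function(d) {
    within <- tapply(d$value, d$subject, var)
    submean <- tapply(d$value, d$subject, mean)
    intra2 <- mean(within)
    inter2 <- var(submean) - intra2 / 4
    c(sqrt(intra2), sqrt(max(inter2, 0)))
  }, numeric(2))
  expect_equal(mean(est[1, ]), 0.2, tolerance = 0.1)
  expect_equal(mean(est[2, ]), 0.6, tolerance = 0.1)
})
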