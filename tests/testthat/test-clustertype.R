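test_that("agglomeration matches a brute-force oracle and stats::hclust", {
  # identical rows merge first at height zero
  m <- rbind(a = c(1, 2), b = c(5, 5), c = c(1, 2))
  tr <- hcluster(m)
  expect_equal(tr$height[1L], 0)
  expect_identical(sort(tr$merge[1L, ]), c(-3L, -1L))

  set.seed(11)
  for (i in 1:30) {
    n <- sample(2:8, 1)
    x <- matrix(rnorm(n * 4), n)
    tree <- hcluster(x)
    oracle <- brute_complete_linkage(x)
    expect_equal(tree$height, oracle$heights)
    expect_identical(merge_leaf_sets(tree$merge), oracle$partitions)
    # reference implementation agrees on tie-free continuous data
    hc <- hclust(dist(x), method = "complete")
    expect_equal(tree$height, hc$height)
    expect_identical(merge_leaf_sets(tree$merge), merge_leaf_sets(hc$merge))
  }

  # permutation invariance: same heights, same leaf partitions
  x <- matrix(rnorm(28), 7); rownames(x) <- letters[1:7]
  p <- sample(7)
  t1 <- hcluster(x); t2 <- hcluster(x[p, ])
  expect_equal(t1$height, t2$height)
  part1 <- lapply(merge_leaf_sets(t1$merge), function(s) sort(t1$labels[s]))
  part2 <- lapply(merge_leaf_sets(t2$merge), function(s) sort(t2$labels[s]))
  expect_identical(part1, part2)

  expect_error(hcluster(matrix(c(1, NA, 2, 3), 2)), "NaN|NA")
  expect_error(hcluster(x[1, , drop = FALSE]), "two items")

  # parameter axis clusters the columns
  tp <- hcluster(x, axis = "parameters")
  expect_length(tp$order, ncol(x))
})

test_that("AU model has its analytic fixed points and clamping behaviour", {
  scales <- seq(0.5, 1.4, length.out = 10)
  flat <- au_from_bp(rep(0.5, 10), scales, 1000)
  expect_equal(flat$au, 0.5)
  expect_equal(flat$v, 0, tolerance = 1e-12)
  expect_equal(flat$c, 0, tolerance = 1e-12)

  expect_identical(au_from_bp(rep(1, 10), scales, 1000)$flag, "clamped")
  expect_equal(au_from_bp(rep(1, 10), scales, 1000)$au, 1)
  expect_equal(au_from_bp(rep(0, 10), scales, 1000)$au, 0)
  # near-total recovery (boundary counts at most scales) still fits,
  # with AU near 1
  dented <- au_from_bp(c(0.99, 1, 1, 1, 1, 1, 1, 1, 1, 1), scales, 1000)
  expect_identical(dented$flag, "ok")
  expect_gt(dented$au, 0.95)
  # fewer than three scales cannot identify (v, c)
  expect_identical(au_from_bp(c(0.4, 0.6), c(0.9, 1.1), 100)$flag,
                   "unstable")
  # exact recovery of (v, c) from noiseless probit-linear BP profiles, and
  # AU monotone in v - c
  strong <- au_from_bp(pnorm(-(-1.5 * sqrt(scales) + 0.5 / sqrt(scales))),
                       scales, 1000)
  expect_equal(strong$v, -1.5, tolerance = 1e-8)
  expect_equal(strong$c, 0.5, tolerance = 1e-8)
  expect_equal(strong$au, 1 - pnorm(-2), tolerance = 1e-8)
  weak <- au_from_bp(pnorm(-(-0.2 * sqrt(scales) + 0.1 / sqrt(scales))),
                     scales, 1000)
  expect_gt(strong$au, weak$au)
})

test_that("BP at scale 1 equals an independent ordinary bootstrap exactly", {
  g <- planted_panel(seed = 13, n_surfaces = 10L)
  nm <- normalize_matrix(g$means)
  tree <- hcluster(nm)
  scales <- c(1, 0.6, 1.3)  # r = 1 first, so it consumes the first draws
  n_boot <- 200L
  bs <- multiscale_bootstrap(nm, tree, scales = scales, n_boot = n_boot,
                             seed = 99)
  bp1 <- attr(bs, "bp_scales")[, 1L]

  # independent ordinary bootstrap with the same resample indices
  p <- ncol(nm)
  targets <- merge_leaf_sets(tree$merge)
  set.seed(99)
  idx <- matrix(sample.int(p, p * n_boot, replace = TRUE), p, n_boot)
  counts <- numeric(length(targets))
  for (b in seq_len(n_boot)) {
    bt <- hcluster(nm[, idx[, b], drop = FALSE])
    found <- merge_leaf_sets(bt$merge)
    for (t in seq_along(targets))
      counts[t] <- counts[t] +
        any(vapply(found, identical, logical(1), y = targets[[t]]))
  }
  expect_identical(unname(bp1), counts / n_boot)

  # identical seeds give identical BP tables at every scale
  bs2 <- multiscale_bootstrap(nm, tree, scales = scales, n_boot = n_boot,
                              seed = 99)
  expect_identical(attr(bs, "bp_scales"), attr(bs2, "bp_scales"))
  expect_error(multiscale_bootstrap(nm, tree, scales = c(1.1, 1.2), seed = 1),
               "straddle")
})

test_that("well-separated planted type clusters receive high AU support", {
  for (s in 1:3) {
    g <- planted_panel(seed = 60 + s)
    nm <- normalize_matrix(g$means)
    tree <- hcluster(nm)
    bs <- multiscale_bootstrap(nm, tree, n_boot = 500, seed = s)
    sets <- merge_leaf_sets(tree$merge)
    for (ty in 1:3) {
      target <- which(g$true_type == ty)
      node <- which(vapply(sets, identical, logical(1), y = target))
      expect_length(node, 1L)
      expect_gte(bs$au[node], 0.9)
    }
  }
})

test_that("tree cut assigns types I-III ordered by mean activation", {
  g <- planted_panel(seed = 31)
  nm <- normalize_matrix(g$means)
  ty <- cut_types(hcluster(nm), nm)
  expect_equal(mclust::adjustedRandIndex(ty$type, g$true_type), 1)
  # planted types are ordered by activation, so labels must match exactly
  expect_identical(unname(ty$type), g$true_type)
  expect_true(all(diff(ty$mapping$mean_activation) > 0))

  # k = leaf count: every surface its own cluster
  small <- nm[1:5, ]
  t5 <- cut_types(hcluster(small), small, k = 5L)
  expect_length(unique(t5$type), 5L)

  # degenerate: identical rows cannot support a 3-cluster cut
  same <- matrix(1, 4, 3)
  expect_error(cut_types(hcluster(same), same, k = 3L), "structure")
})

test_that("Newick export is parseable and round-trips the topology", {
  two <- matrix(c(0, 3, 0, 7), 2, 2, dimnames = list(c("A", "B"), NULL))
  h <- hcluster(two)$height[1L]
  expect_identical(newick_export(hcluster(two), digits = 1L),
                   sprintf("(A:%.1f,B:%.1f);", h, h))

  g <- planted_panel(seed = 17, n_surfaces = 6L)
  nm <- normalize_matrix(g$means)
  tree <- hcluster(nm)
  bs <- multiscale_bootstrap(nm, tree, n_boot = 100, seed = 2)
  txt <- newick_export(tree, support = bs)
  ph <- ape::read.tree(text = txt)
  expect_s3_class(ph, "phylo")
  expect_setequal(ph$tip.label, rownames(nm))
  # same bipartitions as the original tree
  ref <- ape::read.tree(text = newick_export(tree))
  expect_equal(ape::dist.topo(ape::unroot(ph), ape::unroot(ref)), 0,
               ignore_attr = TRUE)
  # node labels carry AU percentages
  expect_true(any(grepl("[0-9]", ph$node.label)))

  f <- tempfile(fileext = ".nwk")
  newick_export(tree, bs, file = f)
  expect_identical(readLines(f), txt)
})

test_that("leave-one-out reclustering reports stability of the typing", {
  g <- planted_panel(seed = 23)
  nm <- normalize_matrix(g$means)
  loo <- loo_recluster(nm, k = 3L, drop = "parameters")
  expect_identical(nrow(loo), ncol(nm))
  expect_true(all(loo$ari == 1))  # well-separated: no parameter is critical
})
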