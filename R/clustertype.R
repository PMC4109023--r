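#' @name clustertype
#' @title Hierarchical clustering of surfaces into thrombus types I-III
#'
#' @description
#' Two-way unsupervised hierarchical clustering of the normalized
#' surfaces-by-parameters matrix under Euclidean distance and complete
#' linkage, multiscale-bootstrap assessment of cluster support (bootstrap
#' probabilities BP and approximately unbiased AU p-values), cutting the tree
#' into the three thrombus types, and Newick export of the annotated
#' dendrogram.
NULL

# leaf order of an hclust merge table (left subtree before right)
merge_order <- function(merge) {
  n <- nrow(merge) + 1L
  expand <- function(node) {
    if (node < 0L) return(-node)
    c(expand(merge[node, 1L]), expand(merge[node, 2L]))
  }
  expand(n - 1L)
}

# leaf-index sets of all internal nodes, in merge order
tree_clusters <- function(merge) {
  sets <- vector("list", nrow(merge))
  for (i in seq_len(nrow(merge))) {
    kids <- merge[i, ]
    sets[[i]] <- sort(c(if (kids[1L] < 0L) -kids[1L] else sets[[kids[1L]]],
                        if (kids[2L] < 0L) -kids[2L] else sets[[kids[2L]]]))
  }
  sets
}

cluster_keys <- function(merge)
  vapply(tree_clusters(merge), paste, character(1), collapse = ",")

#' Agglomerative clustering under Euclidean distance and complete linkage
#'
#' Builds the dendrogram used for thrombus typing. Agglomeration is fully
#' deterministic: when several cluster pairs attain the minimal complete-link
#' distance, the pair whose members were created earliest (leaves in input
#' order, then internal nodes in merge order) is merged first.
#'
#' @param m numeric matrix; rows are clustered.
#' @param axis cluster the `"surfaces"` (rows, default) or the
#'   `"parameters"` (columns) of a surfaces-by-parameters matrix.
#' @return An object of class `hclust` (merge, height, order, labels).
#' @export
hcluster <- function(m, axis = c("surfaces", "parameters")) {
  axis <- match.arg(axis)
  if (inherits(m, "parameter_matrix")) m <- m$mean
  stopifnot(is.matrix(m), is.numeric(m))
  if (axis == "parameters") m <- t(m)
  if (nrow(m) < 2L) stop("need at least two items to cluster", call. = FALSE)
  if (anyNA(m)) stop("NaN/NA cells in matrix; clustering refused", call. = FALSE)
  d <- as.matrix(dist(m))
  res <- .agglomerate_complete(d)
  structure(list(merge = res$merge, height = as.numeric(res$height),
                 order = merge_order(res$merge),
                 labels = rownames(m) %||% as.character(seq_len(nrow(m))),
                 method = "complete", dist.method = "euclidean",
                 call = match.call()),
            class = "hclust")
}

#' Multiscale bootstrap support for clusters
#'
#' Assesses the robustness of every cluster of `tree` by resampling the
#' columns of `m` with replacement at a range of sample sizes `n' = r * n`
#' (scales `r` straddling 1), reclustering, and recording how often each
#' cluster reappears (its bootstrap probability `BP(r)`). The signed
#' distance / curvature model `z(r) = v * sqrt(r) + c / sqrt(r)` is fitted to
#' the probit-transformed BP values by weighted least squares, giving the
#' approximately unbiased p-value `AU = 1 - pnorm(v - c)`. Clusters
#' recovered always (or never) at every scale have no finite probit and are
#' clamped to AU 1 (or 0) with `flag = "clamped"`; fits with fewer than
#' three informative scales are flagged `"unstable"`.
#'
#' @param m the matrix that produced `tree` (rows were clustered).
#' @param tree the [hcluster()] result for `m`.
#' @param scales resampling ratios `n'/n`; default ten values in
#'   `[0.5, 1.4]`.
#' @param n_boot bootstrap replicates per scale (default 1000; the
#'   full-fidelity setting of 10000 randomizations is `n_boot = 1000` across
#'   the ten default scales).
#' @param seed integer seed (required).
#' @return A data frame, one row per internal node (in merge order): `node`,
#'   `members` (comma-separated leaf labels), `bp` (BP at the scale nearest
#'   1), `au`, `v`, `c`, `flag`; the full BP-by-scale matrix is in
#'   `attr(, "bp_scales")` and the scales in `attr(, "scales")`.
#' @export
multiscale_bootstrap <- function(m, tree = hcluster(m),
                                 scales = seq(0.5, 1.4, length.out = 10),
                                 n_boot = 1000L, seed) {
  if (inherits(m, "parameter_matrix")) m <- m$mean
  stopifnot(is.matrix(m), inherits(tree, "hclust"), n_boot >= 1L)
  if (min(scales) >= 1 || max(scales) <= 1)
    stop("scales must straddle 1", call. = FALSE)
  seed <- check_seed(seed)
  n <- nrow(m); p <- ncol(m)
  sets <- tree_clusters(tree$merge)
  keys <- vapply(sets, paste, character(1), collapse = ",")
  bp <- matrix(0, length(keys), length(scales),
               dimnames = list(NULL, sprintf("r=%.3f", scales)))
  with_seed(seed, {
    for (s in seq_along(scales)) {
      np <- max(2L, round(scales[s] * p))
      idx <- matrix(sample.int(p, np * n_boot, replace = TRUE), np, n_boot)
      if (n <= 64L) {
        bp[, s] <- .bootstrap_hits(m, idx, sets) / n_boot
      } else {
        counts <- numeric(length(keys))
        for (b in seq_len(n_boot)) {
          rk <- cluster_keys(.agglomerate_complete(
            as.matrix(dist(m[, idx[, b], drop = FALSE])))$merge)
          counts <- counts + !is.na(match(keys, rk))
        }
        bp[, s] <- counts / n_boot
      }
    }
  })
  r1 <- which.min(abs(scales - 1))
  fits <- t(vapply(seq_along(keys), function(i) {
    f <- au_from_bp(bp[i, ], scales, n_boot)
    c(f$au, f$v, f$c, match(f$flag, c("ok", "clamped", "unstable")) - 1)
  }, numeric(4)))
  colnames(fits) <- c("au", "v", "c", "flag")
  out <- data.frame(node = seq_along(keys),
                    members = vapply(strsplit(keys, ","), function(i)
                      paste(tree$labels[as.integer(i)], collapse = ","),
                      character(1)),
                    bp = bp[, r1], au = fits[, "au"],
                    v = fits[, "v"], c = fits[, "c"],
                    flag = c("ok", "clamped", "unstable")[fits[, "flag"] + 1L],
                    row.names = NULL)
  attr(out, "bp_scales") <- bp
  attr(out, "scales") <- scales
  out
}

#' Approximately unbiased p-value from multiscale bootstrap probabilities
#'
#' Fits the signed distance / curvature model `qnorm(1 - BP(r)) = v * sqrt(r)
#' + c / sqrt(r)` to the probit-transformed bootstrap probabilities by
#' weighted least squares (binomial weights), refines `(v, c)` by maximum
#' likelihood on the binomial recovery counts, and returns
#' `AU = 1 - pnorm(v - c)`. The likelihood refinement keeps the fit well
#' defined when most scales sit at the boundary (BP of exactly 0 or 1, no
#' finite probit), the typical profile of strongly supported clusters at
#' finite `n_boot`. Clusters recovered always (or never) at *every* scale
#' are clamped to AU 1 (or 0) with `flag = "clamped"`; fits with fewer than
#' three scales are flagged `"unstable"`. A flat profile `BP(r) = 0.5`
#' gives `v = c = 0` and `AU = 0.5` exactly.
#'
#' @param bp bootstrap probabilities, one per scale.
#' @param scales resampling ratios `n'/n`.
#' @param n_boot replicates per scale (enters the weights).
#' @return A list: `au`, `bp_corrected` (`1 - pnorm(v + c)`), `v`, `c`,
#'   `flag`.
#' @export
au_from_bp <- function(bp, scales, n_boot) {
  stopifnot(length(bp) == length(scales))
  if (all(bp == 1))
    return(list(au = 1, bp_corrected = 1, v = NA_real_, c = NA_real_,
                flag = "clamped"))
  if (all(bp == 0))
    return(list(au = 0, bp_corrected = 0, v = NA_real_, c = NA_real_,
                flag = "clamped"))
  if (length(scales) < 3L)
    return(list(au = round(mean(bp)), bp_corrected = round(mean(bp)),
                v = NA_real_, c = NA_real_, flag = "unstable"))
  r <- scales
  # starting value: weighted least squares on the probit scale, with
  # boundary counts pulled half a replicate inward (a BP of exactly 0 or 1
  # has no finite probit)
  b <- pmin(pmax(bp, 0.5 / n_boot), (n_boot - 0.5) / n_boot)
  z <- qnorm(1 - b)
  X <- cbind(sqrt(r), 1 / sqrt(r))
  w <- n_boot * stats::dnorm(z)^2 / (b * (1 - b))
  cf <- unname(stats::lm.wfit(X, z, w)$coefficients)
  # maximum-likelihood refinement on the binomial counts themselves: unlike
  # the probit-scale WLS, the likelihood is well defined at boundary counts,
  # which dominate the profile of strongly supported clusters
  k <- bp * n_boot
  nll <- function(par) {
    p <- pnorm(-(par[1] * sqrt(r) + par[2] / sqrt(r)))
    p <- pmin(pmax(p, 1e-16), 1 - 1e-16)
    -sum(k * log(p) + (n_boot - k) * log1p(-p))
  }
  fit <- stats::optim(cf, nll, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  v <- fit$par[1]; cc <- fit$par[2]
  list(au = 1 - pnorm(v - cc), bp_corrected = 1 - pnorm(v + cc),
       v = v, c = cc, flag = "ok")
}

#' Cut the surface tree into thrombus types I-III
#'
#' Cuts the dendrogram at `k` clusters and orders the clusters by their mean
#' normalized value over all parameters, ascending: the least active cluster
#' becomes type I (few single platelets), the most active type III (large,
#' fully activated aggregates). Ties in cluster means are broken by cluster
#' size (descending), then by the lowest member surface index.
#'
#' @param tree [hcluster()] tree over surfaces.
#' @param m the normalized matrix the tree was built from.
#' @param k number of types (default 3).
#' @return A `type_assignment`: `type` (named integer vector per surface),
#'   `cluster` (raw cut labels), `mapping` (data frame cluster, type,
#'   mean_activation, size).
#' @export
cut_types <- function(tree, m, k = 3L) {
  if (inherits(m, "parameter_matrix")) m <- m$mean
  stopifnot(inherits(tree, "hclust"), is.matrix(m),
            nrow(m) == length(tree$order), k >= 1L, k <= nrow(m))
  n <- nrow(m)
  if (k > 1L && tree$height[n - k + 1L] <= 0)
    stop("no ", k, "-cluster structure: the cut falls among zero-height ",
         "merges (identical rows)", call. = FALSE)
  cl <- cutree(tree, k = k)
  means <- tapply(rowMeans(m), cl, mean)
  sizes <- tapply(seq_len(n), cl, length)
  first <- tapply(seq_len(n), cl, min)
  ord <- order(means, -sizes, first)
  mapping <- data.frame(cluster = as.integer(names(means))[ord],
                        type = seq_len(k),
                        mean_activation = as.numeric(means)[ord],
                        size = as.integer(sizes)[ord])
  type <- mapping$type[match(cl, mapping$cluster)]
  names(type) <- tree$labels
  structure(list(type = type, cluster = cl, mapping = mapping, k = k),
            class = "type_assignment")
}

#' Export a support-annotated dendrogram as Newick text
#'
#' Branch lengths are differences of complete-linkage merge heights; internal
#' node labels carry the AU support in percent (and BP when available) from a
#' [multiscale_bootstrap()] table.
#'
#' @param tree an [hcluster()] result.
#' @param support optional support table from [multiscale_bootstrap()].
#' @param file optional path; when given the text is written there.
#' @param digits branch-length precision.
#' @return The Newick string, invisibly when written to `file`.
#' @export
newick_export <- function(tree, support = NULL, file = NULL, digits = 6L) {
  stopifnot(inherits(tree, "hclust"))
  n <- length(tree$order)
  lab <- gsub("[(),:;\\s]", "_", tree$labels)
  node_label <- function(i) {
    if (is.null(support)) return("")
    sprintf("%.0f", 100 * support$au[support$node == i])
  }
  build <- function(node, parent_h) {
    if (node < 0L)
      return(sprintf("%s:%.*f", lab[-node], digits, parent_h))
    h <- tree$height[node]
    kids <- tree$merge[node, ]
    sprintf("(%s,%s)%s:%.*f", build(kids[1L], h), build(kids[2L], h),
            node_label(node), digits, parent_h - h)
  }
  root <- n - 1L
  kids <- tree$merge[root, ]
  h <- tree$height[root]
  txt <- sprintf("(%s,%s)%s;", build(kids[1L], h), build(kids[2L], h),
                 node_label(root))
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

#' Leave-one-out robustness of the type assignment
#'
#' Sensitivity analysis for redundancy of surfaces or parameters: drops each
#' item in turn, reclusters, recuts at `k`, and reports the agreement
#' (adjusted Rand index) with the full-data assignment on the retained
#' surfaces.
#'
#' @param m normalized surfaces-by-parameters matrix.
#' @param k number of types (default 3).
#' @param drop drop `"parameters"` (default) or `"surfaces"`.
#' @return Data frame `dropped`, `ari`.
#' @export
loo_recluster <- function(m, k = 3L, drop = c("parameters", "surfaces")) {
  drop <- match.arg(drop)
  if (inherits(m, "parameter_matrix")) m <- m$mean
  full <- cut_types(hcluster(m), m, k = k)$type
  items <- if (drop == "parameters") seq_len(ncol(m)) else seq_len(nrow(m))
  res <- vapply(items, function(i) {
    mi <- if (drop == "parameters") m[, -i, drop = FALSE] else m[-i, , drop = FALSE]
    ti <- cut_types(hcluster(mi), mi, k = k)$type
    ref <- if (drop == "parameters") full else full[-i]
    mclust::adjustedRandIndex(ref, ti)
  }, numeric(1))
  nm <- if (drop == "parameters") colnames(m) else rownames(m)
  data.frame(dropped = nm %||% as.character(items), ari = res)
}
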