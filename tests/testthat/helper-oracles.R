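# Independent oracles used across the suite. These deliberately use naive,
# transparent algorithms (queue-based flood fill, from-scratch linkage
# recomputation, textbook NIPALS) so they share no code path with the package.

# flood-fill connected-component labelling, pure R
flood_fill_label <- function(mask, connectivity = 8L) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nb <- if (connectivity == 4L)
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  else
    cbind(c(-1, 1, 0, 0, -1, -1, 1, 1), c(0, 0, -1, 1, -1, 1, -1, 1))
  nextlab <- 0L
  for (c0 in seq_len(nc)) for (r0 in seq_len(nr)) {
    if (mask[r0, c0] == 0 || lab[r0, c0] != 0) next
    nextlab <- nextlab + 1L
    queue <- list(c(r0, c0))
    lab[r0, c0] <- nextlab
    while (length(queue)) {
      p <- queue[[1L]]; queue <- queue[-1L]
      for (k in seq_len(nrow(nb))) {
        r <- p[1L] + nb[k, 1L]; c <- p[2L] + nb[k, 2L]
        if (r >= 1 && r <= nr && c >= 1 && c <= nc &&
            mask[r, c] != 0 && lab[r, c] == 0L) {
          lab[r, c] <- nextlab
          queue[[length(queue) + 1L]] <- c(r, c)
        }
      }
    }
  }
  lab
}

# exhaustive complete-linkage agglomeration: at every step the inter-cluster
# distance is recomputed from scratch as the max over all cross pairs of the
# original distance matrix; ties broken by earliest-created pair
brute_complete_linkage <- function(m) {
  d0 <- as.matrix(dist(m))
  n <- nrow(m)
  clusters <- as.list(seq_len(n))
  heights <- numeric(n - 1L)
  partitions <- vector("list", n - 1L)
  for (step in seq_len(n - 1L)) {
    k <- length(clusters)
    best <- Inf; bi <- bj <- NA
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
      dij <- max(d0[clusters[[i]], clusters[[j]]])
      if (dij < best) { best <- dij; bi <- i; bj <- j }
    }
    merged <- sort(c(clusters[[bi]], clusters[[bj]]))
    heights[step] <- best
    partitions[[step]] <- merged
    # new cluster takes slot bi so creation order matches the
    # implementation's slot-ordering convention
    clusters <- append(clusters[-c(bi, bj)], list(merged), after = bi - 1L)
  }
  list(heights = heights, partitions = partitions)
}

# leaf sets of each internal node of an hclust merge table
merge_leaf_sets <- function(merge) {
  sets <- vector("list", nrow(merge))
  for (i in seq_len(nrow(merge))) {
    kids <- merge[i, ]
    sets[[i]] <- sort(c(if (kids[1L] < 0L) -kids[1L] else sets[[kids[1L]]],
                        if (kids[2L] < 0L) -kids[2L] else sets[[kids[2L]]]))
  }
  sets
}

# textbook NIPALS PLS1, written step by step with explicit loops
nipals_oracle_predict <- function(X, y, ncomp, newX = X) {
  xc <- colMeans(X); yc <- mean(y)
  E <- sweep(X, 2, xc); f <- y - yc
  W <- P <- NULL; qs <- c()
  for (a in seq_len(ncomp)) {
    w <- as.numeric(t(E) %*% f)
    w <- w / sqrt(sum(w * w))
    t_a <- as.numeric(E %*% w)
    p_a <- as.numeric(t(E) %*% t_a) / sum(t_a * t_a)
    q_a <- sum(f * t_a) / sum(t_a * t_a)
    E <- E - outer(t_a, p_a)
    f <- f - q_a * t_a
    W <- cbind(W, w); P <- cbind(P, p_a); qs <- c(qs, q_a)
  }
  B <- W %*% solve(t(P) %*% W) %*% qs
  as.numeric(yc + sweep(newX, 2, xc) %*% B)
}

# a small planted matrix + its truth, shared by clustering tests
planted_panel <- function(seed, n_surfaces = 52L, noise_sd = 0.75) {
  gen_parameter_matrix(planted_matrix_truth(n_surfaces = n_surfaces,
                                            noise_sd = noise_sd, seed = seed))
}

# separable receptor design: linear margins >= 0.4 from rounding boundaries,
# no clamping (noise-free responses in {1.1, 2, 2.9})
separable_receptor_truth <- function(noise_sd, seed) {
  beta <- c(intercept = 2, setNames(rep(0, 9), RECEPTOR_PANEL))
  beta["GPVI"] <- 0.9
  beta["a5b1"] <- -0.9
  planted_receptor_truth(beta_true = beta, noise_sd = noise_sd, seed = seed)
}
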