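# Independent brute-force oracles and small fixtures, built in code.

all_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in all_perms(v[-i])) out <- c(out, list(c(v[i], rest)))
  }
  out
}

# Every simple path between two nodes, as node index vectors.
enumerate_paths <- function(p, from, to) {
  others <- setdiff(seq_len(p), c(from, to))
  paths <- list(c(from, to))
  for (k in seq_along(others)) {
    for (mid in utils::combn(others, k, simplify = FALSE)) {
      for (perm in all_perms(mid)) paths <- c(paths, list(c(from, perm, to)))
    }
  }
  paths
}

path_length <- function(W, path) {
  len <- 0
  for (i in seq_len(length(path) - 1)) {
    w <- W[path[i], path[i + 1]]
    if (w == 0) return(Inf)
    len <- len + 1 / abs(w)
  }
  len
}

# Exhaustive shortest-path distances under the 1/|w| length convention.
oracle_distances <- function(W) {
  p <- nrow(W)
  D <- matrix(0, p, p)
  for (i in seq_len(p - 1)) {
    for (j in seq(i + 1, p)) {
      lens <- vapply(enumerate_paths(p, i, j), path_length, numeric(1),
                     W = W)
      D[i, j] <- D[j, i] <- min(lens)
    }
  }
  D
}

oracle_closeness <- function(W) {
  D <- oracle_distances(W)
  diag(D) <- NA
  vapply(seq_len(nrow(D)), function(i) {
    d <- D[i, ]
    d <- d[!is.na(d) & is.finite(d)]
    if (length(d) == 0) 0 else 1 / sum(d)
  }, numeric(1))
}

# Fractional betweenness by enumerating all geodesics per pair.
oracle_betweenness <- function(W, tol = 1e-9) {
  p <- nrow(W)
  b <- numeric(p)
  for (i in seq_len(p - 1)) {
    for (j in seq(i + 1, p)) {
      paths <- enumerate_paths(p, i, j)
      lens <- vapply(paths, path_length, numeric(1), W = W)
      best <- min(lens)
      if (!is.finite(best)) next
      geo <- paths[lens <= best * (1 + tol)]
      for (g in geo) {
        interior <- setdiff(g, c(i, j))
        if (length(interior) > 0) {
          b[interior] <- b[interior] + 1 / length(geo)
        }
      }
    }
  }
  b
}

# Random sparse symmetric weight matrix (connected-ish, mixed signs).
random_weights <- function(p, density = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  W <- matrix(0, p, p)
  ut <- which(upper.tri(W))
  on <- ut[runif(length(ut)) < density]
  W[on] <- runif(length(on), 0.05, 0.9) * sample(c(-1, 1), length(on),
                                                 replace = TRUE)
  W[lower.tri(W)] <- t(W)[lower.tri(W)]
  W
}

# Small two-domain spec with one strong planted edge, for bootstrap tests.
small_spec <- function(edge = 0.5, n1 = 150L, n2 = 150L, seed = 1L) {
  rho <- matrix(0, 4, 4)
  rho[1, 2] <- rho[2, 1] <- edge
  meta <- node_metadata(paste0("N", 1:4),
                        c("one", "one", "two", "two"))
  meta$value_kind <- rep("continuous_nonneg", 4)
  synthetic_spec(
    true_partial = rho, node_meta = meta,
    group_means = list(a = rep(10, 4), b = rep(10, 4)),
    group_sizes = c(n1, n2), noise_sd = rep(1, 4), seed = seed
  )
}

# Default spec with the two group means equalized: draws come from the
# shared within-group covariance structure, so pooled estimates recover
# the planted partial correlations without the group-shift component.
null_shift_spec <- function(n1 = 1000L, n2 = 1000L, seed = 1L) {
  spec <- default_spec(seed = seed)
  means <- (unlist(spec$group_means[[1]]) + unlist(spec$group_means[[2]])) / 2
  synthetic_spec(
    true_partial = spec$true_partial, node_meta = spec$node_meta,
    group_means = list(ds = means, nds = means),
    group_sizes = c(n1, n2), noise_sd = spec$noise_sd, seed = seed
  )
}

expect_identical_files <- function(a, b) {
  expect_identical(readLines(a), readLines(b))
}
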