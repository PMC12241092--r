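#' Specification of a synthetic two-group dataset
#'
#' A `synthetic_spec` fixes everything the generator needs: a ground-truth
#' partial-correlation matrix, node metadata with a measurement kind per
#' variable, target group means on the latent scale, per-variable dispersions
#' and group sizes. Sampling from the same spec and seed is bit-reproducible.
#'
#' @param true_partial Symmetric p x p matrix of ground-truth partial
#'   correlations; zero diagonal, entries in (-1, 1). The implied precision
#'   matrix (see [partial_to_precision()]) must be positive definite.
#' @param node_meta Node metadata ([node_metadata()]) with an extra
#'   `value_kind` column; each kind is one of `"ordinal_0_6"` (rounded and
#'   clamped to 0..6), `"bounded_0_48"` (rounded and clamped to 0..48) or
#'   `"continuous_nonneg"` (clamped at 0).
#' @param group_means List of two numeric vectors of length p: target means
#'   for the first (DS-like) and second (NDS-like) group.
#' @param group_sizes Integer vector of two group sizes (defaults 70 and 91).
#' @param noise_sd Per-variable latent standard deviations, length p.
#' @param seed Integer RNG seed stored with the spec.
#' @return An object of class `synthetic_spec`.
#' @seealso [default_spec()], [sample_dataset()]
#' @export
synthetic_spec <- function(true_partial, node_meta, group_means,
                           group_sizes = c(70L, 91L), noise_sd, seed = 1L) {
  true_partial <- as.matrix(true_partial)
  p <- nrow(true_partial)
  if (ncol(true_partial) != p ||
      max(abs(true_partial - t(true_partial))) > 1e-12) {
    stop("true_partial must be a symmetric square matrix")
  }
  if (any(abs(diag(true_partial)) > 0)) {
    stop("true_partial must have a zero diagonal")
  }
  if (any(abs(true_partial) >= 1)) {
    stop("partial correlations must lie strictly inside (-1, 1)")
  }
  if (nrow(node_meta) != p) {
    stop("node_meta must describe exactly ", p, " nodes")
  }
  kinds <- c("ordinal_0_6", "bounded_0_48", "continuous_nonneg")
  if (is.null(node_meta$value_kind) || !all(node_meta$value_kind %in% kinds)) {
    stop("node_meta$value_kind must be one of: ",
         paste(kinds, collapse = ", "))
  }
  if (length(group_means) != 2 ||
      !all(lengths(group_means) == p)) {
    stop("group_means must be two vectors of length ", p)
  }
  group_sizes <- as.integer(group_sizes)
  if (length(group_sizes) != 2 || any(group_sizes < 2)) {
    stop("group_sizes must be two integers >= 2")
  }
  if (length(noise_sd) != p || any(noise_sd <= 0)) {
    stop("noise_sd must be ", p, " positive dispersions")
  }
  # fail early if the implied precision matrix is not positive definite
  partial_to_precision(true_partial)
  structure(
    list(true_partial = true_partial, node_meta = node_meta,
         group_means = group_means, group_sizes = group_sizes,
         noise_sd = as.numeric(noise_sd), seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

#' @export
print.synthetic_spec <- function(x, ...) {
  p <- nrow(x$true_partial)
  nz <- sum(abs(x$true_partial[upper.tri(x$true_partial)]) > 0)
  cat(sprintf("synthetic_spec: %d nodes, %d true edges, groups n = %d / %d, seed %d\n",
              p, nz, x$group_sizes[1], x$group_sizes[2], x$seed))
  invisible(x)
}

#' Default 18-node two-group specification
#'
#' Emulates a dataset of 13 negative-symptom items (B1-B13, 0-6 ratings),
#' four cognitive-domain scores (Y1 sustained attention, Y2 cognitive
#' flexibility, Y3 ideation fluency, Y4 visuospatial memory) and one
#' social-function total (SSPI, 0-48), observed in a deficit-syndrome-like
#' group (n = 70) and a non-deficit-like group (n = 91).
#'
#' The ground-truth partial-correlation structure is block wise: 0.3 for the
#' strongly coupled pairs (Y1, Y2), (B12, B13), (B5, B6), (B7, B8); 0.25
#' within the anhedonia triad (B1, B2, B3) and the expressivity triad
#' (B9, B10, B11); and 0.15 edges bridging SSPI to B1, B2, Y1 and Y3. All
#' other pairs are conditionally independent. Group means and per-variable
#' dispersions come from [reference_group_summaries()]; symptom and
#' cognitive-impairment scores are higher, and the social-function total is
#' lower, in the DS-like group.
#'
#' @param seed Seed stored with the spec (default 1).
#' @return A [synthetic_spec()].
#' @export
default_spec <- function(seed = 1L) {
  ids <- c(paste0("B", 1:13), paste0("Y", 1:4), "SSPI")
  domain <- c(rep("negative_symptoms", 13), rep("cognition", 4),
              "social_function")
  labels <- c("Intensity of pleasure during activities",
              "Frequency of pleasure during activities",
              "Intensity of expected pleasure from future activities",
              "Distress",
              "Asociality: behavior", "Asociality: internal experience",
              "Avolition: behavior", "Avolition: internal experience",
              "Facial expression", "Vocal expression", "Expressive gestures",
              "Quantity of speech", "Spontaneous elaboration",
              "Sustained attention", "Cognitive flexibility",
              "Ideation fluency", "Visuospatial memory",
              "Social function total")
  meta <- node_metadata(ids, domain, labels)
  meta$value_kind <- c(rep("ordinal_0_6", 13),
                       rep("continuous_nonneg", 4), "bounded_0_48")

  rho <- matrix(0, 18, 18, dimnames = list(ids, ids))
  set_edge <- function(a, b, v) {
    rho[a, b] <<- v
    rho[b, a] <<- v
  }
  set_edge("Y1", "Y2", 0.30)
  set_edge("B12", "B13", 0.30)
  set_edge("B5", "B6", 0.30)
  set_edge("B7", "B8", 0.30)
  for (pair in utils::combn(c("B1", "B2", "B3"), 2, simplify = FALSE)) {
    set_edge(pair[1], pair[2], 0.25)
  }
  for (pair in utils::combn(c("B9", "B10", "B11"), 2, simplify = FALSE)) {
    set_edge(pair[1], pair[2], 0.25)
  }
  for (b in c("B1", "B2", "Y1", "Y3")) set_edge("SSPI", b, 0.15)

  summ <- reference_group_summaries()
  summ <- summ[match(ids, summ$variable), ]
  sds <- reference_sds()
  sds <- sds[match(ids, sds$variable), ]
  synthetic_spec(
    true_partial = rho,
    node_meta = meta,
    group_means = list(ds = summ$mean_ds, nds = summ$mean_nds),
    group_sizes = c(70L, 91L),
    noise_sd = (sds$sd_ds + sds$sd_nds) / 2,
    seed = seed
  )
}

#' Convert a partial-correlation matrix to a precision matrix
#'
#' Uses the standard identity `rho_ij = -theta_ij / sqrt(theta_ii theta_jj)`
#' with unit diagonal scaling: `theta_ii = 1`, `theta_ij = -rho_ij`.
#'
#' @param true_partial Symmetric matrix with zero diagonal, entries in
#'   (-1, 1).
#' @return The precision matrix Theta.
#' @section Errors: If the implied Theta is not positive definite the error
#'   message reports the smallest eigenvalue; shrink the partial correlations
#'   toward zero to fix this.
#' @export
partial_to_precision <- function(true_partial) {
  true_partial <- as.matrix(true_partial)
  if (max(abs(true_partial - t(true_partial))) > 1e-12) {
    stop("true_partial must be symmetric")
  }
  if (any(abs(diag(true_partial)) > 0)) {
    stop("true_partial must have a zero diagonal")
  }
  if (any(abs(true_partial) >= 1)) {
    stop("partial correlations must lie strictly inside (-1, 1)")
  }
  theta <- -true_partial
  diag(theta) <- 1
  ev <- eigen(theta, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    stop(sprintf(paste0("implied precision matrix is not positive definite ",
                        "(smallest eigenvalue %.6g); shrink the partial ",
                        "correlations"), min(ev)))
  }
  theta
}

#' Sample a two-group dataset from a synthetic specification
#'
#' Draws latent multivariate-normal deviates whose correlation matrix is the
#' normalized inverse of the precision implied by `spec$true_partial`, scales
#' them by `spec$noise_sd`, shifts each group to its target latent means, and
#' finally discretizes each variable according to its `value_kind` (a 0-6
#' rating arises by rounding and clamping a continuous liability; the 0-48
#' total analogously; non-negative continuous scores are floored at zero).
#' Group mean shifts act before discretization so the latent covariance
#' structure is shared by both groups.
#'
#' @param spec A [synthetic_spec()].
#' @param discretize If `FALSE` the latent continuous values are returned
#'   unclamped — useful for estimator-consistency checks without
#'   discretization attenuation.
#' @param seed Overrides `spec$seed` when given.
#' @return An [item_dataset()] with group labels `"DS"` and `"NDS"`.
#' @export
sample_dataset <- function(spec, discretize = TRUE, seed = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (any(spec$group_sizes < 2)) stop("group_sizes must be >= 2")
  theta <- partial_to_precision(spec$true_partial)
  sigma <- solve(theta)
  d <- 1 / sqrt(diag(sigma))
  corr <- d * sigma * rep(d, each = nrow(sigma))   # normalized inverse
  scale_mat <- spec$noise_sd %o% spec$noise_sd
  sigma_scaled <- corr * scale_mat
  n1 <- spec$group_sizes[1]
  n2 <- spec$group_sizes[2]
  x <- with_seed(seed %||% spec$seed, {
    x1 <- MASS::mvrnorm(n1, mu = unlist(spec$group_means[[1]]),
                        Sigma = sigma_scaled)
    x2 <- MASS::mvrnorm(n2, mu = unlist(spec$group_means[[2]]),
                        Sigma = sigma_scaled)
    rbind(x1, x2)
  })
  colnames(x) <- spec$node_meta$node_id
  if (discretize) {
    for (j in seq_len(ncol(x))) {
      x[, j] <- switch(
        spec$node_meta$value_kind[j],
        ordinal_0_6 = pmin(pmax(round(x[, j]), 0), 6),
        bounded_0_48 = pmin(pmax(round(x[, j]), 0), 48),
        continuous_nonneg = pmax(x[, j], 0)
      )
    }
  }
  item_dataset(
    x, spec$node_meta[, c("node_id", "label", "domain")],
    group = rep(c("DS", "NDS"), c(n1, n2))
  )
}

#' Write a synthetic specification to a YAML document
#'
#' Serializes the spec as plain text: node roster (with kinds), nonzero
#' upper-triangle partial correlations as an edge list, group means, sizes,
#' dispersions and seed. [read_spec()] reconstructs an identical spec.
#'
#' @param spec A [synthetic_spec()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_spec <- function(spec, path) {
  ids <- spec$node_meta$node_id
  ut <- which(upper.tri(spec$true_partial) & spec$true_partial != 0,
              arr.ind = TRUE)
  num <- function(x) sprintf("%.17g", x)  # %.17g round-trips doubles
  edges <- lapply(seq_len(nrow(ut)), function(i) {
    list(a = ids[ut[i, 1]], b = ids[ut[i, 2]],
         value = num(spec$true_partial[ut[i, 1], ut[i, 2]]))
  })
  doc <- list(
    nodes = lapply(seq_along(ids), function(i) {
      list(id = ids[i], label = spec$node_meta$label[i],
           domain = spec$node_meta$domain[i],
           value_kind = spec$node_meta$value_kind[i])
    }),
    true_partial_edges = edges,
    group_means = list(ds = num(unlist(spec$group_means[[1]])),
                       nds = num(unlist(spec$group_means[[2]]))),
    group_sizes = as.integer(spec$group_sizes),
    noise_sd = num(spec$noise_sd),
    seed = spec$seed
  )
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Read a synthetic specification from a YAML document
#'
#' @param path Path written by [write_spec()].
#' @return A [synthetic_spec()].
#' @export
read_spec <- function(path) {
  doc <- yaml::read_yaml(path)
  ids <- vapply(doc$nodes, function(n) as.character(n$id), "")
  meta <- node_metadata(
    ids,
    domain = vapply(doc$nodes, function(n) as.character(n$domain), ""),
    label = vapply(doc$nodes, function(n) as.character(n$label %||% n$id), "")
  )
  meta$value_kind <- vapply(doc$nodes,
                            function(n) as.character(n$value_kind), "")
  p <- length(ids)
  rho <- matrix(0, p, p, dimnames = list(ids, ids))
  for (e in doc$true_partial_edges) {
    rho[e$a, e$b] <- as.numeric(e$value)
    rho[e$b, e$a] <- as.numeric(e$value)
  }
  synthetic_spec(
    true_partial = rho, node_meta = meta,
    group_means = list(ds = as.numeric(doc$group_means$ds),
                       nds = as.numeric(doc$group_means$nds)),
    group_sizes = as.integer(doc$group_sizes),
    noise_sd = as.numeric(doc$noise_sd),
    seed = as.integer(doc$seed)
  )
}
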