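#' Correlation matrix of a dataset
#'
#' Pairwise product-moment (or rank) correlations of the score columns, the
#' input to the graphical lasso. The diagonal is exactly 1.
#'
#' @param dataset An [item_dataset()].
#' @param method `"pearson"` (default; 0-6 clinical ratings are treated as
#'   continuous) or `"spearman"`.
#' @return An object of class `correlation_matrix`: list with `S` (p x p
#'   matrix), `n`, `p`, `method`.
#' @export
correlation_matrix <- function(dataset,
                               method = c("pearson", "spearman")) {
  method <- match.arg(method)
  x <- dataset$values
  sds <- apply(x, 2, sd)
  if (any(sds == 0)) {
    stop("constant column(s): ",
         paste(dataset$nodes$node_id[sds == 0], collapse = ", "))
  }
  S <- cor(x, method = method)
  S <- (S + t(S)) / 2
  diag(S) <- 1
  structure(list(S = S, n = nrow(x), p = ncol(x), method = method),
            class = "correlation_matrix")
}

as_cor_matrix <- function(S) {
  if (inherits(S, "correlation_matrix")) S$S else as.matrix(S)
}

#' Graphical lasso at a fixed penalty
#'
#' L1-penalized maximum-likelihood estimate of a sparse precision matrix:
#' maximizes `log det(Theta) - tr(S Theta) - lambda * sum_(i!=j) |theta_ij|`
#' by block coordinate descent. Only off-diagonal entries are penalized, so
#' the implied covariance keeps the observed diagonal and the derived
#' partial correlations stay scale-consistent. At `lambda = 0` the
#' unpenalized maximum-likelihood solution `solve(S)` is returned directly.
#'
#' The converged solution satisfies the stationarity (KKT) conditions
#' `|sigma_hat_ij - S_ij| <= lambda + tol` for all `i != j`, with
#' `sigma_hat_ij - S_ij = lambda * sign(theta_ij)` on active entries.
#'
#' @param S A [correlation_matrix()] or a plain covariance/correlation
#'   matrix.
#' @param lambda Penalty, `>= 0`.
#' @param tol Convergence tolerance on the maximum parameter change per
#'   sweep (default 1e-7).
#' @param max_sweeps Sweep cap (default 10000).
#' @param warm Optional previous `precision_estimate` used as a warm start
#'   along a penalty path.
#' @return An object of class `precision_estimate`: list with `theta`,
#'   `sigma` (implied covariance), `lambda`, `sweeps`, `converged`.
#' @export
glasso <- function(S, lambda, tol = 1e-7, max_sweeps = 10000L, warm = NULL) {
  Sm <- as_cor_matrix(S)
  if (lambda < 0) stop("lambda must be >= 0")
  if (lambda == 0) {
    theta <- tryCatch(solve(Sm), error = function(e) {
      stop("S is singular; the unpenalized estimate needs lambda > 0")
    })
    theta <- (theta + t(theta)) / 2
    fit <- list(theta = theta, sigma = Sm, beta = NULL,
                sweeps = 0L, converged = TRUE)
  } else {
    fit <- glasso_cd(Sm, lambda, tol, as.integer(max_sweeps),
                     sigma_init = warm$sigma, beta_init = warm$beta)
    if (!fit$converged) {
      stop(sprintf(paste0("graphical lasso did not converge in %d sweeps ",
                          "(final max parameter change %.3g)"),
                   max_sweeps, fit$max_change))
    }
  }
  structure(
    list(theta = fit$theta, sigma = fit$sigma, beta = fit$beta,
         lambda = lambda, sweeps = fit$sweeps, converged = fit$converged),
    class = "precision_estimate"
  )
}

#' Standardize a precision matrix to partial correlations
#'
#' `w_ij = -theta_ij / sqrt(theta_ii * theta_jj)` with the diagonal set to
#' zero: the edge weights of a Gaussian graphical model.
#'
#' @param theta Symmetric positive-definite precision matrix, or a
#'   `precision_estimate`.
#' @return Symmetric weight matrix with zero diagonal.
#' @export
precision_to_partial <- function(theta) {
  if (inherits(theta, "precision_estimate")) theta <- theta$theta
  theta <- as.matrix(theta)
  d <- diag(theta)
  if (any(d <= 0)) {
    stop("precision matrix has non-positive diagonal entries")
  }
  s <- 1 / sqrt(d)
  W <- -theta * (s %o% s)
  diag(W) <- 0
  (W + t(W)) / 2
}

#' Extended Bayesian information criterion of a Gaussian graphical model
#'
#' `EBIC = -2 l + E log(n) + 4 E gamma log(p)` where
#' `l = (n/2) (log det Theta - tr(S Theta))` and `E` is the number of
#' nonzero upper-triangle off-diagonal entries of `Theta`. `gamma = 0`
#' recovers the ordinary BIC penalty.
#'
#' @param theta Precision matrix or `precision_estimate`.
#' @param S Correlation matrix (object or matrix) the model was fitted to.
#' @param n Number of subjects (taken from `S` when it carries one).
#' @param gamma EBIC hyperparameter, `>= 0`.
#' @return The EBIC score (smaller is better).
#' @export
ebic <- function(theta, S, n = NULL, gamma = 0.5) {
  if (inherits(theta, "precision_estimate")) theta <- theta$theta
  if (inherits(S, "correlation_matrix")) {
    n <- n %||% S$n
    S <- S$S
  }
  if (is.null(n)) stop("n is required")
  if (gamma < 0) stop("gamma must be >= 0")
  p <- nrow(theta)
  ld <- determinant(theta, logarithm = TRUE)
  if (ld$sign <= 0 || !is.finite(ld$modulus)) {
    stop("theta must be positive definite (singular or indefinite input)")
  }
  loglik <- (n / 2) * (as.numeric(ld$modulus) - sum(S * theta))
  E <- sum(abs(theta[upper.tri(theta)]) > 0)
  -2 * loglik + E * log(n) + 4 * E * gamma * log(p)
}

#' Estimate a regularized partial-correlation network
#'
#' The full estimation routine: correlation matrix, graphical lasso along a
#' descending log-spaced penalty path from `lambda_max = max |S_ij|` (i != j)
#' down to `lambda_max * lambda_min_ratio` with warm starts, EBIC model
#' selection, and standardization of the selected precision matrix to
#' partial-correlation edge weights. Weights with absolute value below
#' `1e-10` are set to exactly zero so edge counts are well defined.
#'
#' @param dataset An [item_dataset()].
#' @param gamma EBIC hyperparameter (default 0.5).
#' @param n_lambda Path length (default 100).
#' @param lambda_min_ratio Smallest penalty as a fraction of `lambda_max`
#'   (default 0.01).
#' @param method Correlation method, see [correlation_matrix()].
#' @return An object of class `network_model`: list with `W` (weight
#'   matrix), `nodes`, `lambda`, `gamma`, `ebic`, `n_edges`, `n_positive`,
#'   `possible_pairs`, `n`, `lambda_path`, `ebic_path`, `method`.
#' @export
estimate_network <- function(dataset, gamma = 0.5, n_lambda = 100L,
                             lambda_min_ratio = 0.01,
                             method = c("pearson", "spearman")) {
  method <- match.arg(method)
  S <- correlation_matrix(dataset, method = method)
  p <- S$p
  off <- abs(S$S[upper.tri(S$S)])
  lambda_max <- max(off)
  if (lambda_max <= 0) lambda_max <- lambda_min_ratio  # fully diagonal S
  path <- exp(seq(log(lambda_max), log(lambda_max * lambda_min_ratio),
                  length.out = n_lambda))
  fits <- vector("list", n_lambda)
  scores <- numeric(n_lambda)
  warm <- NULL
  for (i in seq_len(n_lambda)) {
    fits[[i]] <- glasso(S, path[i], warm = warm)
    warm <- fits[[i]]
    scores[i] <- ebic(fits[[i]], S, gamma = gamma)
  }
  best <- which.min(scores)  # ties resolve to the larger penalty
  W <- precision_to_partial(fits[[best]])
  W[abs(W) < 1e-10] <- 0
  dimnames(W) <- list(dataset$nodes$node_id, dataset$nodes$node_id)
  ut <- W[upper.tri(W)]
  structure(
    list(W = W, nodes = dataset$nodes, lambda = path[best], gamma = gamma,
         ebic = scores[best], n_edges = sum(ut != 0),
         n_positive = sum(ut > 0), possible_pairs = p * (p - 1) / 2,
         n = S$n, p = p, lambda_path = path, ebic_path = scores,
         method = method),
    class = "network_model"
  )
}

#' @export
print.network_model <- function(x, ...) {
  cat(sprintf("network_model: %d nodes, %d/%d nonzero edges (%d positive)\n",
              x$p, x$n_edges, x$possible_pairs, x$n_positive))
  if (!is.null(x$lambda)) {
    cat(sprintf("  lambda = %.4g (EBIC gamma = %.2g), n = %d\n",
                x$lambda, x$gamma, x$n))
  }
  invisible(x)
}

# Wrap a bare weight matrix (tests, cross-domain reconstruction) as a model.
as_network_model <- function(W, nodes, lambda = NULL, gamma = NULL,
                             n = NULL) {
  W <- as.matrix(W)
  dimnames(W) <- list(nodes$node_id, nodes$node_id)
  ut <- W[upper.tri(W)]
  p <- nrow(W)
  structure(
    list(W = W, nodes = nodes, n_edges = sum(ut != 0),
         n_positive = sum(ut > 0), possible_pairs = p * (p - 1) / 2,
         p = p, lambda = lambda, gamma = gamma, n = n),
    class = "network_model"
  )
}

#' Export a network as an edge list plus summary
#'
#' Writes the nonzero upper-triangle weights as a tab-delimited edge list
#' (`node_a`, `node_b`, `weight`, 10 significant digits) and a JSON summary
#' with node count, possible pairs, nonzero and positive edge counts and the
#' tuning parameters.
#'
#' @param model A `network_model`.
#' @param path Edge-list output path (TSV).
#' @param summary_path JSON summary path; defaults to the edge-list path
#'   with a `_summary.json` suffix.
#' @return Invisibly, a list with both paths.
#' @export
write_network <- function(model, path, summary_path = NULL) {
  summary_path <- summary_path %||%
    paste0(tools::file_path_sans_ext(path), "_summary.json")
  ids <- model$nodes$node_id
  ut <- which(upper.tri(model$W) & model$W != 0, arr.ind = TRUE)
  edges <- data.frame(
    node_a = ids[ut[, 1]], node_b = ids[ut[, 2]],
    weight = fmt_num(model$W[ut]),
    stringsAsFactors = FALSE
  )
  utils::write.table(edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  summary <- list(
    nodes = model$p,
    possible_pairs = model$possible_pairs,
    nonzero_edges = model$n_edges,
    positive_edges = model$n_positive,
    lambda = model$lambda %||% NA,
    gamma = model$gamma %||% NA
  )
  jsonlite::write_json(summary, summary_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(edges = path, summary = summary_path))
}

#' Read an edge list back into a network model
#'
#' @param path Edge list written by [write_network()].
#' @param nodes Node metadata defining order and domains.
#' @return A `network_model` (weight matrix only).
#' @export
read_network <- function(path, nodes) {
  edges <- read.csv(path, sep = "\t", stringsAsFactors = FALSE)
  p <- nrow(nodes)
  W <- matrix(0, p, p, dimnames = list(nodes$node_id, nodes$node_id))
  if (nrow(edges) > 0) {
    unknown <- setdiff(c(edges$node_a, edges$node_b), nodes$node_id)
    if (length(unknown) > 0) {
      stop("edge list names unknown node(s): ",
           paste(unique(unknown), collapse = ", "))
    }
    for (i in seq_len(nrow(edges))) {
      W[edges$node_a[i], edges$node_b[i]] <- edges$weight[i]
      W[edges$node_b[i], edges$node_a[i]] <- edges$weight[i]
    }
  }
  as_network_model(W, nodes)
}
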