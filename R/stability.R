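# Bootstrap accuracy and stability of network estimates: nonparametric
# edge-weight confidence intervals and case-dropping correlation-stability
# (CS) coefficients.

index_values <- function(model, index) {
  switch(index,
    strength = as.numeric(strength(model)),
    expected_influence = as.numeric(expected_influence(model)),
    closeness = as.numeric(closeness(model)),
    betweenness = as.numeric(betweenness(model)),
    bridge_strength = bridge_strength(model)$bridge_strength,
    edge = model$W[upper.tri(model$W)],
    stop("unknown stability index: ", index)
  )
}

#' Nonparametric bootstrap confidence intervals for edge weights
#'
#' Resamples subjects with replacement (full n), re-estimates the network on
#' every resample and summarizes each node pair's weight distribution with
#' quantile confidence bounds. A resample on which estimation fails is
#' redrawn (counted); more than 10% failures abort.
#'
#' @param dataset An [item_dataset()].
#' @param B Number of bootstrap resamples (default 1000; use fewer for quick
#'   checks).
#' @param gamma,... Passed to [estimate_network()].
#' @param level Confidence level (default 0.95).
#' @param seed RNG seed; identical seeds give identical tables.
#' @return A `data.frame` (class `edge_ci_table`) with one row per node
#'   pair: `node_a`, `node_b`, `observed`, `boot_mean`, `lower`, `upper`.
#'   Attributes: `B`, `level`, `n_redraws`, `seed`.
#' @export
bootstrap_edges <- function(dataset, B = 1000L, gamma = 0.5, level = 0.95,
                            seed = NULL, ...) {
  stopifnot(B >= 1)
  n <- n_subjects(dataset)
  full <- estimate_network(dataset, gamma = gamma, ...)
  ut <- upper.tri(full$W)
  boots <- matrix(NA_real_, nrow = B, ncol = sum(ut))
  n_redraws <- 0L
  with_seed(seed, {
    for (b in seq_len(B)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        fit <- tryCatch(
          estimate_network(subset_subjects(dataset, idx), gamma = gamma, ...),
          error = function(e) NULL
        )
        if (!is.null(fit)) break
        n_redraws <- n_redraws + 1L
        if (n_redraws > 0.1 * B) {
          stop("more than 10% of bootstrap resamples failed to estimate")
        }
      }
      boots[b, ] <- fit$W[ut]
    }
  })
  if (n_redraws > 0) {
    message(sprintf("bootstrap_edges: %d failed resample(s) redrawn",
                    n_redraws))
  }
  alpha <- (1 - level) / 2
  out <- upper_tri_pairs(full$nodes$node_id)
  out$observed <- full$W[ut]
  out$boot_mean <- colMeans(boots)
  out$lower <- apply(boots, 2, quantile, probs = alpha)
  out$upper <- apply(boots, 2, quantile, probs = 1 - alpha)
  structure(out, class = c("edge_ci_table", "data.frame"),
            B = B, level = level, n_redraws = n_redraws, seed = seed)
}

#' Case-dropping bootstrap of centrality and edge estimates
#'
#' Draws subsamples that retain a progressively smaller share of the
#' subjects (without replacement), re-estimates the network on each, and
#' records the correlation between the subsample index values and the
#' full-sample values. One network is estimated per subsample and every
#' requested index is read off it.
#'
#' @param dataset An [item_dataset()].
#' @param indices Character vector from `"strength"`, `"closeness"`,
#'   `"betweenness"`, `"bridge_strength"`, `"expected_influence"`, `"edge"`.
#' @param drop_proportions Ordered grid of drop fractions in (0, 1);
#'   default `seq(0.05, 0.75, by = 0.05)`. A proportion `q` retains
#'   `ceiling((1 - q) * n)` subjects; the largest drop must retain at least
#'   `p + 1` subjects.
#' @param B Subsamples per proportion (default 100 for desk-scale runs;
#'   1000 for reporting).
#' @param gamma,... Passed to [estimate_network()].
#' @param cor_threshold,prob_threshold CS thresholds (defaults 0.7 and
#'   0.95), see [cs_coefficient()].
#' @param seed RNG seed.
#' @return An object of class `stability_analysis`: a named list of
#'   `stability_result` objects (one per index), each with the correlation
#'   matrix (`B` x length(grid)), the CS coefficient, thresholds and the
#'   count of undefined (degenerate) correlations, plus shared metadata.
#' @export
case_dropping <- function(dataset,
                          indices = c("strength", "bridge_strength", "edge"),
                          drop_proportions = seq(0.05, 0.75, by = 0.05),
                          B = 100L, gamma = 0.5,
                          cor_threshold = 0.7, prob_threshold = 0.95,
                          seed = NULL, ...) {
  indices <- match.arg(indices,
                       c("strength", "closeness", "betweenness",
                         "bridge_strength", "expected_influence", "edge"),
                       several.ok = TRUE)
  if (any(diff(drop_proportions) <= 0) ||
      any(drop_proportions <= 0 | drop_proportions >= 1)) {
    stop("drop_proportions must be strictly increasing, inside (0, 1)")
  }
  n <- n_subjects(dataset)
  p <- ncol(dataset$values)
  retained <- ceiling((1 - drop_proportions) * n)
  if (min(retained) < p + 1) {
    stop(sprintf(paste0("largest drop proportion retains %d subjects but ",
                        "at least %d (p + 1) are needed"),
                 min(retained), p + 1))
  }
  full <- estimate_network(dataset, gamma = gamma, ...)
  full_vals <- lapply(setNames(indices, indices), index_values,
                      model = full)
  Q <- length(drop_proportions)
  cors <- lapply(setNames(indices, indices), function(i) {
    matrix(NA_real_, nrow = B, ncol = Q,
           dimnames = list(NULL, paste0("q", drop_proportions)))
  })
  n_undefined <- setNames(integer(length(indices)), indices)
  with_seed(seed, {
    for (qi in seq_len(Q)) {
      m <- retained[qi]
      for (b in seq_len(B)) {
        idx <- sample.int(n, m, replace = FALSE)
        fit <- tryCatch(
          estimate_network(subset_subjects(dataset, idx), gamma = gamma, ...),
          error = function(e) NULL
        )
        if (is.null(fit)) next
        for (ind in indices) {
          sub_vals <- index_values(fit, ind)
          if (sd(sub_vals) == 0 || sd(full_vals[[ind]]) == 0) {
            n_undefined[ind] <- n_undefined[ind] + 1L
          } else {
            cors[[ind]][b, qi] <- cor(sub_vals, full_vals[[ind]])
          }
        }
      }
    }
  })
  if (any(n_undefined > 0)) {
    message("case_dropping: undefined correlations excluded — ",
            paste(names(n_undefined)[n_undefined > 0],
                  n_undefined[n_undefined > 0],
                  sep = ": ", collapse = ", "))
  }
  results <- lapply(setNames(indices, indices), function(ind) {
    res <- structure(
      list(index = ind, drop_proportions = drop_proportions,
           correlations = cors[[ind]], cs = NA_real_,
           cor_threshold = cor_threshold, prob_threshold = prob_threshold,
           n_undefined = n_undefined[[ind]], B = B, seed = seed),
      class = "stability_result"
    )
    res$cs <- cs_coefficient(res)
    res
  })
  structure(results, class = "stability_analysis",
            B = B, seed = seed, gamma = gamma, n = n)
}

#' Correlation-stability (CS) coefficient
#'
#' The largest drop proportion `q` such that, at every proportion up to and
#' including `q`, at least `prob_threshold` of the subsample correlations
#' with the full-sample values are `>= cor_threshold`; 0 when even the
#' smallest proportion fails. Centrality estimates are conventionally called
#' interpretable at CS >= 0.25 and stable at CS > 0.5. The monotone
#' qualification over all smaller proportions prevents non-monotone flukes
#' from inflating the coefficient.
#'
#' @param result A `stability_result` from [case_dropping()].
#' @param cor_threshold,prob_threshold Override the thresholds stored in
#'   `result`.
#' @return The CS coefficient: an element of the drop grid, or 0.
#' @export
cs_coefficient <- function(result, cor_threshold = NULL,
                           prob_threshold = NULL) {
  stopifnot(inherits(result, "stability_result"))
  grid <- result$drop_proportions
  if (length(grid) == 0) stop("empty drop-proportion grid")
  cor_threshold <- cor_threshold %||% result$cor_threshold
  prob_threshold <- prob_threshold %||% result$prob_threshold
  cs <- 0
  for (qi in seq_along(grid)) {
    cc <- result$correlations[, qi]
    cc <- cc[!is.na(cc)]
    if (length(cc) == 0) break
    if (mean(cc >= cor_threshold) >= prob_threshold) {
      cs <- grid[qi]
    } else {
      break
    }
  }
  cs
}

#' @export
print.stability_analysis <- function(x, ...) {
  cat(sprintf("stability_analysis: B = %d per proportion, n = %d\n",
              attr(x, "B"), attr(x, "n")))
  for (res in x) {
    cat(sprintf("  CS(%s) = %.2f  (cor >= %.2f with prob >= %.2f)\n",
                res$index, res$cs, res$cor_threshold, res$prob_threshold))
  }
  invisible(x)
}

#' Write stability results to TSV (edge CIs) or JSON (CS summary)
#'
#' @param x An `edge_ci_table` or `stability_analysis`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_stability <- function(x, path) {
  if (inherits(x, "edge_ci_table")) {
    out <- as.data.frame(x)
    num <- vapply(out, is.numeric, TRUE)
    out[num] <- lapply(out[num], fmt_num)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else if (inherits(x, "stability_analysis")) {
    doc <- list(
      B = attr(x, "B"), n = attr(x, "n"),
      seed = attr(x, "seed") %||% NA, gamma = attr(x, "gamma"),
      indices = lapply(x, function(res) {
        list(index = res$index, cs = res$cs,
             cor_threshold = res$cor_threshold,
             prob_threshold = res$prob_threshold,
             drop_proportions = res$drop_proportions,
             median_correlation = as.numeric(apply(res$correlations, 2,
                                                   median, na.rm = TRUE)),
             n_undefined = res$n_undefined)
      })
    )
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    stop("x must be an edge_ci_table or stability_analysis")
  }
  invisible(path)
}
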