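#' Welch two-sample t-test from summary statistics
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom,
#' computed from group means, standard deviations and sizes:
#' `t = (mean_1 - mean_2) / sqrt(sd_1^2/n_1 + sd_2^2/n_2)`. The sign of `t`
#' follows `mean_1 - mean_2`.
#'
#' @param mean_1,mean_2 Group means.
#' @param sd_1,sd_2 Group standard deviations (non-negative; at least one
#'   positive unless the means differ).
#' @param n_1,n_2 Group sizes, each at least 2.
#' @return A list with `t`, `df` (Welch-Satterthwaite) and `p` (two-sided).
#' @examples
#' # scale total score, deficit (n=70) vs non-deficit (n=91) group
#' welch_t(44.93, 13.03, 70, 19.70, 9.85, 91)
#' @export
welch_t <- function(mean_1, sd_1, n_1, mean_2, sd_2, n_2) {
  if (n_1 < 2 || n_2 < 2) stop("each group needs n >= 2")
  if (sd_1 < 0 || sd_2 < 0) stop("standard deviations must be non-negative")
  if (sd_1 == 0 && sd_2 == 0) {
    if (mean_1 == mean_2) {
      stop("t is undefined: both groups have zero variance and equal means")
    }
    return(list(t = sign(mean_1 - mean_2) * Inf, df = NA_real_, p = 0))
  }
  v1 <- sd_1^2 / n_1
  v2 <- sd_2^2 / n_2
  se <- sqrt(v1 + v2)
  t <- (mean_1 - mean_2) / se
  df <- (v1 + v2)^2 / (v1^2 / (n_1 - 1) + v2^2 / (n_2 - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' Two-group comparisons over dataset variables
#'
#' Reproduces a clinical characteristics table from raw data: per-group mean
#' and standard deviation for each requested variable plus a derived
#' negative-symptom scale total (sum of B1-B13 when all 13 items are
#' present), with a Welch test per row. Group 1 is the first factor level of
#' the dataset's group label (alphabetical for character input, so `"DS"`
#' precedes `"NDS"`); `sign(t) = sign(mean_1 - mean_2)`.
#'
#' @param dataset An [item_dataset()] with a two-level group label.
#' @param variables Node ids to compare; defaults to every node.
#' @param totals Add the derived `BNSS_total` row when possible (default
#'   `TRUE`).
#' @return A `data.frame` with columns `variable`, `mean_1`, `disp_1`,
#'   `mean_2`, `disp_2`, `n_1`, `n_2`, `t`, `df`, `p`.
#' @export
compare_groups <- function(dataset, variables = NULL, totals = TRUE) {
  if (is.null(dataset$group)) {
    stop("dataset has no group labels; nothing to compare")
  }
  g <- dataset$group
  sizes <- table(g)
  if (any(sizes < 2)) {
    stop("each group needs at least 2 subjects; sizes: ",
         paste(names(sizes), sizes, sep = "=", collapse = ", "))
  }
  variables <- variables %||% dataset$nodes$node_id
  unknown <- setdiff(variables, dataset$nodes$node_id)
  if (length(unknown) > 0) {
    stop("unknown variable(s): ", paste(unknown, collapse = ", "))
  }
  cols <- dataset$values[, variables, drop = FALSE]
  items <- paste0("B", 1:13)
  if (totals && all(items %in% dataset$nodes$node_id)) {
    cols <- cbind(cols,
                  BNSS_total = rowSums(dataset$values[, items, drop = FALSE]))
  }
  lev <- levels(g)
  i1 <- g == lev[1]
  i2 <- g == lev[2]
  rows <- lapply(colnames(cols), function(v) {
    x1 <- cols[i1, v]
    x2 <- cols[i2, v]
    wt <- welch_t(mean(x1), sd(x1), length(x1), mean(x2), sd(x2), length(x2))
    data.frame(variable = v,
               mean_1 = mean(x1), disp_1 = sd(x1),
               mean_2 = mean(x2), disp_2 = sd(x2),
               n_1 = length(x1), n_2 = length(x2),
               t = wt$t, df = wt$df, p = wt$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "groups") <- lev
  out
}

#' Write a group-comparison table as TSV
#'
#' @param comparison Output of [compare_groups()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_group_table <- function(comparison, path) {
  out <- comparison
  num <- vapply(out, is.numeric, TRUE)
  out[num] <- lapply(out[num], fmt_num)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
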