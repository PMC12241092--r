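#' Node metadata table
#'
#' Builds and validates the node-metadata table that assigns every network
#' variable to a clinical domain. Domain membership is declared here, never
#' inferred from column names, because it drives the bridge-centrality
#' analysis.
#'
#' @param node_id Character vector of unique short identifiers
#'   (e.g. `"B1"`..`"B13"`, `"Y1"`..`"Y4"`, `"SSPI"`).
#' @param domain Character vector assigning each node to a community such as
#'   `"negative_symptoms"`, `"cognition"` or `"social_function"`. Any label
#'   set is allowed.
#' @param label Optional display strings; defaults to `node_id`.
#' @return A `data.frame` with columns `node_id`, `label`, `domain`.
#' @export
node_metadata <- function(node_id, domain, label = node_id) {
  node_id <- as.character(node_id)
  if (anyDuplicated(node_id)) {
    stop("node_id values must be unique; duplicated: ",
         paste(unique(node_id[duplicated(node_id)]), collapse = ", "))
  }
  if (length(domain) != length(node_id)) {
    stop("every node needs exactly one domain label")
  }
  if (anyNA(domain) || any(!nzchar(domain))) {
    stop("missing domain label for node(s): ",
         paste(node_id[is.na(domain) | !nzchar(domain)], collapse = ", "))
  }
  data.frame(
    node_id = node_id,
    label = as.character(label),
    domain = as.character(domain),
    stringsAsFactors = FALSE
  )
}

#' Subjects-by-variables dataset
#'
#' The universal input of the pipeline: a complete numeric score matrix with
#' aligned node metadata and an optional two-group label per subject.
#' Validation is strict — any missing or non-numeric value is an error that
#' names its coordinates, because downstream correlation and lasso stages
#' assume complete data.
#'
#' @param values Numeric matrix or data frame, subjects in rows, one column
#'   per node (columns in node order).
#' @param nodes Node metadata from [node_metadata()], aligned to columns.
#' @param subject_ids Optional subject identifiers (default `S1`, `S2`, ...).
#' @param group Optional per-subject group label with exactly two levels
#'   (e.g. `"DS"` / `"NDS"`); each present group needs at least 3 subjects.
#' @return An object of class `item_dataset` with elements `values`
#'   (numeric matrix with node columns), `subject_ids`, `group` (factor or
#'   `NULL`) and `nodes`.
#' @export
item_dataset <- function(values, nodes, subject_ids = NULL, group = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) {
    bad <- which(is.na(suppressWarnings(
      matrix(as.numeric(values), nrow(values))
    )) & !is.na(values), arr.ind = TRUE)
    if (nrow(bad) > 0) {
      stop(sprintf("non-numeric cell at row %d, column '%s'",
                   bad[1, 1], colnames(values)[bad[1, 2]] %||% bad[1, 2]))
    }
    storage.mode(values) <- "double"
  }
  if (ncol(values) != nrow(nodes)) {
    stop(sprintf("dataset has %d columns but metadata defines %d nodes",
                 ncol(values), nrow(nodes)))
  }
  if (anyNA(values)) {
    bad <- which(is.na(values), arr.ind = TRUE)
    coords <- apply(bad, 1, function(rc) {
      sprintf("(row %d, column '%s')", rc[1], nodes$node_id[rc[2]])
    })
    stop("missing values at: ", paste(coords, collapse = ", "))
  }
  colnames(values) <- nodes$node_id
  if (is.null(subject_ids)) {
    subject_ids <- paste0("S", seq_len(nrow(values)))
  }
  if (length(subject_ids) != nrow(values)) {
    stop("subject_ids length must equal the number of rows")
  }
  rownames(values) <- NULL
  if (!is.null(group)) {
    group <- as.factor(as.character(group))
    if (length(group) != nrow(values)) {
      stop("group length must equal the number of rows")
    }
    if (nlevels(group) != 2) {
      stop("group must have exactly two levels, got: ",
           paste(levels(group), collapse = ", "))
    }
    sizes <- table(group)
    if (any(sizes < 3)) {
      stop("each group needs at least 3 subjects; sizes: ",
           paste(names(sizes), sizes, sep = "=", collapse = ", "))
    }
  }
  structure(
    list(values = values, subject_ids = as.character(subject_ids),
         group = group, nodes = nodes),
    class = "item_dataset"
  )
}

#' @export
print.item_dataset <- function(x, ...) {
  cat(sprintf("item_dataset: %d subjects x %d nodes\n",
              nrow(x$values), ncol(x$values)))
  cat("  domains:",
      paste(sprintf("%s (%d)", names(table(x$nodes$domain)),
                    table(x$nodes$domain)), collapse = ", "), "\n")
  if (!is.null(x$group)) {
    cat("  groups: ",
        paste(sprintf("%s (n=%d)", levels(x$group), table(x$group)),
              collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

n_subjects <- function(dataset) nrow(dataset$values)

# Row-subset a dataset, keeping labels aligned. Bootstrap resamples may
# legitimately leave a group with < 3 subjects, so validation is bypassed.
subset_subjects <- function(dataset, idx) {
  out <- dataset
  out$values <- dataset$values[idx, , drop = FALSE]
  out$subject_ids <- dataset$subject_ids[idx]
  if (!is.null(dataset$group)) out$group <- dataset$group[idx]
  out
}

#' Read a dataset from a values file and a metadata document
#'
#' The values file is comma-separated with a mandatory header row naming the
#' columns; the metadata document (YAML) lists the nodes in network order and
#' optionally names a group and a subject-id column. Columns are reordered to
#' follow the metadata document, never silently.
#'
#' @param path_values Path to the CSV score table.
#' @param path_metadata Path to the YAML metadata document with a `nodes`
#'   list (`id`, optional `label`, `domain`) and optional `group_column` /
#'   `id_column` entries.
#' @return An [item_dataset()].
#' @export
read_dataset <- function(path_values, path_metadata) {
  if (!file.exists(path_values)) {
    stop("values file not found: ", path_values)
  }
  if (!file.exists(path_metadata)) {
    stop("metadata document not found: ", path_metadata)
  }
  meta <- yaml::read_yaml(path_metadata)
  if (is.null(meta$nodes)) {
    stop("metadata document has no 'nodes' entry: ", path_metadata)
  }
  nodes <- node_metadata(
    node_id = vapply(meta$nodes, function(n) as.character(n$id), ""),
    domain = vapply(meta$nodes, function(n) as.character(n$domain), ""),
    label = vapply(meta$nodes, function(n)
      as.character(n$label %||% n$id), "")
  )
  raw <- read.csv(path_values, check.names = FALSE, colClasses = "character",
                  stringsAsFactors = FALSE)
  missing_cols <- setdiff(nodes$node_id, names(raw))
  if (length(missing_cols) > 0) {
    stop("values file lacks column(s) named in metadata: ",
         paste(missing_cols, collapse = ", "))
  }
  group <- NULL
  if (!is.null(meta$group_column)) {
    if (!meta$group_column %in% names(raw)) {
      stop("group column '", meta$group_column, "' not present in ",
           path_values)
    }
    group <- raw[[meta$group_column]]
  }
  subject_ids <- NULL
  if (!is.null(meta$id_column) && meta$id_column %in% names(raw)) {
    subject_ids <- raw[[meta$id_column]]
  }
  cells <- as.matrix(raw[, nodes$node_id, drop = FALSE])
  blank <- which(is.na(cells) | !nzchar(trimws(cells)), arr.ind = TRUE)
  if (nrow(blank) > 0) {
    coords <- apply(blank, 1, function(rc) {
      sprintf("(row %d, column '%s')", rc[1], nodes$node_id[rc[2]])
    })
    stop("missing values at: ", paste(coords, collapse = ", "))
  }
  num <- suppressWarnings(matrix(as.numeric(cells), nrow(cells)))
  bad <- which(is.na(num), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("non-numeric cell '%s' at row %d, column '%s'",
                 cells[bad[1, 1], bad[1, 2]], bad[1, 1],
                 nodes$node_id[bad[1, 2]]))
  }
  colnames(num) <- nodes$node_id
  item_dataset(num, nodes, subject_ids = subject_ids, group = group)
}

#' Write a dataset to a values file and a metadata document
#'
#' Inverse of [read_dataset()]: the pair round-trips values, node order,
#' domains and group labels exactly.
#'
#' @param dataset An [item_dataset()].
#' @param path_values Output CSV path.
#' @param path_metadata Output YAML path.
#' @return Invisibly, the two paths.
#' @export
write_dataset <- function(dataset, path_values, path_metadata) {
  df <- data.frame(subject_id = dataset$subject_ids,
                   stringsAsFactors = FALSE)
  if (!is.null(dataset$group)) df$group <- as.character(dataset$group)
  # %.17g round-trips IEEE doubles exactly
  vals <- as.data.frame(apply(dataset$values, 2, sprintf, fmt = "%.17g"),
                        stringsAsFactors = FALSE)
  df <- cbind(df, vals)
  write.csv(df, path_values, row.names = FALSE, quote = FALSE)
  meta <- list(
    id_column = "subject_id",
    nodes = lapply(seq_len(nrow(dataset$nodes)), function(i) {
      list(id = dataset$nodes$node_id[i],
           label = dataset$nodes$label[i],
           domain = dataset$nodes$domain[i])
    })
  )
  if (!is.null(dataset$group)) meta$group_column <- "group"
  yaml::write_yaml(meta, path_metadata)
  invisible(c(values = path_values, metadata = path_metadata))
}
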