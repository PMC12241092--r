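#' Pipeline configuration
#'
#' Assembles and validates the configuration consumed by [run_pipeline()].
#' Exactly one input source is used: file paths (`values`, `metadata`) or a
#' synthetic specification.
#'
#' @param values,metadata Paths to a score CSV and its YAML metadata (see
#'   [read_dataset()]); `NULL` when simulating.
#' @param synthetic_spec A [synthetic_spec()], a path readable by
#'   [read_spec()], or `"default"` for [default_spec()]; `NULL` when reading
#'   files.
#' @param gamma EBIC hyperparameter (default 0.5).
#' @param n_boots Edge-weight bootstrap resamples (default 1000).
#' @param case_drop_B Subsamples per drop proportion (default 100).
#' @param drop_proportions Case-dropping grid.
#' @param indices Stability indices, see [case_dropping()].
#' @param seed Top-level seed; every stage derives its own seed from it.
#' @param out_dir Output directory (created if needed).
#' @param stages Subset of `c("simulate", "compare", "network",
#'   "centrality", "bridge", "stability")` or `"all"`.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(values = NULL, metadata = NULL,
                            synthetic_spec = NULL, gamma = 0.5,
                            n_boots = 1000L, case_drop_B = 100L,
                            drop_proportions = seq(0.05, 0.75, by = 0.05),
                            indices = c("strength", "bridge_strength",
                                        "edge"),
                            seed = 1L, out_dir = ".", stages = "all") {
  if (is.null(synthetic_spec) && (is.null(values) || is.null(metadata))) {
    stop("either file input (values + metadata) or a synthetic spec is required")
  }
  all_stages <- c("simulate", "compare", "network", "centrality", "bridge",
                  "stability")
  if (identical(stages, "all")) stages <- all_stages
  unknown <- setdiff(stages, all_stages)
  if (length(unknown) > 0) {
    stop("unknown stage(s): ", paste(unknown, collapse = ", "))
  }
  structure(
    list(values = values, metadata = metadata,
         synthetic_spec = synthetic_spec, gamma = gamma,
         n_boots = as.integer(n_boots), case_drop_B = as.integer(case_drop_B),
         drop_proportions = drop_proportions, indices = indices,
         seed = as.integer(seed), out_dir = out_dir, stages = stages),
    class = "pipeline_config"
  )
}

pipeline_stage <- function(name, code) {
  message(sprintf("[%s] running", name))
  tryCatch(force(code), error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full network-analysis pipeline
#'
#' Executes, in order: data acquisition (read or simulate), two-group
#' comparison, network estimation, centrality, bridge analysis and
#' stability bootstraps, writing every table to the output directory. All
#' randomness is derived from the single configured seed, so a rerun with
#' the same configuration is byte-identical. When the dataset carries no
#' group labels, the comparison stage is skipped with a logged notice and
#' the network stages still run.
#'
#' @param config A [pipeline_config()] or a YAML file path holding one.
#' @return Invisibly, a list with the dataset, network model, centrality
#'   and bridge tables, stability results and all output paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    config <- do.call(pipeline_config, yaml::read_yaml(config))
  }
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  paths <- list()
  results <- list()

  if (!is.null(config$synthetic_spec)) {
    dataset <- pipeline_stage("simulate", {
      spec <- config$synthetic_spec
      if (is.character(spec)) {
        spec <- if (identical(spec, "default")) {
          default_spec()
        } else {
          read_spec(spec)
        }
      }
      ds <- sample_dataset(spec, seed = derive_seed(config$seed, 1L))
      if ("simulate" %in% config$stages) {
        paths$dataset <- out("dataset.csv")
        write_dataset(ds, out("dataset.csv"), out("dataset_metadata.yaml"))
      }
      ds
    })
  } else {
    dataset <- pipeline_stage("read", {
      read_dataset(config$values, config$metadata)
    })
  }
  results$dataset <- dataset
  message(sprintf("[data] %d subjects, %d nodes", nrow(dataset$values),
                  ncol(dataset$values)))

  if ("compare" %in% config$stages) {
    if (is.null(dataset$group)) {
      message("[compare] skipped: dataset has no group labels")
    } else {
      results$comparison <- pipeline_stage("compare", {
        cmp <- compare_groups(dataset)
        paths$comparison <- out("group_comparison.tsv")
        write_group_table(cmp, out("group_comparison.tsv"))
        cmp
      })
    }
  }

  need_model <- any(c("network", "centrality", "bridge", "stability") %in%
                      config$stages)
  if (need_model) {
    results$model <- pipeline_stage("network", {
      model <- estimate_network(dataset, gamma = config$gamma)
      message(sprintf(
        "[network] lambda = %.4g, %d/%d edges (%d positive)",
        model$lambda, model$n_edges, model$possible_pairs, model$n_positive))
      if ("network" %in% config$stages) {
        paths$network <- out("network_edges.tsv")
        write_network(model, out("network_edges.tsv"),
                      out("network_summary.json"))
      }
      model
    })
  }

  if ("centrality" %in% config$stages) {
    results$centrality <- pipeline_stage("centrality", {
      ct <- centrality_table(results$model, standardize = TRUE)
      paths$centrality <- out("centrality.tsv")
      write_node_table(ct, out("centrality.tsv"))
      ct
    })
  }

  if ("bridge" %in% config$stages) {
    results$bridge <- pipeline_stage("bridge", {
      bt <- bridge_strength(results$model)
      paths$bridge <- out("bridge.tsv")
      write_node_table(bt, out("bridge.tsv"))
      bridge_net <- cross_domain_network(results$model)
      paths$bridge_network <- out("bridge_network_edges.tsv")
      write_network(bridge_net, out("bridge_network_edges.tsv"),
                    out("bridge_network_summary.json"))
      bt
    })
  }

  if ("stability" %in% config$stages) {
    results$edge_ci <- pipeline_stage("stability", {
      ci <- bootstrap_edges(dataset, B = config$n_boots,
                            gamma = config$gamma,
                            seed = derive_seed(config$seed, 2L))
      paths$edge_ci <- out("edge_ci.tsv")
      write_stability(ci, out("edge_ci.tsv"))
      ci
    })
    results$stability <- pipeline_stage("stability", {
      st <- case_dropping(dataset, indices = config$indices,
                          drop_proportions = config$drop_proportions,
                          B = config$case_drop_B, gamma = config$gamma,
                          seed = derive_seed(config$seed, 3L))
      for (res in st) {
        message(sprintf("[stability] CS(%s) = %.2f", res$index, res$cs))
      }
      paths$stability <- out("stability.json")
      write_stability(st, out("stability.json"))
      st
    })
  }

  echo <- list(
    gamma = config$gamma, n_boots = config$n_boots,
    case_drop_B = config$case_drop_B,
    drop_proportions = config$drop_proportions,
    indices = config$indices, seed = config$seed, stages = config$stages
  )
  jsonlite::write_json(echo, out("config_echo.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  results$paths <- paths
  invisible(results)
}
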