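# Internal helpers shared across modules.

# Derive a stage seed from a top-level seed. Keeps results reproducible per
# stage while every source of randomness still flows from one integer.
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 2147480009L + 104729L * (as.integer(offset) %% 1000L)) %%
    2147480009L
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

upper_tri_pairs <- function(ids) {
  p <- length(ids)
  idx <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
  data.frame(
    node_a = ids[idx[, "row"]],
    node_b = ids[idx[, "col"]],
    stringsAsFactors = FALSE
  )
}

fmt_num <- function(x, digits = 10) {
  formatC(x, format = "g", digits = digits)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
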