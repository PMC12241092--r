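fake_stability <- function(correlations, grid, cor_threshold = 0.7,
                           prob_threshold = 0.95) {
  structure(
    list(index = "strength", drop_proportions = grid,
         correlations = correlations, cs = NA_real_,
         cor_threshold = cor_threshold, prob_threshold = prob_threshold,
         n_undefined = 0L, B = nrow(correlations), seed = NULL),
    class = "stability_result"
  )
}

test_that("cs_coefficient walks the grid monotonically", {
  grid <- seq(0.05, 0.75, by = 0.05)
  perfect <- fake_stability(matrix(1, 40, length(grid)), grid)
  expect_equal(cs_coefficient(perfect), 0.75)

  # failure at the smallest proportion: cs = 0
  bad <- matrix(1, 40, length(grid))
  bad[1:3, 1] <- 0.5  # > 5% of samples below the correlation threshold
  expect_equal(cs_coefficient(fake_stability(bad, grid)), 0)

  # a later dip gates everything beyond it, even if larger q recover
  dip <- matrix(1, 40, length(grid))
  dip[1:3, 4] <- 0.5
  expect_equal(cs_coefficient(fake_stability(dip, grid)), grid[3])

  expect_error(cs_coefficient(fake_stability(matrix(1, 5, 0), numeric(0))),
               "empty")
})

test_that("relaxing the correlation threshold never lowers cs", {
  set.seed(12)
  grid <- seq(0.1, 0.7, by = 0.1)
  for (rep in 1:20) {
    cors <- matrix(runif(30 * length(grid), 0.3, 1), 30)
    res <- fake_stability(cors, grid)
    cs_vals <- vapply(c(0.9, 0.7, 0.5, 0.3), function(th) {
      cs_coefficient(res, cor_threshold = th)
    }, numeric(1))
    expect_true(all(diff(cs_vals) >= 0))
  }
})

test_that("bootstrap edge CIs degenerate correctly at B = 1 and are deterministic", {
  ds <- sample_dataset(small_spec(n1 = 100L, n2 = 100L), seed = 2)
  ci1 <- bootstrap_edges(ds, B = 1, seed = 7)
  expect_equal(ci1$lower, ci1$upper)
  expect_equal(ci1$lower, ci1$boot_mean)

  ci_a <- bootstrap_edges(ds, B = 20, seed = 5)
  ci_b <- bootstrap_edges(ds, B = 20, seed = 5)
  expect_identical(ci_a, ci_b)
  ci_c <- bootstrap_edges(ds, B = 20, seed = 6)
  expect_false(identical(ci_a$lower, ci_c$lower))
})

test_that("a strong true edge gets a CI excluding zero; duplication narrows CIs", {
  spec <- small_spec(edge = 0.5, n1 = 1000L, n2 = 1000L)
  ds <- sample_dataset(spec, discretize = FALSE, seed = 3)
  ci <- bootstrap_edges(ds, B = 200, seed = 31)
  row <- ci[ci$node_a == "N1" & ci$node_b == "N2", ]
  expect_gt(row$lower, 0)

  dup <- symptomnet:::subset_subjects(ds, rep(seq_len(2000), 2))
  ci_dup <- bootstrap_edges(dup, B = 200, seed = 31)
  row_dup <- ci_dup[ci_dup$node_a == "N1" & ci_dup$node_b == "N2", ]
  expect_lt(row_dup$upper - row_dup$lower, row$upper - row$lower)
})

test_that("edge-weight CIs track a known truth up to shrinkage toward zero", {
  # The lasso penalty biases edge weights toward zero, so the bootstrap
  # quantile interval may sit entirely below a strong true weight; it must
  # not sit above it, and it must separate the edge from zero.
  spec <- small_spec(edge = 0.5, n1 = 125L, n2 = 125L)
  ok <- 0L
  excludes_zero <- 0L
  for (rep in 1:200) {
    ds <- sample_dataset(spec, discretize = FALSE, seed = 1000 + rep)
    ci <- bootstrap_edges(ds, B = 100, seed = rep)
    row <- ci[ci$node_a == "N1" & ci$node_b == "N2", ]
    if (row$lower <= 0.5) ok <- ok + 1L  # covers, or biased downward only
    if (row$lower > 0) excludes_zero <- excludes_zero + 1L
  }
  expect_gte(ok / 200, 0.85)
  expect_gte(excludes_zero / 200, 0.85)
})

test_that("case_dropping validates its grid and sample sizes", {
  ds <- sample_dataset(default_spec(), seed = 4)
  expect_error(
    case_dropping(ds, drop_proportions = c(0.3, 0.2), B = 2),
    "strictly increasing"
  )
  expect_error(
    case_dropping(ds, drop_proportions = c(0.5, 0.95), B = 2),
    "p \\+ 1"
  )
})

test_that("case_dropping is deterministic and correlations stay in [-1, 1]", {
  ds <- sample_dataset(default_spec(), seed = 4)
  st1 <- case_dropping(ds, indices = c("strength", "edge"),
                       drop_proportions = c(0.1, 0.3, 0.5), B = 8, seed = 9)
  st2 <- case_dropping(ds, indices = c("strength", "edge"),
                       drop_proportions = c(0.1, 0.3, 0.5), B = 8, seed = 9)
  expect_identical(st1$strength$correlations, st2$strength$correlations)
  expect_identical(st1$edge$cs, st2$edge$cs)
  cc <- st1$strength$correlations
  expect_true(all(abs(cc[!is.na(cc)]) <= 1 + 1e-12))
  expect_true(st1$strength$cs %in% c(0, c(0.1, 0.3, 0.5)))
})

test_that("degenerate full-sample indices are excluded as undefined", {
  # independent columns: the selected network is empty, strength constant 0
  set.seed(44)
  nodes <- node_metadata(paste0("V", 1:6), rep(c("d1", "d2"), 3))
  ds <- item_dataset(matrix(rnorm(400 * 6), 400, 6), nodes)
  expect_message(
    st <- case_dropping(ds, indices = "strength",
                        drop_proportions = c(0.1, 0.2), B = 5, seed = 2),
    "undefined"
  )
  expect_equal(st$strength$cs, 0)
  expect_gt(st$strength$n_undefined, 0)
})

test_that("with abundant data strength stability reaches the top of the grid", {
  spec <- null_shift_spec(900L, 900L, seed = 23L)
  ds <- sample_dataset(spec, discretize = FALSE, seed = 23)
  st <- case_dropping(ds, indices = "strength",
                      drop_proportions = seq(0.15, 0.75, by = 0.15),
                      B = 10, seed = 24)
  expect_equal(st$strength$cs, 0.75)
})

test_that("stability writers produce readable TSV and JSON", {
  ds <- sample_dataset(default_spec(), seed = 5)
  ci <- bootstrap_edges(ds, B = 3, seed = 1)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_stability(ci, path)
  tab <- read.delim(path)
  expect_equal(nrow(tab), 153)
  expect_true(all(tab$lower <= tab$upper + 1e-9))

  st <- case_dropping(ds, indices = "strength",
                      drop_proportions = c(0.1, 0.3), B = 3, seed = 1)
  jpath <- withr::local_tempfile(fileext = ".json")
  write_stability(st, jpath)
  doc <- jsonlite::read_json(jpath)
  expect_equal(doc$B, 3)
  expect_equal(doc$indices[[1]]$index, "strength")
  expect_true(doc$indices[[1]]$cs %in% c(0, 0.1, 0.3))
})
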