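test_that("Welch and Student statistics match closed forms and t.test", {
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  w <- welch_t(a, b)
  expect_equal(w$t_stat, -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(w$df, 4, tolerance = 1e-12)
  expect_equal(w$effect, -3, tolerance = 1e-12)  # -3 / sqrt((1+1)/2)
  ref <- t.test(a, b)  # independent reference routine
  expect_equal(w$t_stat, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(w$df, unname(ref$parameter), tolerance = 1e-12)

  s <- student_t(c(1, 2, 3, 7), c(2, 4, 9, 11))
  ref_s <- t.test(c(1, 2, 3, 7), c(2, 4, 9, 11), var.equal = TRUE)
  expect_equal(s$t_stat, unname(ref_s$statistic), tolerance = 1e-12)
  expect_identical(s$df, 6)

  same <- welch_t(c(2, 3, 4), c(2, 3, 4))
  expect_identical(same$t_stat, 0)
  expect_identical(same$effect, 0)
  # equal variances: Student and Welch coincide
  x <- c(1, 2, 3, 4); y <- c(2, 3, 4, 5)
  expect_equal(welch_t(x, y)$t_stat, student_t(x, y)$t_stat,
               tolerance = 1e-12)
  expect_equal(welch_t(x, y)$df, student_t(x, y)$df, tolerance = 1e-12)
})

test_that("degenerate zero-variance comparisons are guarded and flagged", {
  w <- welch_t(c(5, 5, 5), c(2, 2, 2))
  expect_true(w$degenerate)
  expect_identical(w$t_stat, 1e6)
  expect_identical(welch_t(c(2, 2), c(5, 5))$t_stat, -1e6)
  expect_error(welch_t(1, c(1, 2)), ">= 2")
})

test_that("effect sizes are translation invariant and scale equivariant", {
  set.seed(3)
  a <- rnorm(20, 4); b <- rnorm(25, 2, 2)
  e0 <- welch_t(a, b)$effect
  expect_equal(welch_t(a + 7, b + 7)$effect, e0, tolerance = 1e-12)
  expect_equal(welch_t(3 * a, 3 * b)$effect, e0, tolerance = 1e-12)
})

test_that("bootstrap aggregation averages replicate percentiles", {
  expect_identical(aggregate_effect(4.2), 4.2)
  expect_equal(aggregate_effect(rep(2.5, 6), reps = 50, seed = 1), 2.5,
               tolerance = 1e-12)
  # against an independent Monte-Carlo estimate of the same expectation
  effects <- 0:9
  got <- aggregate_effect(effects, percentile = 10, reps = 4000, seed = 7)
  set.seed(1234)
  oracle <- mean(replicate(4000, {
    quantile(sample(effects, 10, replace = TRUE), 0.1, names = FALSE)
  }))
  expect_equal(got, oracle, tolerance = 0.05)
  expect_error(aggregate_effect(numeric()), "empty")
  # deterministic under a fixed seed
  expect_identical(aggregate_effect(effects, reps = 100, seed = 5),
                   aggregate_effect(effects, reps = 100, seed = 5))
})

markers_fixture <- function() {
  corpus <- cached_corpus("mk", small_synth_config(seed = 31))
  prep <- run_preprocess(corpus$datasets)
  list(corpus = corpus, pooled = pool_corpus(prep), prep = prep)
}

test_that("two-type tissues rank by the single-comparison effect", {
  set.seed(8)
  n <- 40
  vals <- cbind(c(rnorm(n, 6, .5), rnorm(n, 4, .5)),
                c(rnorm(n, 4, .5), rnorm(n, 6, .5)),
                rnorm(2 * n, 5, .5))
  cells <- make_cells(2 * n, cell_type = rep(c("CL:0000236", "CL:0000084"),
                                             each = n))
  m <- Matrix::Matrix(vals, sparse = TRUE)
  colnames(m) <- c("GA", "GB", "GC")
  mk <- compute_markers(m, cells, "UBERON:0002048", "CL:0000236", seed = 2)
  expect_identical(mk$gene[1], "GA")
  # aggregated effect equals the raw single-comparison effect
  direct <- welch_t(vals[cells$cell_type == "CL:0000236", 1],
                    vals[cells$cell_type == "CL:0000084", 1])$effect
  expect_equal(mk$effect[mk$gene == "GA"], direct, tolerance = 1e-12)
  # k caps at the number of scored genes
  expect_lte(nrow(mk), 3)
  # invariant under permutation of cell order
  perm <- sample(2 * n)
  mk2 <- compute_markers(m[perm, ], cells[perm, ], "UBERON:0002048",
                         "CL:0000236", seed = 2)
  expect_equal(mk2, mk, tolerance = 1e-12)
})

test_that("planted markers are recovered in the top 25 by both variants", {
  fx <- markers_fixture()
  truth <- fx$corpus$truth$markers
  for (method in c("welch", "student")) {
    mk <- markers_all(fx$prep, seed = 9, method = method)
    rec <- vapply(split(truth, truth$cell_type), function(tt) {
      pred <- mk$gene[mk$tissue == tt$tissue[1] &
                        mk$cell_type == tt$cell_type[1]]
      all(tt$gene %in% pred)
    }, logical(1))
    expect_true(all(rec))
  }
})

test_that("marker tables are seed-deterministic with small seed sensitivity", {
  fx <- markers_fixture()
  m1 <- compute_markers(fx$pooled$normalized, fx$pooled$cells,
                        "UBERON:0002048", "CL:0000236", seed = 4)
  m2 <- compute_markers(fx$pooled$normalized, fx$pooled$cells,
                        "UBERON:0002048", "CL:0000236", seed = 4)
  expect_identical(m1, m2)
  m3 <- compute_markers(fx$pooled$normalized, fx$pooled$cells,
                        "UBERON:0002048", "CL:0000236", seed = 5)
  shared <- intersect(m1$gene, m3$gene)
  expect_gte(length(shared), 20)  # rankings agree up to Monte-Carlo noise
  delta <- abs(m1$effect[match(shared, m1$gene)] -
                 m3$effect[match(shared, m3$gene)])
  expect_lt(max(delta), 0.2)
})

test_that("a singleton tissue yields an empty marker table with a warning", {
  cells <- make_cells(6)
  m <- Matrix::Matrix(matrix(rnorm(12, 5), 6, 2), sparse = TRUE)
  colnames(m) <- c("GA", "GB")
  expect_warning(mk <- compute_markers(m, cells, "UBERON:0002048"),
                 "fewer than 2")
  expect_identical(nrow(mk), 0L)
})
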