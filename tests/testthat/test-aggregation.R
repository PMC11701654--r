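# a tiny "already normalized and masked" stratum: values > 3 are present,
# 0 encodes missing/masked
tiny_prep <- function(values, cells) {
  m <- Matrix::Matrix(values, sparse = TRUE)
  colnames(m) <- sprintf("G%02d", seq_len(ncol(m)))
  rownames(m) <- rownames(cells)
  list(normalized = m, cells = cells)
}

test_that("cube keys hold non-zero means with full cell-count denominators", {
  cells <- make_cells(3)
  prep <- tiny_prep(cbind(c(0, 3.5, 4.5)), cells)
  cube <- build_cube(prep)
  expect_identical(nrow(cube), 1L)
  expect_equal(cube$mean_nonzero, 4.0)
  expect_identical(cube$n_expressing, 2L)
  expect_identical(cube$n_cells, 3L)

  # a gene with no present value anywhere is absent from the cube
  prep2 <- tiny_prep(cbind(c(0, 3.5, 4.5), c(0, 0, 0)), cells)
  expect_false("G02" %in% build_cube(prep2)$gene)

  expect_error(build_cube(prep, group_by = "flavour"), "unknown facet")
})

test_that("facet stratification merges back to the unstratified cube", {
  corpus <- cached_corpus("plain", small_synth_config(seed = 5))
  prep <- run_preprocess(corpus$datasets)
  plain <- build_cube(prep)
  by_sex <- build_cube(prep, group_by = "sex")
  expect_true(all(by_sex$n_expressing <= by_sex$n_cells))
  expect_true(all(by_sex$n_expressing >= 1))
  # cell-weighted merge of the sex strata reproduces the plain cube
  by_sex$sum <- by_sex$mean_nonzero * by_sex$n_expressing
  merged <- stats::aggregate(cbind(sum, n_expressing, n_cells) ~
                               tissue + cell_type + gene,
                             data = as.data.frame(by_sex), FUN = sum)
  merged <- merged[order(merged$tissue, merged$cell_type, merged$gene), ]
  plain_df <- as.data.frame(plain)
  plain_df <- plain_df[order(plain_df$tissue, plain_df$cell_type,
                             plain_df$gene), ]
  expect_identical(merged$gene, plain_df$gene)
  expect_equal(merged$sum / merged$n_expressing, plain_df$mean_nonzero,
               tolerance = 1e-12)
  expect_identical(as.integer(merged$n_expressing),
                   plain_df$n_expressing)
  # n_cells reconstructs only where the gene is expressed in every sex
  # stratum (absent strata contribute no denominator row)
  n_strata <- stats::aggregate(sum ~ tissue + cell_type + gene,
                               data = as.data.frame(by_sex),
                               FUN = length)
  n_strata <- n_strata[order(n_strata$tissue, n_strata$cell_type,
                             n_strata$gene), ]
  full <- n_strata$sum == length(unique(by_sex$sex))
  expect_identical(as.integer(merged$n_cells[full]),
                   plain_df$n_cells[full])
})

test_that("per-dataset cubes merge exactly to the concatenated-corpus cube", {
  corpus <- cached_corpus("plain", small_synth_config(seed = 5))
  prep <- run_preprocess(corpus$datasets)
  split_cube <- build_cube(prep)
  pooled <- pool_corpus(prep)
  merged_cube <- build_cube(list(list(normalized = pooled$normalized,
                                      cells = pooled$cells)))
  expect_equal(as.data.frame(split_cube), as.data.frame(merged_cube),
               tolerance = 1e-12)
})

test_that("genes absent from a dataset are missing, not zero", {
  cells_a <- make_cells(2)
  cells_b <- make_cells(2)
  rownames(cells_b) <- c("BCX01", "BCX02")
  a <- tiny_prep(cbind(c(4, 6), c(5, 0)), cells_a)    # genes G01, G02
  b <- tiny_prep(cbind(c(8, 10)), cells_b)            # gene G01 only
  cube <- build_cube(list(a, b))
  g1 <- cube[cube$gene == "G01", ]
  g2 <- cube[cube$gene == "G02", ]
  expect_equal(g1$mean_nonzero, mean(c(4, 6, 8, 10)))
  expect_identical(g1$n_cells, 4L)
  # G02 was never measured in dataset b: denominator excludes b's cells
  expect_identical(g2$n_cells, 2L)
  expect_identical(g2$n_expressing, 1L)
})

test_that("cube roll-up recomputes means from rolled sums", {
  graph <- cc_ontology(data.frame(child = c("CL:B", "CL:PLASMA"),
                                  parent = c("CL:LYMPH", "CL:B")))
  cells <- make_cells(3, cell_type = c("CL:B", "CL:B", "CL:PLASMA"))
  prep <- tiny_prep(cbind(c(3.5, 4.5, 6.0)), cells)
  cube <- build_cube(prep)
  rolled <- cube_rollup(cube, graph)
  ly <- rolled[rolled$cell_type == "CL:LYMPH", ]
  expect_equal(ly$mean_nonzero, 14 / 3, tolerance = 1e-12)
  expect_identical(ly$n_expressing, 3L)
  expect_identical(ly$n_cells, 3L)
  bb <- rolled[rolled$cell_type == "CL:B", ]
  expect_equal(bb$mean_nonzero, 14 / 3, tolerance = 1e-12)  # B + plasma
  # single-term ontology: identity
  g1 <- cc_ontology(data.frame(child = "CL:B", parent = "CL:B2"))
  cube1 <- build_cube(tiny_prep(cbind(c(4, 6)),
                               make_cells(2, cell_type = "CL:B")))
  r1 <- cube_rollup(cube1, g1)
  expect_equal(r1$mean_nonzero[r1$cell_type == "CL:B"], 5)

  # rolled n_cells agrees with the label roll-up on the same annotations
  lab <- rollup(cells$cell_type, graph = graph)
  for (term in lab$term) {
    expect_identical(rolled$n_cells[rolled$cell_type == term],
                     lab$n_cells[lab$term == term])
  }
})
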