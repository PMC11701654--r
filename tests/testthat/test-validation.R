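# exact hypergeometric tail by direct enumeration over overlap sizes
enum_tail <- function(universe, n_ref, n_pred, ov) {
  xs <- 0:min(n_ref, n_pred)
  probs <- choose(n_ref, xs) * choose(universe - n_ref, n_pred - xs) /
    choose(universe, n_pred)
  sum(probs[xs >= ov])
}

test_that("marker recall and its chance probability are exact", {
  r <- marker_recall(letters[1:5], letters[1:5], 20)
  expect_identical(r$recall, 1)
  r0 <- marker_recall(letters[1:5], letters[6:9], 20)
  expect_identical(r0$recall, 0)
  expect_equal(r0$p_chance, 1, tolerance = 1e-12)

  # universe 10, reference 4, predicted 5, overlap 3
  r3 <- marker_recall(c("a", "b", "c", "x", "y"), c("a", "b", "c", "d"), 10)
  expect_identical(r3$n_overlap, 3L)
  expect_equal(r3$p_chance, enum_tail(10, 4, 5, 3), tolerance = 1e-12)

  # exhaustive agreement across small universes
  set.seed(19)
  for (i in 1:50) {
    u <- sample(4:15, 1)
    genes <- sprintf("g%02d", seq_len(u))
    ref <- sample(genes, sample(1:(u - 1), 1))
    pred <- sample(genes, sample(1:u, 1))
    got <- marker_recall(pred, ref, u)
    expect_equal(got$p_chance,
                 enum_tail(u, length(ref), length(pred), got$n_overlap),
                 tolerance = 1e-12)
  }
  expect_error(marker_recall(letters[1:3], character(), 10), "empty")
})

test_that("repeated-measures ANOVA matches paired t and aov oracles", {
  # constant per-gene values across levels: no treatment effect at all
  flat <- data.frame(gene = rep(c("g1", "g2", "g3"), each = 2),
                     level = rep(c("d1", "d2"), 3),
                     value = rep(c(1.2, 3.4, 5.6), each = 2))
  a0 <- rm_anova(flat)
  expect_identical(a0$F, 0)
  expect_identical(a0$p, 1)

  # two balanced levels: F equals the paired t statistic squared
  set.seed(5)
  g <- sprintf("g%02d", 1:12)
  d <- data.frame(gene = rep(g, 2), level = rep(c("d1", "d2"), each = 12),
                  value = c(rnorm(12, 5), rnorm(12, 5.4)))
  a <- rm_anova(d)
  tt <- t.test(d$value[d$level == "d1"], d$value[d$level == "d2"],
               paired = TRUE)
  expect_equal(a$F, unname(tt$statistic)^2, tolerance = 1e-9)
  expect_equal(a$p, tt$p.value, tolerance = 1e-9)

  # multi-level design against the within-subjects aov decomposition
  set.seed(6)
  d3 <- expand.grid(gene = sprintf("g%02d", 1:5),
                    level = c("l1", "l2", "l3"),
                    stringsAsFactors = FALSE)
  d3$value <- rnorm(15, 5) + ifelse(d3$level == "l2", 0.8, 0)
  a3 <- rm_anova(d3)
  fit <- summary(aov(value ~ level + Error(gene / level), data = d3))
  ref <- fit[["Error: gene:level"]][[1]]
  expect_equal(a3$F, ref[["F value"]][1], tolerance = 1e-9)
  expect_equal(a3$p, ref[["Pr(>F)"]][1], tolerance = 1e-9)
  expect_identical(a3$df1, 2L)
  expect_identical(a3$df2, 8L)

  # unbalanced input: incomplete genes are dropped, not fatal
  d_unb <- rbind(d, data.frame(gene = "gX", level = "d1", value = 4))
  a_unb <- rm_anova(d_unb)
  expect_identical(a_unb$n_subjects, 12L)
  expect_equal(a_unb$F, a$F, tolerance = 1e-12)

  expect_error(rm_anova(data.frame(gene = "g", level = "d1", value = 1)),
               ">= 2")
})

test_that("recall study recovers planted references and prunes colinear types", {
  corpus <- cached_corpus("mk", small_synth_config(seed = 31))
  prep <- run_preprocess(corpus$datasets)

  rs <- recall_study(prep, corpus$truth$markers, graph = NULL, seed = 2)
  expect_equal(attr(rs, "mean_recall"), 1.0)
  expect_true(all(rs$p_chance < 0.01))

  # with the ontology, the basal member of the colinear pair is dropped:
  # plasma cell (CL:0000786) sits below B cell (CL:0000236)
  rs_pruned <- recall_study(prep, corpus$truth$markers,
                            graph = corpus$graph, seed = 2)
  expect_false("CL:0000236" %in% rs_pruned$cell_type)
  expect_true("CL:0000786" %in% rs_pruned$cell_type)

  # corrupting half of each reference set halves recall
  noisy <- generate_reference_markers(corpus, noise = 0.5, seed = 3)
  rs_noisy <- recall_study(prep, noisy, graph = NULL, seed = 2)
  expect_lt(abs(attr(rs_noisy, "mean_recall") - 0.5), 0.2)

  # a reference tissue missing from the corpus is skipped with a warning
  ref_extra <- rbind(corpus$truth$markers,
                     data.frame(tissue = "UBERON:0000000",
                                cell_type = "CL:0000236", gene = "GENE0001"))
  expect_warning(recall_study(prep, ref_extra, graph = NULL, seed = 2),
                 "absent from corpus")
})

test_that("the batch-effect study validates its inputs and supports one gene", {
  corpus <- cached_corpus("plain", small_synth_config(seed = 5))
  gs <- list(single = corpus$datasets[[1]]$genes[3])
  ba <- batch_effect_study(corpus$datasets, "dataset_id", "cptt_log", gs)
  # one row per cell type; a single gene leaves no error df, so the
  # statistic is reported undefined
  expect_identical(nrow(ba),
                   length(unique(corpus$datasets[[1]]$cells$cell_type)))
  expect_true(all(is.na(ba$F)))
  expect_identical(unique(ba$n_genes), 1L)

  expect_error(batch_effect_study(corpus$datasets[1], "dataset_id",
                                  "cptt_log", gs), "constant")
})
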