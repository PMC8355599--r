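test_that("dynamic threshold keeps scores at or above the fraction of the max", {
  expect_setequal(dynamic_threshold(c(A = 1.0, B = 0.5, C = 0.09), 0.1),
                  c("A", "B"))
  # boundary: exactly 10% of the max is kept (only strictly lower is removed)
  expect_setequal(dynamic_threshold(c(A = 1.0, B = 0.1), 0.1), c("A", "B"))
  expect_setequal(dynamic_threshold(c(A = 0.4), 0.1), "A")
  # the top scorer always survives, any fraction <= 1
  expect_true("A" %in% dynamic_threshold(c(A = 2, B = 1.9), 1))
  expect_error(dynamic_threshold(setNames(numeric(), character())), "empty")
})

test_that("dynamic threshold agrees with direct enumeration on score tables", {
  withr::local_seed(42)
  for (i in 1:50) {
    n <- sample(1:8, 1)
    scores <- setNames(round(runif(n), 3), paste0("T", seq_len(n)))
    frac <- sample(c(0.05, 0.1, 0.25, 0.5, 1), 1)
    keep <- dynamic_threshold(scores, frac)
    want <- names(scores)[!(scores < frac * max(scores))]
    expect_setequal(keep, want)
  }
})

test_that("forest importance ranks an informative regulator over noise", {
  withr::local_seed(1)
  n <- 300L
  wins <- 0L
  n_runs <- 10L
  for (s in seq_len(n_runs)) {
    a <- rnorm(n)
    cand <- rbind(A = a, B = rnorm(n), C = rnorm(n))
    target <- a + rnorm(n, sd = 0.3)
    tab <- forest_importance(target, cand,
                             pruning_params(n_trees = 100, seed = s))
    expect_true(all(tab$scores >= 0))
    if (names(which.max(tab$scores)) == "A") wins <- wins + 1L
  }
  expect_gte(wins, n_runs - 1L)
})

test_that("forest importance handles the degenerate candidate counts", {
  withr::local_seed(2)
  x <- rnorm(50)
  target <- 2 * x + rnorm(50, sd = 0.1)
  one <- matrix(x, nrow = 1, dimnames = list("A", NULL))
  tab <- forest_importance(target, one, pruning_params(n_trees = 50, seed = 1))
  expect_named(tab$scores, "A")
  expect_gt(tab$scores[["A"]], 0)

  expect_error(
    forest_importance(rep(1, 50), one, pruning_params(n_trees = 10, seed = 1)),
    class = "grnprune_unprunable"
  )
  expect_error(
    forest_importance(rnorm(5), one[, 1:5, drop = FALSE],
                      pruning_params(n_trees = 10, seed = 1)),
    "too few samples"
  )
  expect_error(
    forest_importance(target, one, pruning_params(n_trees = 10, seed = 1),
                      target_id = "A"),
    "exclude the target"
  )
})

test_that("forest importance is deterministic given the seed", {
  withr::local_seed(3)
  cand <- rbind(A = rnorm(60), B = rnorm(60), C = rnorm(60))
  target <- cand["A", ] + rnorm(60, sd = 0.5)
  p <- pruning_params(n_trees = 50, seed = 99)
  t1 <- forest_importance(target, cand, p)
  t2 <- forest_importance(target, cand, p)
  expect_identical(t1$scores, t2$scores)
  t3 <- forest_importance(target, cand, pruning_params(n_trees = 50, seed = 100))
  expect_false(identical(t1$scores, t3$scores))
})

test_that("pruning keeps the informative regulator and drops the decoy", {
  withr::local_seed(4)
  n <- 400L
  a <- rnorm(n)
  expr <- rbind(
    A = a, B = rnorm(n),
    g = a + rnorm(n, sd = 0.3)
  )
  refnet <- grn(c("A", "B"), c("g", "g"))
  pruned <- prune_grn(refnet, expr, pruning_params(n_trees = 100, seed = 1))
  ed <- grn_edges(pruned)
  expect_true(nrow(ed[tf == "A" & target == "g"]) == 1L)
  expect_equal(nrow(ed), 1L)
})

test_that("pruning drop rules remove unprunable genes entirely", {
  withr::local_seed(5)
  n <- 60L
  expr <- rbind(A = rnorm(n), g1 = rnorm(n), flat = rep(3, n))
  # g2 absent from expr -> dropped; flat has zero variance -> dropped;
  # g3's only TF is absent from expr -> no candidates -> dropped
  refnet <- grn(c("A", "A", "A", "Bmissing"),
                c("g1", "g2", "flat", "g3"))
  pruned <- prune_grn(refnet, expr, pruning_params(n_trees = 20, seed = 1))
  expect_equal(target_ids(pruned), "g1")
  # the TF universe is inherited even when TFs lose all targets
  expect_true(all(c("A", "Bmissing") %in% tf_ids(pruned)))
})

test_that("a gene regulated only by itself is dropped", {
  withr::local_seed(6)
  expr <- rbind(A = rnorm(50), g = rnorm(50))
  refnet <- grn(c("g", "A"), c("g", "A"))
  pruned <- prune_grn(refnet, expr, pruning_params(n_trees = 20, seed = 1))
  expect_false("g" %in% target_ids(pruned))
})

test_that("pruned networks are subsets of the reference with >= 1 regulator per gene", {
  for (seed in 1:3) {
    sim <- simulate_genome(n_tfs = 8, n_genes = 15, true_per_gene = 2,
                           decoys_per_gene = 3, threshold_nt = 1000,
                           seed = seed)
    expr <- simulate_expression(sim$truth, n_samples = 120, seed = seed)
    ref <- assign_tfs(sim$peaks, sim$genes, 1000)
    pruned <- prune_grn(ref, expr, pruning_params(n_trees = 50, seed = seed))
    expect_true(all(edge_key_df(pruned) %in% edge_key_df(ref)))
    indeg <- table(grn_edges(pruned)$target)
    expect_true(all(indeg >= 1L))
    expect_true(all(target_ids(pruned) %in% target_ids(ref)))
  }
})

test_that("pruning is deterministic and independent of gene order", {
  sim <- simulate_genome(n_tfs = 6, n_genes = 10, true_per_gene = 2,
                         decoys_per_gene = 2, threshold_nt = 1000, seed = 11)
  expr <- simulate_expression(sim$truth, n_samples = 80, seed = 11)
  ref <- assign_tfs(sim$peaks, sim$genes, 1000)
  p <- pruning_params(n_trees = 30, seed = 7)
  out1 <- prune_grn(ref, expr, p)
  out2 <- prune_grn(ref, expr, p)
  expect_identical(grn_edges(out1), grn_edges(out2))

  # reversing the edge table must not change the result: per-gene seeds are
  # derived from the gene id, not the iteration position
  rev_ed <- grn_edges(ref)[.N:1]
  ref_rev <- grn(rev_ed$tf, rev_ed$target, label = ref$label)
  out3 <- prune_grn(ref_rev, expr, p)
  expect_identical(grn_edges(out1), grn_edges(out3))
})

test_that("per-gene seeds are stable and distinct", {
  s1 <- grnprune:::gene_seed(1L, "G0001")
  expect_identical(s1, grnprune:::gene_seed(1L, "G0001"))
  expect_false(s1 == grnprune:::gene_seed(1L, "G0002"))
  expect_false(s1 == grnprune:::gene_seed(2L, "G0001"))
  expect_true(s1 >= 0 && s1 < 2^31 - 1)
})
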