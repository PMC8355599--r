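test_that("connectance follows the pairs-present formula", {
  ppi <- interaction_network(c("T1", "T2"), c("T2", "T3"))
  expect_equal(connectance(c("T1", "T2", "T3"), ppi), 2 / 3)
  # a 4-clique reaches the upper bound 1
  cl <- t(combn(paste0("T", 1:4), 2))
  ppi4 <- interaction_network(cl[, 1], cl[, 2])
  expect_equal(connectance(paste0("T", 1:4), ppi4), 1)
  # single regulator: undefined
  expect_true(is.na(connectance("T1", ppi)))
  expect_true(is.na(connectance(character(), ppi)))
  # regulators missing from the ppi node set dilute the denominator
  expect_equal(connectance(c("T1", "T2", "ghost"), ppi), 1 / 3)
})

test_that("connectance matches brute-force enumeration over all small cases", {
  tfs <- paste0("T", 1:5)
  all_pairs <- t(combn(tfs, 2)) # 10 possible edges
  withr::local_seed(8)
  subgraphs <- c(0L, 1023L, sample.int(1022L, 40L)) # empty, complete, random
  sets <- unlist(lapply(2:5, function(k) combn(tfs, k, simplify = FALSE)),
                 recursive = FALSE)
  for (mask in subgraphs) {
    on <- which(bitwAnd(mask, bitwShiftL(1L, 0:9)) != 0L)
    ppi <- interaction_network(all_pairs[on, 1], all_pairs[on, 2], nodes = tfs)
    for (regs in sets) {
      got <- connectance(regs, ppi)
      # oracle: count qualifying pairs one by one
      cnt <- 0L
      for (i in seq_len(length(regs) - 1)) {
        for (j in seq(i + 1, length(regs))) {
          k1 <- paste(sort(c(regs[i], regs[j])), collapse = "|")
          edges_on <- apply(all_pairs[on, , drop = FALSE], 1,
                            function(e) paste(sort(e), collapse = "|"))
          cnt <- cnt + (k1 %in% edges_on)
        }
      }
      want <- cnt / choose(length(regs), 2)
      expect_equal(got, want)
      expect_true(got >= 0 && got <= 1)
    }
  }
})

test_that("connectance comparison tallies better/worse/equal per gene", {
  ppi <- interaction_network("A", "B", nodes = c("A", "B", "C"))
  before <- grn(c("A", "B", "C"), rep("g", 3))
  after <- grn(c("A", "B"), rep("g", 2))
  rep <- compare_connectance(before, after, ppi)
  expect_equal(rep$per_gene$rho_before, 1 / 3)
  expect_equal(rep$per_gene$rho_after, 1)
  expect_equal(rep$fractions[["better"]], 1)
  expect_equal(rep$n_comparable, 1L)

  # identical networks: every comparable gene is equal
  rep2 <- compare_connectance(before, before, ppi)
  expect_equal(rep2$fractions[["equal"]], 1)

  # genes left with < 2 regulators are excluded and counted as undefined
  after1 <- grn("A", "g")
  rep3 <- compare_connectance(before, after1, ppi)
  expect_equal(rep3$n_comparable, 0L)
  expect_equal(rep3$n_undefined, 1L)

  expect_error(compare_connectance(after, grn("A", "other"), ppi), "absent")
})

test_that("connectance fractions match a per-gene brute tally on random networks", {
  withr::local_seed(9)
  tfs <- paste0("T", 1:8)
  pp <- t(combn(tfs, 2))
  on <- sample(nrow(pp), 12)
  ppi <- interaction_network(pp[on, 1], pp[on, 2], nodes = tfs)
  for (rep_i in 1:3) {
    genes <- paste0("g", 1:20)
    bed <- data.table::rbindlist(lapply(genes, function(g) {
      data.table::data.table(tf = sample(tfs, sample(2:6, 1)), target = g)
    }))
    aed <- bed[, .SD[sample(.N, max(1L, .N - sample(0:2, 1)))], by = target]
    before <- grn(bed$tf, bed$target)
    after <- grn(aed$tf, aed$target)
    got <- compare_connectance(before, after, ppi)
    # independent tally straight from the definition
    tally <- c(better = 0L, worse = 0L, equal = 0L)
    n_undef <- 0L
    for (g in target_ids(after)) {
      rb <- connectance(grn_edges(before)[target == g, tf], ppi)
      ra <- connectance(grn_edges(after)[target == g, tf], ppi)
      if (is.na(rb) || is.na(ra)) n_undef <- n_undef + 1L
      else if (ra > rb) tally["better"] <- tally["better"] + 1L
      else if (ra < rb) tally["worse"] <- tally["worse"] + 1L
      else tally["equal"] <- tally["equal"] + 1L
    }
    expect_equal(got$fractions, tally / sum(tally))
    expect_equal(got$n_undefined, n_undef)
    expect_equal(sum(got$fractions), 1)
  }
})

test_that("correlation networks follow the positive-r convention", {
  withr::local_seed(10)
  base <- rnorm(40)
  expr <- rbind(
    T1 = base, T2 = base * 2 + 5, # r = 1 with T1
    T3 = -base, # r = -1 with T1/T2
    T4 = rnorm(40)
  )
  cn <- correlation_network(expr, rownames(expr), 0.85)
  expect_equal(nrow(cn$edges), 1L)
  expect_setequal(cn$nodes, c("T1", "T2"))
  # anti-correlated pairs never make an edge under the positive convention
  cn2 <- correlation_network(expr, c("T1", "T3"), 0.25)
  expect_equal(nrow(cn2$edges), 0L)
  # ...but do in absolute mode
  cn3 <- correlation_network(expr, c("T1", "T3"), 0.25, mode = "absolute")
  expect_equal(nrow(cn3$edges), 1L)
})

test_that("correlation network edges match direct pairwise computation", {
  withr::local_seed(11)
  expr <- matrix(rpois(5 * 60, 30), 5, 60,
                 dimnames = list(paste0("T", 1:5), NULL))
  expr["T2", ] <- expr["T1", ] + rpois(60, 4)
  for (thr in c(0.25, 0.45, 0.65, 0.85)) {
    cn <- correlation_network(expr, rownames(expr), thr)
    want <- list()
    for (i in 1:4) for (j in (i + 1):5) {
      r <- cor(expr[i, ], expr[j, ])
      if (r >= thr) want[[length(want) + 1L]] <-
          sort(c(rownames(expr)[i], rownames(expr)[j]))
    }
    got <- cn$edges[, paste(a, b)]
    expect_setequal(got, vapply(want, paste, collapse = " ", character(1)))
  }
})

test_that("correlation network warns on missing and flat TFs", {
  withr::local_seed(12)
  expr <- rbind(T1 = rnorm(30), T2 = rep(1, 30))
  w <- capture_warnings(correlation_network(expr, c("T1", "T2", "T9"), 0.5))
  expect_match(w, "absent", all = FALSE)
  expect_match(w, "zero-variance", all = FALSE)
  expect_warning(correlation_network(expr, c("T1", "T2"), 0.5),
                 "zero-variance")
  # symmetric in sample order
  expr2 <- rbind(T1 = rnorm(30), T2 = rnorm(30), T3 = rnorm(30))
  cn1 <- correlation_network(expr2, rownames(expr2), 0.25)
  cn2 <- correlation_network(expr2[, sample(30)], rownames(expr2), 0.25)
  expect_identical(cn1$edges[, list(a, b)], cn2$edges[, list(a, b)])
})

test_that("scored-edge filtering detects the 0-1000 scale and keeps >= min", {
  ed <- data.table::data.table(
    a = c("T1", "T2", "T1", "T3"), b = c("T2", "T3", "T3", "T4"),
    combined_score = c(800, 499, 900, 500),
    textmining = c(350, 620, 100, 650)
  )
  net <- filter_scored_edges(ed, "combined_score", 0.8)
  expect_equal(nrow(net$edges), 2L) # 800 kept at the boundary, 900 kept
  net2 <- filter_scored_edges(ed, "combined_score", 0.5)
  expect_equal(nrow(net2$edges), 3L) # 499 dropped, 500 boundary kept
  # row-by-row oracle on another field
  net3 <- filter_scored_edges(ed, "textmining", 0.6)
  want <- ed[ed$textmining / 1000 >= 0.6]
  expect_setequal(net3$edges[, paste(a, b)], want[, paste(pmin(a, b), pmax(a, b))])
  # scores already on 0-1 stay untouched
  ed2 <- data.table::data.table(a = "x", b = "y", s = 0.7)
  expect_equal(nrow(filter_scored_edges(ed2, "s", 0.7)$edges), 1L)
  expect_error(filter_scored_edges(ed, "nope", 0.5),
               class = "grnprune_config_error")
})

test_that("coexpression comparison is null on identical networks", {
  withr::local_seed(13)
  expr <- matrix(rnorm(8 * 30), 8, 30,
                 dimnames = list(paste0("g", 1:8), NULL))
  net <- grn(
    tf = c("A", "B", "A", "B", "A", "C", "A", "C"),
    target = c("g1", "g1", "g2", "g2", "g3", "g3", "g4", "g4")
  )
  rep <- coexpression_comparison(net, net, expr, k_max = 2)
  expect_equal(rep$t_statistic, 0)
  expect_equal(rep$p_value, 1)
  expect_equal(rep$n_pairs_before, rep$n_pairs_after)
})

test_that("cumulative shared-TF pair sets shrink as k grows", {
  withr::local_seed(14)
  sim <- simulate_genome(n_tfs = 8, n_genes = 25, true_per_gene = 3,
                         decoys_per_gene = 3, threshold_nt = 1000, seed = 3)
  expr <- simulate_expression(sim$truth, n_samples = 80, seed = 3)
  ref <- assign_tfs(sim$peaks, sim$genes, 1000)
  rep <- coexpression_comparison(ref, ref, expr, k_max = 4)
  expect_equal(rep$k, 2:4)
  expect_true(all(diff(rep$n_pairs_before) <= 0))
  expect_true(all(diff(rep$n_pairs_after) <= 0))
})

test_that("co-regulated gene pairs co-express more than unrelated pairs", {
  # generative construction: pairs sharing both true TFs vs sharing none
  deltas <- vapply(1:5, function(s) {
    sim <- simulate_genome(n_tfs = 10, n_genes = 40, true_per_gene = 2,
                           decoys_per_gene = 0, threshold_nt = 1000, seed = s)
    expr <- simulate_expression(sim$truth, n_samples = 150, seed = s)
    ed <- grn_edges(sim$truth$true_net)
    sets <- split(ed$tf, ed$target)
    genes <- names(sets)
    share2 <- c(); share0 <- c()
    for (i in seq_along(genes)[-length(genes)]) for (j in seq(i + 1, length(genes))) {
      n_sh <- length(intersect(sets[[i]], sets[[j]]))
      r <- cor(expr[genes[i], ], expr[genes[j], ])
      if (n_sh == 2) share2 <- c(share2, r)
      if (n_sh == 0) share0 <- c(share0, r)
    }
    mean(share2) - mean(share0)
  }, numeric(1))
  expect_true(mean(deltas) > 0)
  expect_true(all(deltas > 0))
})
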