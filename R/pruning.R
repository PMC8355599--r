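# Step two: per-gene random-forest relevance of the pre-assigned candidate
# regulators, then removal of every candidate scoring below a fraction of the
# gene's top score. Inference is deliberately restricted to the candidates
# from the distance step -- the forest ranks regulators, it does not discover
# them genome-wide.

#' Parameters for expression-based pruning
#'
#' @param n_trees trees per forest. 1000 gives production-stable rankings;
#'   100 is adequate for unit-scale data and is what the test-suite settings
#'   use.
#' @param k_split candidates considered at each split; `NULL` (default) means
#'   `ceiling(sqrt(p))` of the `p` candidates, the usual regression-forest
#'   default.
#' @param min_samples_split minimum samples a node must hold to be split
#'   (default 2, i.e. grow trees fully).
#' @param relevance_fraction dynamic-threshold fraction in (0, 1]: candidates
#'   scoring below `relevance_fraction * max(score)` for a gene are removed
#'   (default 0.1, i.e. 10% of the top regulator's relevance).
#' @param seed integer seed; per-gene seeds are derived deterministically from
#'   it and the gene identifier, so results do not depend on gene order.
#' @return list of class `pruning_params`
#' @export
pruning_params <- function(n_trees = 1000L, k_split = NULL,
                           min_samples_split = 2L,
                           relevance_fraction = 0.1, seed = 1L) {
  stopifnot(
    is.numeric(n_trees), n_trees >= 1,
    is.null(k_split) || (is.numeric(k_split) && k_split >= 1),
    is.numeric(min_samples_split), min_samples_split >= 1,
    is.numeric(relevance_fraction),
    relevance_fraction > 0, relevance_fraction <= 1,
    is.numeric(seed)
  )
  structure(
    list(
      n_trees = as.integer(n_trees),
      k_split = if (is.null(k_split)) NULL else as.integer(k_split),
      min_samples_split = as.integer(min_samples_split),
      relevance_fraction = as.numeric(relevance_fraction),
      seed = as.integer(seed)
    ),
    class = "pruning_params"
  )
}

#' Random-forest relevance of candidate regulators for one gene
#'
#' Fits an ensemble of regression trees predicting the (standardised) target
#' expression from the candidate TF expression profiles: each tree is grown on
#' a bootstrap resample, choosing at every node the best variance-reducing
#' split among `k_split` randomly drawn candidates. A candidate's importance
#' is the decrease in node impurity (sample-weighted variance) summed over the
#' nodes that split on it, averaged over trees and divided by the sample count
#' -- nonnegative, and larger for candidates whose expression predicts the
#' target better. The target is standardised to zero mean and unit variance
#' beforehand so importances are comparable across genes.
#'
#' The forest itself is delegated to [randomForest::randomForest()]; its
#' `IncNodePurity` measure is exactly this mean total variance reduction.
#'
#' @param target_expr numeric vector: target gene expression over samples
#' @param candidate_expr numeric matrix, candidates x samples, rownames = TF
#'   identifiers; must not contain the target gene itself
#' @param params a [pruning_params()]
#' @param target_id optional target identifier (used in messages and to check
#'   the candidate set excludes the target)
#' @return list of class `importance_table` with elements `target_id`,
#'   `scores` (named numeric, all >= 0), `n_samples_used`, `seed`
#' @export
forest_importance <- function(target_expr, candidate_expr, params = pruning_params(),
                              target_id = NA_character_) {
  stopifnot(inherits(params, "pruning_params"))
  if (is.vector(candidate_expr)) {
    candidate_expr <- matrix(candidate_expr, nrow = 1L,
                             dimnames = list("candidate", NULL))
  }
  if (is.null(rownames(candidate_expr))) {
    stop("`candidate_expr` must have TF identifiers as rownames")
  }
  n <- length(target_expr)
  if (ncol(candidate_expr) != n) {
    stop("`target_expr` and `candidate_expr` disagree on sample count")
  }
  if (n < 10L) {
    stop("too few samples (", n, "); need at least 10")
  }
  if (!is.na(target_id) && target_id %in% rownames(candidate_expr)) {
    stop("candidate set must exclude the target gene itself")
  }
  s <- sd(target_expr)
  if (!is.finite(s) || s == 0) {
    stop(errorCondition(
      paste0("zero-variance target", if (!is.na(target_id)) paste0(" ", target_id)),
      class = c("grnprune_unprunable", "error")
    ))
  }
  y <- (target_expr - mean(target_expr)) / s
  p <- nrow(candidate_expr)
  mtry <- if (is.null(params$k_split)) ceiling(sqrt(p)) else min(params$k_split, p)
  # min_samples_split is the smallest node still eligible for splitting;
  # randomForest's `nodesize` is the smallest terminal node.
  nodesize <- max(1L, params$min_samples_split - 1L)
  imp <- with_seed(params$seed, {
    rf <- randomForest::randomForest(
      x = t(candidate_expr), y = y,
      ntree = params$n_trees, mtry = mtry, nodesize = nodesize,
      importance = FALSE
    )
    rf$importance[, "IncNodePurity"]
  })
  scores <- setNames(pmax(as.numeric(imp), 0) / n, rownames(candidate_expr))
  structure(
    list(target_id = target_id, scores = scores,
         n_samples_used = n, seed = params$seed),
    class = "importance_table"
  )
}

#' Dynamic relevance threshold
#'
#' Keeps every candidate whose score reaches `fraction` of the maximum score
#' in the table; only candidates scoring strictly *lower* than the cutoff are
#' removed, so a score exactly equal to `fraction * max` is retained, and the
#' top-scoring candidate always survives.
#'
#' @param table an `importance_table` from [forest_importance()], or a named
#'   numeric vector of scores
#' @param fraction fraction of the maximum score in (0, 1]
#' @return character vector of retained TF identifiers
#' @examples
#' dynamic_threshold(c(A = 1, B = 0.5, C = 0.09), fraction = 0.1)
#' @export
dynamic_threshold <- function(table, fraction = 0.1) {
  scores <- if (inherits(table, "importance_table")) table$scores else table
  if (!is.numeric(scores) || is.null(names(scores))) {
    stop("`table` must be an importance_table or a named numeric vector")
  }
  if (length(scores) == 0L) stop("empty importance table")
  stopifnot(fraction > 0, fraction <= 1)
  cutoff <- fraction * max(scores)
  names(scores)[scores >= cutoff]
}

#' Prune a reference network with expression data
#'
#' For each target gene of the reference network that is present in the
#' expression matrix, restricts the candidate set to its assigned regulators
#' that are also present in the matrix (excluding the gene itself), scores
#' them with [forest_importance()], and keeps the edges passing
#' [dynamic_threshold()]. Target genes absent from the expression data, with
#' zero expression variance, or left with no candidates are dropped entirely
#' -- pruning can only remove, so the result is always a subnetwork of the
#' reference, and the drop rule is what shrinks the node count.
#'
#' Each gene's forest is seeded from `params$seed` and the gene identifier
#' ([gene_seed()]), making the result independent of gene iteration order.
#'
#' @param refnet reference [grn()]
#' @param expr numeric expression matrix (genes x samples) with gene rownames
#' @param params a [pruning_params()]
#' @param progress emit a message every `progress` genes (0 = silent)
#' @return pruned [grn()]; its TF universe is inherited from `refnet`
#' @export
prune_grn <- function(refnet, expr, params = pruning_params(), progress = 0L) {
  stopifnot(inherits(refnet, "grn"), is.matrix(expr), inherits(params, "pruning_params"))
  if (is.null(rownames(expr))) stop("`expr` must have gene rownames")
  regsets <- regulator_sets(refnet)
  targets <- names(regsets)
  if (!length(intersect(c(targets, unique(refnet$edges$tf)), rownames(expr)))) {
    stop("reference network and expression matrix share no gene identifiers")
  }
  if (ncol(expr) < 10L) stop("too few samples (", ncol(expr), "); need at least 10")
  targets <- intersect(targets, rownames(expr))
  kept <- vector("list", length(targets))
  for (i in seq_along(targets)) {
    g <- targets[i]
    cand <- setdiff(intersect(regsets[[g]], rownames(expr)), g)
    if (!length(cand)) next
    gp <- params
    gp$seed <- gene_seed(params$seed, g)
    tab <- tryCatch(
      forest_importance(expr[g, ], expr[cand, , drop = FALSE], gp, target_id = g),
      grnprune_unprunable = function(e) NULL
    )
    if (is.null(tab)) next
    keep <- dynamic_threshold(tab, params$relevance_fraction)
    kept[[i]] <- data.table(tf = keep, target = g)
    if (progress > 0L && i %% progress == 0L) {
      message("pruned ", i, "/", length(targets), " genes")
    }
  }
  ed <- rbindlist(kept)
  if (nrow(ed) == 0L) {
    return(grn(label = paste0(refnet$label, "+pruned"), tfs = tf_ids(refnet)))
  }
  grn(ed$tf, ed$target, label = paste0(refnet$label, "+pruned"),
      tfs = tf_ids(refnet))
}
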