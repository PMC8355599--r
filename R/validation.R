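# Quality metrics for the pruning step: connectance of each gene's regulator
# set against TF-TF interaction networks, and co-expression of gene pairs
# sharing regulators, each compared before vs after pruning. The rationale:
# TFs regulating the same gene tend to interact physically or functionally,
# so a cleaner regulator set should be denser in a trustworthy TF-TF network.

#' Connectance of a regulator set in a TF-TF interaction network
#'
#' Connectance (connectivity density) of the set of TFs assigned to one gene:
#' the number of interaction-network edges realised among the regulators,
#' divided by the number of pairs that could exist, `n(n-1)/2`. Lies in
#' `[0, 1]`; undefined (`NA`) for fewer than two regulators. Regulators
#' missing from the interaction network's node set still count toward the
#' denominator but can never contribute an edge -- incomplete interaction
#' coverage depresses connectance rather than hiding it.
#'
#' @param regulators character vector of TF identifiers (duplicates ignored)
#' @param ppi an [interaction_network()]
#' @return numeric scalar in `[0, 1]`, or `NA` when undefined
#' @examples
#' ppi <- interaction_network(c("T1", "T2"), c("T2", "T3"))
#' connectance(c("T1", "T2", "T3"), ppi) # 2/3
#' @export
connectance <- function(regulators, ppi) {
  stopifnot(inherits(ppi, "interaction_network"))
  regs <- unique(as.character(regulators))
  n <- length(regs)
  if (n < 2L) return(NA_real_)
  present <- sum(ppi$edges$a %in% regs & ppi$edges$b %in% regs)
  present / (n * (n - 1) / 2)
}

#' Compare per-gene connectance before and after pruning
#'
#' For every target of the pruned network, computes the connectance of its
#' regulator set in `before` and in `after` against the same interaction
#' network, and tallies for how many genes connectance increased (`better`),
#' decreased (`worse`) or stayed equal. Both values are exact rationals with
#' known denominators, so equality is tested exactly. Genes with an undefined
#' connectance on either side (fewer than two regulators) are excluded from
#' the fractions and counted in `n_undefined`.
#'
#' @param before reference [grn()]
#' @param after pruned [grn()]; its targets must be a subset of `before`'s
#' @param ppi an [interaction_network()]
#' @return list of class `connectance_report`: `per_gene` (data.table with
#'   `gene`, `rho_before`, `rho_after`, `status`), `fractions` (named numeric
#'   `better`/`worse`/`equal` summing to 1 over comparable genes),
#'   `n_comparable`, `n_undefined`, `ppi_label`
#' @export
compare_connectance <- function(before, after, ppi) {
  stopifnot(inherits(before, "grn"), inherits(after, "grn"),
            inherits(ppi, "interaction_network"))
  regs_b <- regulator_sets(before)
  regs_a <- regulator_sets(after)
  missing <- setdiff(names(regs_a), names(regs_b))
  if (length(missing)) {
    stop("targets of `after` absent from `before`: ",
         paste(head(missing, 3), collapse = ", "))
  }
  genes <- names(regs_a)
  rho_b <- vapply(genes, function(g) connectance(regs_b[[g]], ppi), numeric(1))
  rho_a <- vapply(genes, function(g) connectance(regs_a[[g]], ppi), numeric(1))
  status <- rep(NA_character_, length(genes))
  ok <- !is.na(rho_b) & !is.na(rho_a)
  status[ok] <- ifelse(rho_a[ok] > rho_b[ok], "better",
                       ifelse(rho_a[ok] < rho_b[ok], "worse", "equal"))
  per_gene <- data.table(gene = genes, rho_before = rho_b, rho_after = rho_a,
                         status = status)
  n_comp <- sum(ok)
  fr <- if (n_comp) {
    c(better = sum(status == "better", na.rm = TRUE),
      worse = sum(status == "worse", na.rm = TRUE),
      equal = sum(status == "equal", na.rm = TRUE)) / n_comp
  } else {
    c(better = NA_real_, worse = NA_real_, equal = NA_real_)
  }
  structure(
    list(per_gene = per_gene, fractions = fr, n_comparable = n_comp,
         n_undefined = sum(!ok), ppi_label = ppi$label),
    class = "connectance_report"
  )
}

#' @export
print.connectance_report <- function(x, ...) {
  cat(sprintf(
    "<connectance_report vs %s> %d comparable genes (%d undefined)\n",
    if (nzchar(x$ppi_label)) x$ppi_label else "ppi", x$n_comparable,
    x$n_undefined
  ))
  print(round(x$fractions, 3))
  invisible(x)
}

#' Pearson co-expression network among TFs
#'
#' Builds an undirected TF-TF network from expression data: an edge connects
#' two TFs when the Pearson correlation of their expression profiles reaches
#' the threshold. The default convention is positive correlation (`r >=
#' threshold`); `mode = "absolute"` uses `|r| >= threshold`. Node set =
#' TFs with at least one edge, so higher thresholds shrink both edges and
#' nodes. TFs absent from the matrix or with zero expression variance are
#' excluded with a warning.
#'
#' @param expr numeric expression matrix (genes x samples)
#' @param tfs character vector of TF identifiers
#' @param threshold correlation threshold in (-1, 1)
#' @param mode `"positive"` (default) or `"absolute"`
#' @return an [interaction_network()] labelled `corr_<threshold>`, with edge
#'   weights = correlation coefficients
#' @export
correlation_network <- function(expr, tfs, threshold,
                                mode = c("positive", "absolute")) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(expr), threshold > -1, threshold < 1)
  tfs <- unique(as.character(tfs))
  absent <- setdiff(tfs, rownames(expr))
  if (length(absent)) {
    warning(length(absent), " TF(s) absent from the expression matrix dropped",
            call. = FALSE)
    tfs <- setdiff(tfs, absent)
  }
  if (length(tfs)) {
    v <- apply(expr[tfs, , drop = FALSE], 1L, sd)
    if (any(v == 0)) {
      warning(sum(v == 0), " zero-variance TF(s) excluded", call. = FALSE)
      tfs <- tfs[v > 0]
    }
  }
  label <- paste0("corr_", threshold)
  if (length(tfs) < 2L) {
    return(interaction_network(label = label))
  }
  cm <- cor(t(expr[tfs, , drop = FALSE]))
  keep <- upper.tri(cm) & (if (mode == "positive") cm >= threshold else abs(cm) >= threshold)
  idx <- which(keep, arr.ind = TRUE)
  interaction_network(tfs[idx[, 1]], tfs[idx[, 2]], label = label,
                      weight = cm[keep])
}

#' Filter a scored TF-TF edge table into an interaction network
#'
#' Keeps unordered pairs whose score in the chosen evidence channel reaches
#' `min_score`. STRING exports score on an integer 0-1000 scale; when any
#' score exceeds 1 the column is divided by 1000 before comparison, so
#' `min_score` is always on the 0-1 scale. Duplicate unordered pairs keep
#' their best score; self-pairs are dropped.
#'
#' @param edges data.table from [read_scored_edges()] (columns `a`, `b`, plus
#'   one or more numeric score columns)
#' @param score_field name of the score column to filter on
#' @param min_score minimum score on the 0-1 scale (kept when `score >=
#'   min_score`)
#' @return an [interaction_network()]
#' @export
filter_scored_edges <- function(edges, score_field, min_score) {
  edges <- as.data.table(edges)
  fields <- setdiff(names(edges), c("a", "b"))
  if (!score_field %in% fields) {
    stop_config("unknown score field '", score_field, "'; available: ",
                paste(fields, collapse = ", "))
  }
  s <- as.numeric(edges[[score_field]])
  if (any(s > 1, na.rm = TRUE)) s <- s / 1000
  keep <- !is.na(s) & s >= min_score
  interaction_network(edges$a[keep], edges$b[keep], weight = s[keep],
                      label = paste0(score_field, ">=", min_score))
}

#' Co-expression of co-regulated gene pairs, before vs after pruning
#'
#' Co-regulated genes should co-express. For each `k` in `2..k_max`, collects
#' the unordered pairs of target genes sharing at least `k` regulators
#' (cumulative sets) in each network separately, computes each pair's Pearson
#' correlation over all samples, and compares the pruned network's pair
#' correlations against the reference network's with a Welch (unequal
#' variance) two-sample t-test. Only targets present in the expression matrix
#' participate. A `k` with fewer than two pairs on either side is reported
#' with `NA` statistics.
#'
#' @param before reference [grn()]
#' @param after pruned [grn()]
#' @param expr numeric expression matrix (genes x samples)
#' @param k_max largest shared-regulator count to report (>= 2)
#' @return data.table of class `coexpr_report`, one row per `k`: `k`,
#'   `n_pairs_before`, `mean_r_before`, `n_pairs_after`, `mean_r_after`,
#'   `t_statistic`, `p_value`
#' @export
coexpression_comparison <- function(before, after, expr, k_max = 5L) {
  stopifnot(inherits(before, "grn"), inherits(after, "grn"),
            is.matrix(expr), k_max >= 2L)
  shared_b <- shared_regulator_pairs(before, rownames(expr))
  shared_a <- shared_regulator_pairs(after, rownames(expr))
  genes <- unique(c(shared_b$genes, shared_a$genes))
  cm <- if (length(genes) >= 2L) cor(t(expr[genes, , drop = FALSE])) else NULL
  pair_r <- function(sh, k) {
    sel <- sh$pairs[sh$pairs$n >= k]
    if (!nrow(sel)) return(numeric())
    cm[cbind(match(sel$g1, rownames(cm)), match(sel$g2, colnames(cm)))]
  }
  rows <- lapply(2:k_max, function(k) {
    rb <- pair_r(shared_b, k)
    ra <- pair_r(shared_a, k)
    tt <- if (length(rb) >= 2L && length(ra) >= 2L) {
      tryCatch(t.test(ra, rb, var.equal = FALSE),
               error = function(e) NULL)
    } else NULL
    data.table(
      k = k,
      n_pairs_before = length(rb),
      mean_r_before = if (length(rb)) mean(rb) else NA_real_,
      n_pairs_after = length(ra),
      mean_r_after = if (length(ra)) mean(ra) else NA_real_,
      t_statistic = if (is.null(tt)) NA_real_ else unname(tt$statistic),
      p_value = if (is.null(tt)) NA_real_ else tt$p.value
    )
  })
  out <- rbindlist(rows)
  setattr(out, "class", c("coexpr_report", class(out)))
  out
}

# Unordered target pairs sharing >= 2 regulators, with shared counts, for
# targets present in `universe`. Shared counts come from the incidence
# matrix cross-product (targets x TFs), kept sparse.
shared_regulator_pairs <- function(net, universe) {
  ed <- net$edges[net$edges$target %in% universe]
  genes <- sort(unique(ed$target))
  if (length(genes) < 2L) {
    return(list(genes = genes,
                pairs = data.table(g1 = character(), g2 = character(),
                                   n = integer())))
  }
  tfs <- sort(unique(ed$tf))
  m <- Matrix::sparseMatrix(
    i = match(ed$target, genes),
    j = match(ed$tf, tfs),
    x = 1,
    dims = c(length(genes), length(tfs))
  )
  s <- Matrix::tcrossprod(m)
  s <- methods::as(methods::as(s, "generalMatrix"), "TsparseMatrix")
  keep <- s@i < s@j & s@x >= 2
  pairs <- data.table(
    g1 = genes[s@i[keep] + 1L],
    g2 = genes[s@j[keep] + 1L],
    n = as.integer(s@x[keep])
  )
  list(genes = genes, pairs = pairs)
}
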