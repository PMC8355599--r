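# Fully synthetic fixtures with known ground truth: a toy genome whose peaks
# sit at controlled distances from gene TSSs, and expression generated from a
# known linear TF -> gene model. Every pipeline stage is testable against the
# recorded truth without any external download.

#' Simulate a toy genome with peaks at known TSS distances
#'
#' Places target genes on synthetic chromosomes with inter-gene spacing larger
#' than twice the distance threshold (so a peak can only ever be assigned to
#' the gene it was planted for), and TF genes on a separate chromosome with no
#' peaks nearby. For every target gene, a set of *true* regulators and a
#' disjoint set of *decoy* TFs are drawn, and one peak per candidate is
#' planted at a uniform random distance within `threshold_nt` of the TSS
#' (random side, distance 0 = peak overlapping the TSS). By construction,
#' [assign_tfs()] at `threshold_nt` recovers exactly the union of true and
#' decoy candidates per gene: the reference network over-includes, and a good
#' pruner should strip the decoys.
#'
#' True edges carry linear effect weights drawn uniformly from
#' `[0.7, 1.3]` -- regulators of comparable, clearly detectable strength.
#'
#' @param n_tfs number of TFs
#' @param n_genes number of (non-TF) target genes
#' @param true_per_gene true regulators per gene
#' @param decoys_per_gene decoy candidates per gene (TFs within the window
#'   that do not regulate the gene)
#' @param threshold_nt distance window in nucleotides
#' @param seed integer seed
#' @param noise_sd standard deviation of the additive expression noise, on
#'   the scale of one standardised TF profile (default 1: noise comparable to
#'   a single regulator's contribution)
#' @param peak_width peak width in nucleotides
#' @return list with `genes` (annotation data.table as from
#'   [read_annotation()]), `peaks` (data.table as from [read_peaks()]), and
#'   `truth` (class `grn_truth`: `true_net`, `weights`, `decoys`,
#'   `candidates`, `noise_sd`, `threshold_nt`, `tf_ids`, `gene_ids`, `seed`)
#' @export
simulate_genome <- function(n_tfs = 25L, n_genes = 150L, true_per_gene = 3L,
                            decoys_per_gene = 12L, threshold_nt = 1500L,
                            seed = 1L, noise_sd = 1, peak_width = 100L) {
  stopifnot(n_tfs >= 1, n_genes >= 1, true_per_gene >= 1, decoys_per_gene >= 0,
            threshold_nt > 0, peak_width >= 1, noise_sd > 0)
  if (true_per_gene + decoys_per_gene > n_tfs) {
    stop("true_per_gene + decoys_per_gene must not exceed n_tfs")
  }
  spacing <- 2L * as.integer(threshold_nt) + as.integer(peak_width) + 1000L
  offset <- as.integer(threshold_nt) + as.integer(peak_width) + 1000L
  if (spacing <= 2L * threshold_nt) stop("infeasible gene spacing")
  tf_id <- sprintf("TF%03d", seq_len(n_tfs))
  gid <- sprintf("G%04d", seq_len(n_genes))

  with_seed(seed, {
    per_chrom <- 50L
    chrom <- paste0("chr", (seq_len(n_genes) - 1L) %/% per_chrom + 1L)
    slot <- (seq_len(n_genes) - 1L) %% per_chrom
    tss <- offset + slot * spacing
    genes <- data.table(
      gene_id = gid, chrom = chrom,
      strand = sample(c("+", "-"), n_genes, replace = TRUE),
      tss = as.integer(tss), is_tf = FALSE
    )
    tf_genes <- data.table(
      gene_id = tf_id, chrom = "chrTF",
      strand = sample(c("+", "-"), n_tfs, replace = TRUE),
      tss = as.integer(offset + (seq_len(n_tfs) - 1L) * spacing),
      is_tf = TRUE
    )
    cand_rows <- lapply(seq_len(n_genes), function(i) {
      cand <- sample(tf_id, true_per_gene + decoys_per_gene)
      data.table(
        tf = cand, target = gid[i],
        is_true = seq_along(cand) <= true_per_gene
      )
    })
    candidates <- rbindlist(cand_rows)
    candidates[, weight := ifelse(is_true, runif(.N, 0.7, 1.3), 0)]

    gtab <- genes[match(candidates$target, genes$gene_id)]
    d <- sample.int(as.integer(threshold_nt) + 1L, nrow(candidates),
                    replace = TRUE) - 1L
    side <- sample(c(-1L, 1L), nrow(candidates), replace = TRUE)
    w <- as.integer(peak_width)
    # 0-based half-open peaks at exact distance d from the TSS:
    #   d = 0 .......... peak spans the TSS
    #   upstream ....... last covered base = tss - d
    #   downstream ..... first covered base = tss + d
    pk_start <- ifelse(d == 0L, gtab$tss - w %/% 2L,
                       ifelse(side < 0L, gtab$tss - d + 1L - w, gtab$tss + d))
    peaks <- data.table(
      chrom = gtab$chrom,
      start = as.integer(pk_start),
      end = as.integer(pk_start + w),
      tf = candidates$tf,
      score = NA_real_
    )
  })

  true <- candidates[candidates$is_true == TRUE]
  truth <- structure(
    list(
      true_net = grn(true$tf, true$target, label = "true", tfs = tf_id),
      weights = true[, list(tf, target, weight)],
      decoys = candidates[candidates$is_true == FALSE, list(tf, target)],
      candidates = copy(candidates),
      noise_sd = noise_sd,
      threshold_nt = as.integer(threshold_nt),
      tf_ids = tf_id,
      gene_ids = gid,
      seed = as.integer(seed)
    ),
    class = "grn_truth"
  )
  list(genes = rbind(genes, tf_genes), peaks = peaks, truth = truth)
}

#' Simulate expression from a known regulatory model
#'
#' TF profiles are drawn from a small set of shared latent factors plus
#' independent noise, giving the TF compendium a realistic correlation
#' structure (factor loading 0.7, one factor per ~8 TFs). Each target gene is
#' the weighted sum of its true regulators' profiles plus Gaussian noise with
#' `truth$noise_sd`. Profiles are then shifted to non-negative values, scaled
#' and rounded to a counts-like integer range; Pearson correlations and tree
#' splits are insensitive to this per-gene affine step.
#'
#' @param truth `grn_truth` from [simulate_genome()]
#' @param n_samples number of samples (>= 50)
#' @param seed integer seed (same seed, same matrix)
#' @return numeric matrix (TF and target genes) x samples
#' @export
simulate_expression <- function(truth, n_samples = 400L, seed = 1L) {
  stopifnot(inherits(truth, "grn_truth"), n_samples >= 50L)
  tfs <- truth$tf_ids
  gid <- truth$gene_ids
  n_tfs <- length(tfs)
  with_seed(seed, {
    n_factors <- max(2L, ceiling(n_tfs / 8))
    f <- matrix(rnorm(n_factors * n_samples), n_factors, n_samples)
    fac_of <- rep_len(seq_len(n_factors), n_tfs)
    loading <- 0.7
    tf_expr <- loading * f[fac_of, , drop = FALSE] +
      sqrt(1 - loading^2) * matrix(rnorm(n_tfs * n_samples), n_tfs, n_samples)
    rownames(tf_expr) <- tfs
    wt <- truth$weights
    g_expr <- matrix(rnorm(length(gid) * n_samples, sd = truth$noise_sd),
                     length(gid), n_samples, dimnames = list(gid, NULL))
    for (i in seq_len(nrow(wt))) {
      g_expr[wt$target[i], ] <- g_expr[wt$target[i], ] +
        wt$weight[i] * tf_expr[wt$tf[i], ]
    }
    x <- rbind(tf_expr, g_expr)
    x <- t(apply(x, 1L, function(r) round((r - min(r)) * 20)))
  })
  colnames(x) <- sprintf("S%04d", seq_len(n_samples))
  x
}

#' Precision and recall of a pruned network against the simulated truth
#'
#' Edge-level precision (`|pruned and true| / |pruned|`) and recall
#' (`|pruned and true| / |true|`). The reference network itself scores
#' `precision = true / (true + decoys)` and `recall = 1`, the baseline a
#' useful pruner must beat on precision without giving up too much recall.
#'
#' @param pruned a [grn()]
#' @param truth `grn_truth` from [simulate_genome()]
#' @return named numeric vector `c(precision=, recall=)`; precision is `NA`
#'   (with a warning) for an empty pruned network
#' @export
evaluate_recovery <- function(pruned, truth) {
  stopifnot(inherits(pruned, "grn"), inherits(truth, "grn_truth"))
  true_keys <- edge_key(truth$true_net$edges$tf, truth$true_net$edges$target)
  pr_keys <- edge_key(pruned$edges$tf, pruned$edges$target)
  tp <- sum(pr_keys %in% true_keys)
  precision <- if (length(pr_keys)) tp / length(pr_keys) else {
    warning("empty pruned network: precision undefined", call. = FALSE)
    NA_real_
  }
  c(precision = precision, recall = tp / length(true_keys))
}

#' Interaction network of truly co-regulating TF pairs
#'
#' The TF-TF network implied by the simulated truth: two TFs interact when
#' they truly co-regulate at least `min_shared` genes. Used as the reference
#' interaction network for connectance validation on synthetic data.
#'
#' @param truth `grn_truth` from [simulate_genome()]
#' @param min_shared minimum number of co-regulated genes (default 1)
#' @return an [interaction_network()]
#' @export
truth_coregulation_network <- function(truth, min_shared = 1L) {
  stopifnot(inherits(truth, "grn_truth"), min_shared >= 1L)
  ed <- truth$true_net$edges
  sets <- split(ed$tf, ed$target)
  pairs <- rbindlist(lapply(sets, function(regs) {
    regs <- sort(unique(regs))
    if (length(regs) < 2L) return(NULL)
    cmb <- combn(regs, 2L)
    data.table(a = cmb[1L, ], b = cmb[2L, ])
  }))
  if (is.null(pairs) || nrow(pairs) == 0L) {
    return(interaction_network(nodes = truth$tf_ids, label = "true_coregulation"))
  }
  cnt <- pairs[, list(N = .N), by = list(a, b)]
  cnt <- cnt[cnt$N >= min_shared]
  interaction_network(cnt$a, cnt$b, nodes = truth$tf_ids,
                      label = "true_coregulation")
}

#' Write a synthetic fixture set to disk
#'
#' Writes the toy genome as BED (one file per TF would mirror ENCODE exports;
#' here a single name-column BED), GFF3 annotation, expression TSV, the true
#' network TSV and the TF list -- the complete plain-text input set for an
#' end-to-end run.
#'
#' @param sim result of [simulate_genome()]
#' @param expr result of [simulate_expression()]
#' @param dir output directory (created if needed)
#' @return named character vector of the files written
#' @export
write_fixtures <- function(sim, expr, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    peaks = file.path(dir, "peaks.bed"),
    annotation = file.path(dir, "genes.gff3"),
    expression = file.path(dir, "expression.tsv"),
    true_net = file.path(dir, "true_network.tsv"),
    tf_list = file.path(dir, "tf_list.txt")
  )
  pk <- sim$peaks
  writeLines(paste(pk$chrom, pk$start, pk$end, pk$tf, sep = "\t"),
             paths[["peaks"]])
  gn <- sim$genes
  # GFF3 is 1-based inclusive; internal TSS is 0-based. A 1 kb gene body
  # downstream of the TSS keeps start/end consistent with the strand.
  g_start1 <- ifelse(gn$strand == "+", gn$tss + 1L, pmax(1L, gn$tss + 1L - 999L))
  g_end1 <- ifelse(gn$strand == "+", gn$tss + 1L + 999L, gn$tss + 1L)
  writeLines(c(
    "##gff-version 3",
    paste(gn$chrom, "grnprune", "gene", g_start1, g_end1, ".", gn$strand, ".",
          paste0("ID=", gn$gene_id), sep = "\t")
  ), paths[["annotation"]])
  write_expression(expr, paths[["expression"]])
  write_grn(sim$truth$true_net, paths[["true_net"]], format = "tsv")
  writeLines(sim$truth$tf_ids, paths[["tf_list"]])
  paths
}
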