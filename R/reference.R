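# Step one: distance-thresholded assignment of TF binding sites to genes,
# plus network characterisation and edge-set comparison.

#' Assign TFs to genes by binding-site distance to the TSS
#'
#' Builds the reference regulatory network: a directed edge `tf -> gene`
#' exists whenever some peak of that TF lies within `threshold` nucleotides of
#' the gene's TSS on the same chromosome. The window is symmetric (upstream
#' and downstream). Distance between a peak `[start, end)` and a TSS is 0 when
#' the TSS falls inside the peak, and otherwise the distance from the TSS to
#' the nearest covered base, `min(|tss - start|, |tss - (end - 1)|)`. With
#' `mode = "midpoint"` the distance is instead measured from the peak
#' midpoint. Multiple qualifying peaks of one TF near one gene collapse to a
#' single unweighted edge.
#'
#' Implemented as an interval overlap between peaks and `TSS +/- threshold`
#' windows via [GenomicRanges::findOverlaps()]; the result is identical to
#' exhaustive all-pairs distance checking.
#'
#' @param peaks data.table from [read_peaks()] (columns `chrom`, `start`,
#'   `end`, `tf`; 0-based half-open)
#' @param genes data.table from [read_annotation()] (columns `gene_id`,
#'   `chrom`, `tss`, `is_tf`)
#' @param threshold maximum TSS distance in nucleotides (> 0)
#' @param mode `"interval"` (default) measures distance from the nearest peak
#'   boundary/overlap; `"midpoint"` from the peak midpoint
#' @return a [grn()] labelled with the threshold; its TF universe is the TF
#'   set of `peaks`
#' @examples
#' peaks <- data.table::data.table(chrom = "chr1", start = 100L, end = 200L,
#'                                 tf = "TF1")
#' genes <- data.table::data.table(gene_id = "g1", chrom = "chr1",
#'                                 strand = "+", tss = 1600L, is_tf = FALSE)
#' assign_tfs(peaks, genes, threshold = 1500)
#' @export
assign_tfs <- function(peaks, genes, threshold, mode = c("interval", "midpoint")) {
  mode <- match.arg(mode)
  if (!is.data.frame(genes) || nrow(genes) == 0L) {
    stop("empty gene catalog")
  }
  stopifnot(is.numeric(threshold), length(threshold) == 1L, threshold > 0)
  peaks <- as.data.table(peaks)
  genes <- as.data.table(genes)
  tf_universe <- sort(unique(peaks$tf))

  known <- peaks$chrom %in% unique(genes$chrom)
  if (!all(known)) {
    warning(sum(!known), " peak(s) on chromosomes absent from the annotation",
            " were skipped", call. = FALSE)
    peaks <- peaks[known]
  }
  if (nrow(peaks) == 0L) {
    return(grn(label = format_threshold_label(threshold), tfs = tf_universe))
  }

  # 1-based closed coordinates for the overlap engine. A peak [s, e) covers
  # bases s..e-1 (0-based), i.e. s+1..e (1-based closed).
  if (mode == "interval") {
    pk_start <- peaks$start + 1L
    pk_end <- peaks$end
  } else {
    mid <- floor((peaks$start + peaks$end - 1L) / 2) + 1L
    pk_start <- mid
    pk_end <- mid
  }
  lv <- sort(unique(c(peaks$chrom, genes$chrom)))
  pk <- GenomicRanges::GRanges(
    seqnames = factor(peaks$chrom, levels = lv),
    ranges = IRanges::IRanges(start = pk_start, end = pk_end)
  )
  # TSS window [tss - threshold, tss + threshold] (0-based closed), shifted
  # to 1-based. Negative starts are fine for overlap purposes.
  win <- GenomicRanges::GRanges(
    seqnames = factor(genes$chrom, levels = lv),
    ranges = IRanges::IRanges(
      start = genes$tss - as.integer(threshold) + 1L,
      end = genes$tss + as.integer(threshold) + 1L
    )
  )
  hits <- GenomicRanges::findOverlaps(pk, win)
  ed <- unique(data.table(
    tf = peaks$tf[S4Vectors::queryHits(hits)],
    target = genes$gene_id[S4Vectors::subjectHits(hits)]
  ))
  grn(ed$tf, ed$target, label = format_threshold_label(threshold),
      tfs = tf_universe)
}

format_threshold_label <- function(threshold) {
  sprintf("tss_dist<=%g", threshold)
}

#' Summarize a regulatory network
#'
#' Node and edge counts plus average in/out-degree. Following the convention
#' that only connected nodes count, `n_genes` is the number of nodes with at
#' least one incident edge; `avg_indegree` is edges divided by distinct
#' targets and `avg_outdegree` edges divided by distinct TFs with at least one
#' out-edge, so `avg_outdegree * n_tfs == n_edges` holds exactly.
#'
#' @param net a [grn()]
#' @return one-row data.frame with columns `label`, `n_genes`, `n_tfs`,
#'   `n_targets`, `n_edges`, `avg_indegree`, `avg_outdegree`
#' @export
summarize_grn <- function(net) {
  stopifnot(inherits(net, "grn"))
  ed <- net$edges
  n_tfs <- length(unique(ed$tf))
  n_targets <- length(unique(ed$target))
  data.frame(
    label = net$label,
    n_genes = length(unique(c(ed$tf, ed$target))),
    n_tfs = n_tfs,
    n_targets = n_targets,
    n_edges = nrow(ed),
    avg_indegree = if (n_targets) nrow(ed) / n_targets else 0,
    avg_outdegree = if (n_tfs) nrow(ed) / n_tfs else 0,
    stringsAsFactors = FALSE
  )
}

#' Edge membership across networks
#'
#' Compares the edge sets of two or more networks (edges identified by their
#' source and target ids, as in a Venn diagram of edges). Returns both the
#' per-edge membership table over the union and the count of edges in every
#' exclusive region.
#'
#' @param nets list of [grn()] objects
#' @param names optional names for the networks; defaults to their labels
#' @return list with `membership` (data.table: `tf`, `target`, one logical
#'   column per network) and `regions` (named integer vector; names are `&`
#'   -joined network names, counts sum to the union size)
#' @export
compare_edge_sets <- function(nets, names = NULL) {
  stopifnot(is.list(nets), length(nets) >= 2L)
  lapply(nets, function(n) stopifnot(inherits(n, "grn")))
  if (is.null(names)) {
    names <- vapply(seq_along(nets), function(i) {
      if (nzchar(nets[[i]]$label)) nets[[i]]$label else paste0("net", i)
    }, character(1))
  }
  if (anyDuplicated(names)) names <- make.unique(names)
  keys <- lapply(nets, function(n) edge_key(n$edges$tf, n$edges$target))
  all_edges <- unique(rbindlist(lapply(nets, function(n) n$edges[, list(tf, target)])))
  uk <- edge_key(all_edges$tf, all_edges$target)
  memb <- copy(all_edges)
  for (i in seq_along(nets)) {
    memb[, (names[i]) := uk %in% keys[[i]]]
  }
  pattern <- apply(as.matrix(memb[, names, with = FALSE]), 1L, function(row) {
    paste(names[row], collapse = "&")
  })
  regions <- table(pattern)
  list(
    membership = memb,
    regions = setNames(as.integer(regions), names(regions))
  )
}
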