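# Shared fixtures and independent oracles. The oracles deliberately avoid the
# code paths they check: assignment is re-derived by exhaustive all-pairs
# distance arithmetic, connectance by explicit pair enumeration.

# Random gene catalog + peak set on a couple of chromosomes.
random_fixture <- function(seed, n_tfs = 10L, n_genes = 100L, n_peaks = 500L,
                           span = 60000L) {
  withr::local_seed(seed)
  chroms <- c("chr1", "chr2", "chr3")
  genes <- data.table::data.table(
    gene_id = sprintf("g%03d", seq_len(n_genes)),
    chrom = sample(chroms, n_genes, replace = TRUE),
    strand = sample(c("+", "-"), n_genes, replace = TRUE),
    tss = sample.int(span, n_genes, replace = TRUE),
    is_tf = FALSE
  )
  start <- sample.int(span, n_peaks, replace = TRUE)
  peaks <- data.table::data.table(
    chrom = sample(chroms, n_peaks, replace = TRUE),
    start = start,
    end = start + sample.int(400L, n_peaks, replace = TRUE),
    tf = sprintf("tf%02d", sample.int(n_tfs, n_peaks, replace = TRUE)),
    score = NA_real_
  )
  list(genes = genes, peaks = peaks)
}

# Brute-force all-pairs assignment: for every peak x gene pair on the same
# chromosome, compute the interval-to-TSS distance directly and keep pairs
# within the threshold. Returns a sorted unique edge data.table.
oracle_assign <- function(peaks, genes, threshold) {
  rows <- list()
  for (i in seq_len(nrow(peaks))) {
    g <- genes[genes$chrom == peaks$chrom[i], ]
    if (!nrow(g)) next
    s <- peaks$start[i]
    e <- peaks$end[i]
    inside <- g$tss >= s & g$tss < e
    d <- ifelse(inside, 0L, pmin(abs(g$tss - s), abs(g$tss - (e - 1L))))
    hit <- which(d <= threshold)
    if (length(hit)) {
      rows[[length(rows) + 1L]] <- data.table::data.table(
        tf = peaks$tf[i], target = g$gene_id[hit]
      )
    }
  }
  if (!length(rows)) {
    return(data.table::data.table(tf = character(), target = character()))
  }
  out <- unique(data.table::rbindlist(rows))
  data.table::setkey(out, tf, target)
  out[]
}

# Random directed network for round-trip tests.
random_grn <- function(seed, n_tfs = 6L, n_targets = 20L, n_edges = 40L) {
  withr::local_seed(seed)
  tfs <- sprintf("TF%02d", seq_len(n_tfs))
  targets <- sprintf("g%03d", seq_len(n_targets))
  grn(sample(tfs, n_edges, replace = TRUE),
      sample(targets, n_edges, replace = TRUE),
      label = paste0("rand", seed))
}

edge_key_df <- function(net) {
  ed <- grn_edges(net)
  sort(paste(ed$tf, ed$target, sep = "\r"))
}

# Minimal GFF3 writer for annotation-parsing tests.
write_mini_gff <- function(path, rows) {
  writeLines(c("##gff-version 3", rows), path)
}
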