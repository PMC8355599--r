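# Readers and writers for every external representation the pipeline touches.
# Internal convention: all genomic coordinates are 0-based half-open, the BED
# convention. BED is taken verbatim; GTF/GFF (1-based inclusive) is converted
# on read. TSS positions are single 0-based genomic positions.

#' Read ChIP-Seq peaks from a BED-like file
#'
#' Accepts the 3+ column tab-delimited BED dialect. Coordinates are kept
#' verbatim (BED is already 0-based half-open). The TF each peak belongs to is
#' resolved either from `tf_id` (one-TF-per-file layout, the usual ENCODE
#' per-experiment export) or from a per-row name column (merged multi-TF
#' files); exactly one of the two must be given. Comment (`#`), `track` and
#' `browser` lines are skipped.
#'
#' @param path path to a BED file
#' @param tf_id TF identifier applied to every peak in the file
#' @param name_column 1-based column index holding the TF identifier per row
#' @param score_column optional 1-based column index holding a numeric score
#'   (defaults to BED column 5 when present)
#' @return data.table with columns `chrom`, `start`, `end` (0-based half-open),
#'   `tf`, `score`
#' @export
read_peaks <- function(path, tf_id = NULL, name_column = NULL,
                       score_column = NULL) {
  if (is.null(tf_id) && is.null(name_column)) {
    stop_config("no TF identifier resolvable: supply `tf_id` or `name_column`")
  }
  if (!is.null(tf_id) && !is.null(name_column)) {
    stop_config("supply either `tf_id` or `name_column`, not both")
  }
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (!length(idx)) {
    return(data.table(chrom = character(), start = integer(), end = integer(),
                      tf = character(), score = numeric()))
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  ncol_min <- min(lengths(fields))
  if (ncol_min < 3L) {
    bad <- idx[which.min(lengths(fields))]
    stop_parse("line ", bad, ": expected >= 3 tab-delimited columns")
  }
  getcol <- function(j) vapply(fields, `[[`, character(1), j)
  chrom <- getcol(1L)
  start <- suppressWarnings(as.integer(getcol(2L)))
  end <- suppressWarnings(as.integer(getcol(3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) {
    stop_parse("line ", idx[bad[1]], ": non-integer coordinates")
  }
  bad <- which(end <= start | start < 0L)
  if (length(bad)) {
    stop_parse("line ", idx[bad[1]], ": invalid interval (need 0 <= start < end)")
  }
  if (!is.null(name_column)) {
    if (ncol_min < name_column) {
      stop_config("name_column = ", name_column, " but file has rows with only ",
                  ncol_min, " columns")
    }
    tf <- getcol(as.integer(name_column))
    if (any(!nzchar(tf))) {
      stop_parse("line ", idx[which(!nzchar(tf))[1]], ": empty TF name")
    }
  } else {
    tf <- rep_len(as.character(tf_id), length(idx))
  }
  score <- rep_len(NA_real_, length(idx))
  sc <- if (!is.null(score_column)) as.integer(score_column) else if (ncol_min >= 5L) 5L else NA_integer_
  if (!is.na(sc) && ncol_min >= sc) {
    score <- suppressWarnings(as.numeric(getcol(sc)))
  }
  data.table(chrom = chrom, start = start, end = end, tf = tf, score = score)
}

#' Read a gene catalog from GTF/GFF annotation
#'
#' Keeps gene-level records and derives a single strand-aware TSS per gene:
#' with GTF/GFF 1-based inclusive coordinates, the TSS is `start - 1` on the
#' `+` strand and `end - 1` on the `-` strand once converted to the internal
#' 0-based convention. Records without a strand or without a resolvable gene
#' identifier are an error, since both are required for assignment.
#'
#' @param path path to a GTF/GFF/GFF3 file
#' @param feature feature type of gene-level records (default `"gene"`)
#' @param tf_list optional character vector of TF gene identifiers used to set
#'   the `is_tf` flag
#' @return data.table with columns `gene_id`, `chrom`, `strand`, `tss`
#'   (0-based), `is_tf`
#' @export
read_annotation <- function(path, feature = "gene", tf_list = NULL) {
  fmt <- if (grepl("\\.gtf(\\.gz)?$", path, ignore.case = TRUE)) "gtf" else "gff3"
  gr <- rtracklayer::import(path, format = fmt)
  md <- S4Vectors::mcols(gr)
  if ("type" %in% names(md)) {
    sel <- as.character(md$type) == feature
    if (any(sel)) {
      gr <- gr[sel]
      md <- S4Vectors::mcols(gr)
    }
  }
  if (!length(gr)) stop_parse("no '", feature, "' records found in ", path)
  ids <- NULL
  for (field in c("gene_id", "ID", "Name")) {
    if (field %in% names(md) && !all(is.na(md[[field]]))) {
      ids <- as.character(md[[field]])
      break
    }
  }
  if (is.null(ids) || anyNA(ids) || any(!nzchar(ids))) {
    stop_parse("gene records without a resolvable identifier ",
               "(need gene_id, ID or Name attribute)")
  }
  if (anyDuplicated(ids)) {
    stop_parse("duplicated gene identifier: ", ids[anyDuplicated(ids)])
  }
  strand <- as.character(BiocGenerics::strand(gr))
  if (any(strand == "*")) {
    stop_parse("gene record without strand: ", ids[which(strand == "*")[1]])
  }
  start1 <- BiocGenerics::start(gr) # 1-based inclusive
  end1 <- BiocGenerics::end(gr)
  tss <- ifelse(strand == "+", start1 - 1L, end1 - 1L)
  data.table(
    gene_id = ids,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = strand,
    tss = as.integer(tss),
    is_tf = ids %in% as.character(tf_list)
  )
}

#' Read a genes-by-samples expression matrix
#'
#' Delimited text with gene identifiers in the first column and sample
#' identifiers in the header row. Values are raw counts and must be
#' non-negative, finite numbers; duplicate gene identifiers are rejected.
#'
#' @param path path to a TSV/CSV file
#' @return numeric matrix, rows = genes, columns = samples
#' @export
read_expression <- function(path) {
  dt <- fread(path, header = TRUE, data.table = TRUE)
  if (nrow(dt) == 0L || ncol(dt) < 2L) {
    stop_parse("empty expression matrix in ", path)
  }
  ids <- as.character(dt[[1]])
  if (anyDuplicated(ids)) {
    stop_parse("duplicated gene id in expression matrix: ",
               ids[anyDuplicated(ids)])
  }
  m <- as.matrix(dt[, -1, with = FALSE])
  if (!is.numeric(m)) {
    j <- which(!vapply(dt[, -1, with = FALSE], is.numeric, logical(1)))[1]
    bad <- which(is.na(suppressWarnings(as.numeric(dt[[j + 1L]]))))[1]
    stop_parse("non-numeric expression value at gene ", ids[bad],
               ", sample ", names(dt)[j + 1L])
  }
  if (anyNA(m) || any(!is.finite(m))) {
    w <- which(!is.finite(m), arr.ind = TRUE)[1, ]
    stop_parse("non-finite expression value at gene ", ids[w[1]],
               ", sample ", colnames(m)[w[2]])
  }
  if (any(m < 0)) {
    w <- which(m < 0, arr.ind = TRUE)[1, ]
    stop_parse("negative expression value at gene ", ids[w[1]],
               ", sample ", colnames(m)[w[2]])
  }
  rownames(m) <- ids
  m
}

#' Write an expression matrix as TSV
#' @param expr numeric matrix with gene rownames and sample colnames
#' @param path output path
#' @export
write_expression <- function(expr, path) {
  dt <- data.table(gene_id = rownames(expr))
  dt <- cbind(dt, as.data.table(expr))
  fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Write a regulatory network
#'
#' Formats: `tsv` (two-column edge list with a `tf`/`target` header), `sif`
#' (tab-delimited Cytoscape SIF with interaction type `regulates`) and
#' `graphml` (via igraph). All three round-trip through [read_grn()] to the
#' identical edge set.
#'
#' @param net a [grn()]
#' @param path output path
#' @param format one of `"tsv"`, `"sif"`, `"graphml"`; default inferred from
#'   the file extension
#' @export
write_grn <- function(net, path, format = NULL) {
  stopifnot(inherits(net, "grn"))
  format <- resolve_net_format(path, format)
  ed <- net$edges
  if (format == "tsv") {
    fwrite(ed[, list(tf, target)], path, sep = "\t")
  } else if (format == "sif") {
    lines <- if (nrow(ed)) paste(ed$tf, "regulates", ed$target, sep = "\t") else character()
    writeLines(lines, path, useBytes = TRUE)
  } else { # graphml
    g <- igraph::graph_from_data_frame(
      ed[, list(tf, target)],
      directed = TRUE,
      vertices = data.frame(name = grn_nodes(net), stringsAsFactors = FALSE)
    )
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Read a regulatory network written by [write_grn()]
#' @param path input path
#' @param format one of `"tsv"`, `"sif"`, `"graphml"`; default inferred from
#'   the file extension
#' @param label label for the returned network
#' @return a [grn()]
#' @export
read_grn <- function(path, format = NULL, label = "") {
  format <- resolve_net_format(path, format)
  if (format == "tsv") {
    dt <- fread(path, header = TRUE, sep = "\t",
                colClasses = list(character = 1:2))
    grn(dt[[1]], dt[[2]], label = label)
  } else if (format == "sif") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(lines)]
    if (!length(lines)) return(grn(label = label))
    parts <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(parts) < 3L)) {
      stop_parse("SIF line without source/interaction/target: line ",
                 which(lengths(parts) < 3L)[1])
    }
    grn(vapply(parts, `[[`, character(1), 1L),
        vapply(parts, `[[`, character(1), 3L), label = label)
  } else {
    g <- igraph::read_graph(path, format = "graphml")
    ed <- igraph::as_edgelist(g, names = TRUE)
    grn(ed[, 1], ed[, 2], label = label,
        tfs = unique(ed[, 1]))
  }
}

resolve_net_format <- function(path, format) {
  if (is.null(format)) {
    ext <- tolower(sub(".*\\.", "", path))
    format <- switch(ext, tsv = "tsv", txt = "tsv", sif = "sif",
                     graphml = "graphml", xml = "graphml", NULL)
    if (is.null(format)) {
      stop_config("cannot infer network format from extension '.", ext,
                  "'; pass `format`")
    }
  }
  if (!format %in% c("tsv", "sif", "graphml")) {
    stop_config("unknown network format '", format,
                "'; use 'tsv', 'sif' or 'graphml'")
  }
  format
}

#' Read a plain gene list (one identifier per line)
#' @param path input path
#' @return character vector; empty lines and `#` comments are skipped
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Read an undirected TF-TF edge list
#'
#' Two-column tab-delimited text, optionally with a header. Lines define
#' unordered interaction pairs (curated PPI exports and the like).
#'
#' @param path input path
#' @param label label for the returned network
#' @return an [interaction_network()]
#' @export
read_interaction_network <- function(path, label = "") {
  dt <- fread(path, header = "auto", colClasses = list(character = 1:2))
  if (ncol(dt) < 2L) stop_parse("need at least two columns in ", path)
  interaction_network(as.character(dt[[1]]), as.character(dt[[2]]),
                      label = label)
}

#' Read a STRING-style scored edge table
#'
#' Tab- or space-delimited text whose first two columns are protein/TF
#' identifiers and whose remaining numeric columns are evidence-channel scores
#' (e.g. `combined_score`, `textmining`, `experimentally_determined`). The
#' dialect (which score columns exist, and whether they use the 0-1000 STRING
#' integer scale or a 0-1 scale) is detected from the header and values by
#' [filter_scored_edges()].
#'
#' @param path input path
#' @return data.table; first two columns renamed `a`, `b`
#' @export
read_scored_edges <- function(path) {
  dt <- fread(path, header = TRUE)
  if (ncol(dt) < 3L) {
    stop_parse("scored edge table needs two id columns and >= 1 score column")
  }
  setnames(dt, 1:2, c("a", "b"))
  dt[, a := as.character(a)]
  dt[, b := as.character(b)]
  dt
}
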