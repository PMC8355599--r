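# Core containers: directed regulatory networks and undirected TF-TF
# interaction networks. Both are thin S3 wrappers around data.tables so that
# edge-level operations stay vectorised.

#' Construct a directed regulatory network
#'
#' A regulatory network is a set of directed `tf -> target` edges. Duplicate
#' edges collapse to one (the networks are unweighted); TF-to-TF edges and, if
#' present in the input, self-edges are allowed. The TF universe of the
#' network is the union of edge sources and any explicitly declared TFs, so a
#' TF that loses all its targets during subsetting is still known to be a TF.
#'
#' @param tf character vector of regulator (source) identifiers
#' @param target character vector of target identifiers, same length as `tf`
#' @param label free-text label (e.g. the distance threshold used)
#' @param tfs optional character vector declaring additional TF identifiers
#'   beyond the edge sources
#' @return an object of class `grn`
#' @examples
#' net <- grn(c("A", "A", "B"), c("x", "y", "x"), label = "toy")
#' n_edges(net)
#' @export
grn <- function(tf = character(), target = character(), label = "", tfs = NULL) {
  tf <- as.character(tf)
  target <- as.character(target)
  if (length(tf) != length(target)) {
    stop("`tf` and `target` must have the same length")
  }
  if (anyNA(tf) || anyNA(target) || any(!nzchar(tf)) || any(!nzchar(target))) {
    stop("edge endpoints must be non-missing, non-empty strings")
  }
  edges <- unique(data.table(tf = tf, target = target))
  setkey(edges, tf, target)
  structure(
    list(
      edges = edges,
      tfs = sort(unique(c(tf, as.character(tfs)))),
      label = as.character(label)[1]
    ),
    class = "grn"
  )
}

#' @export
print.grn <- function(x, ...) {
  cat(sprintf(
    "<grn%s> %d edges, %d TFs with out-edges, %d targets\n",
    if (nzchar(x$label)) paste0(" ", x$label) else "",
    nrow(x$edges), length(unique(x$edges$tf)), length(unique(x$edges$target))
  ))
  if (nrow(x$edges)) print(head(x$edges, 5))
  invisible(x)
}

#' Edge table of a regulatory network
#' @param net a `grn`
#' @return data.table with columns `tf`, `target` (a copy)
#' @export
grn_edges <- function(net) {
  stopifnot(inherits(net, "grn"))
  copy(net$edges)
}

#' TF universe of a regulatory network
#' @param net a `grn`
#' @return character vector of TF identifiers (declared plus edge sources)
#' @export
tf_ids <- function(net) {
  stopifnot(inherits(net, "grn"))
  net$tfs
}

#' Target identifiers of a regulatory network
#' @param net a `grn`
#' @return character vector of distinct edge targets
#' @export
target_ids <- function(net) {
  stopifnot(inherits(net, "grn"))
  sort(unique(net$edges$target))
}

#' Node set of a regulatory network (nodes with at least one incident edge)
#' @param net a `grn`
#' @return character vector
#' @export
grn_nodes <- function(net) {
  stopifnot(inherits(net, "grn"))
  sort(unique(c(net$edges$tf, net$edges$target)))
}

#' Number of edges
#' @param net a `grn`
#' @export
n_edges <- function(net) nrow(net$edges)

#' Per-target regulator sets
#' @param net a `grn`
#' @return named list mapping each target to the character vector of its TFs
#' @export
regulator_sets <- function(net) {
  stopifnot(inherits(net, "grn"))
  if (!nrow(net$edges)) return(structure(list(), names = character()))
  split(net$edges$tf, net$edges$target)
}

#' Construct an undirected TF-TF interaction network
#'
#' Pairs are stored canonically (lexicographically smaller endpoint first) and
#' deduplicated; self-pairs are dropped. The node set defaults to the union of
#' edge endpoints but may be declared wider (e.g. all TFs that were queried,
#' including those with no interactions), which matters for connectance:
#' regulators absent from the interaction data still enlarge the denominator.
#'
#' @param a,b character vectors: endpoints of each undirected edge
#' @param nodes optional character vector of node identifiers; defaults to the
#'   edge endpoints
#' @param label free-text provenance label (e.g. `"corr_0.25"`)
#' @param weight optional numeric edge weights (e.g. correlation coefficients
#'   or confidence scores), same length as `a`
#' @return an object of class `interaction_network`
#' @export
interaction_network <- function(a = character(), b = character(), nodes = NULL,
                                label = "", weight = NULL) {
  a <- as.character(a)
  b <- as.character(b)
  if (length(a) != length(b)) stop("`a` and `b` must have the same length")
  ed <- data.table(a = pmin(a, b), b = pmax(a, b))
  if (!is.null(weight)) {
    stopifnot(length(weight) == length(a))
    ed[, weight := as.numeric(weight)]
    ed <- ed[ed$a != ed$b]
    # keep the best-supported record of each unordered pair
    ed <- ed[order(ed$a, ed$b, -ed$weight)]
    ed <- unique(ed, by = c("a", "b"))
  } else {
    ed <- unique(ed[ed$a != ed$b])
  }
  setkey(ed, a, b)
  nodes <- sort(unique(c(as.character(nodes), ed$a, ed$b)))
  structure(
    list(nodes = nodes, edges = ed, label = as.character(label)[1]),
    class = "interaction_network"
  )
}

#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf(
    "<interaction_network%s> %d nodes, %d edges\n",
    if (nzchar(x$label)) paste0(" ", x$label) else "",
    length(x$nodes), nrow(x$edges)
  ))
  invisible(x)
}
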