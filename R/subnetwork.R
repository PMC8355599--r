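# Subnetwork extraction: TF-centered ego networks and gene-list restriction
# (e.g. a mitochondrial-gene network regulated by all TFs).

#' Outgoing ego subnetwork of a TF
#'
#' The induced subgraph on a center node plus its out-neighbors (the genes it
#' regulates): every edge of the network whose two endpoints lie in that node
#' set is retained, so regulatory edges *among* the center's targets -- and
#' edges from targets back to the center -- stay in the subnetwork, not just
#' the star around the center.
#'
#' @param net a [grn()]
#' @param center gene identifier; must be a node of `net`
#' @return a [grn()] (always a subgraph of `net`; idempotent)
#' @export
ego_out <- function(net, center) {
  stopifnot(inherits(net, "grn"), is.character(center), length(center) == 1L)
  ed <- net$edges
  if (!center %in% c(ed$tf, ed$target)) {
    stop("center '", center, "' is not a node of the network")
  }
  nodes <- c(center, ed$target[ed$tf == center])
  keep <- ed$tf %in% nodes & ed$target %in% nodes
  grn(ed$tf[keep], ed$target[keep],
      label = paste0(net$label, "+ego_", center))
}

#' Restrict a network to a target gene list
#'
#' Keeps the regulations whose target is in `keep`, while TFs of the network
#' are implicitly always retained as nodes: edges onto TF targets survive
#' regardless of the list, so the regulatory wiring among the TFs stays
#' intact (the construction used for gene-list subnetworks such as the
#' mitochondrial GRN).
#'
#' @param net a [grn()]
#' @param keep character vector of target gene identifiers to retain
#' @return a [grn()]; warns when nothing is left
#' @export
restrict_targets <- function(net, keep) {
  stopifnot(inherits(net, "grn"))
  keep <- as.character(keep)
  ed <- net$edges
  tfs <- tf_ids(net)
  sel <- ed$target %in% keep | ed$target %in% tfs
  if (!any(sel)) {
    warning("no edges left after restriction; returning an empty network",
            call. = FALSE)
  }
  grn(ed$tf[sel], ed$target[sel],
      label = paste0(net$label, "+restricted"), tfs = tfs)
}
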