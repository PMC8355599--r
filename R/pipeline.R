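# End-to-end driver: reference networks at each distance threshold, pruning,
# summaries, validation reports and a machine-readable manifest. Configurable
# from R or from a YAML file; identical config + seed reproduces identical
# output files byte for byte.

#' Build a pipeline configuration
#'
#' Either `simulate` (parameters for [simulate_genome()] /
#' [simulate_expression()]) or `paths` (locations of peaks, annotation,
#' expression, TF list and optionally a TF-TF interaction network) must be
#' given. Thresholds must be sorted ascending; inputs are checked to exist at
#' configuration time so a full run never aborts halfway for a typo.
#'
#' @param thresholds distance thresholds in nucleotides, ascending (default
#'   1500, 2000, 5000)
#' @param pruning a [pruning_params()]
#' @param correlation_thresholds co-expression network thresholds (default
#'   0.25, 0.45, 0.65, 0.85)
#' @param k_max largest shared-regulator count for the co-expression report
#' @param simulate `NULL`, or a list of arguments for [simulate_genome()]
#'   (plus optional `n_samples`)
#' @param paths `NULL`, or a named list with `peaks` (BED; either a single
#'   file with `name_column` or a named vector of per-TF files), `annotation`
#'   (GTF/GFF), `expression` (TSV), `tf_list`, and optionally `ppi`
#'   (edge-list TSV)
#' @return list of class `pipeline_config`
#' @export
pipeline_config <- function(thresholds = c(1500, 2000, 5000),
                            pruning = pruning_params(),
                            correlation_thresholds = c(0.25, 0.45, 0.65, 0.85),
                            k_max = 5L,
                            simulate = NULL,
                            paths = NULL) {
  stopifnot(inherits(pruning, "pruning_params"))
  if (is.unsorted(thresholds, strictly = TRUE)) {
    stop_config("`thresholds` must be sorted in strictly ascending order")
  }
  if (any(thresholds <= 0)) stop_config("thresholds must be positive")
  if (is.null(simulate) == is.null(paths)) {
    stop_config("exactly one of `simulate` or `paths` must be given")
  }
  if (!is.null(paths)) {
    need <- c("peaks", "annotation", "expression", "tf_list")
    miss <- setdiff(need, names(paths))
    if (length(miss)) {
      stop_config("`paths` missing: ", paste(miss, collapse = ", "))
    }
    files <- unlist(paths, use.names = FALSE)
    absent <- files[!file.exists(files)]
    if (length(absent)) {
      stop_config("input file(s) not found: ", paste(absent, collapse = ", "))
    }
  }
  structure(
    list(thresholds = as.numeric(thresholds), pruning = pruning,
         correlation_thresholds = as.numeric(correlation_thresholds),
         k_max = as.integer(k_max), simulate = simulate, paths = paths),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; the `pruning`
#' block maps onto [pruning_params()]. Relative input paths are resolved
#' against the YAML file's directory.
#'
#' @param path YAML file
#' @return list of class `pipeline_config`
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  pr <- do.call(pruning_params, as.list(y$pruning))
  if (!is.null(y$paths)) {
    y$paths <- lapply(y$paths, function(p) {
      ifelse(file.exists(p), p, file.path(dirname(path), p))
    })
  }
  pipeline_config(
    thresholds = if (is.null(y$thresholds)) c(1500, 2000, 5000) else unlist(y$thresholds),
    pruning = pr,
    correlation_thresholds = if (is.null(y$correlation_thresholds)) {
      c(0.25, 0.45, 0.65, 0.85)
    } else unlist(y$correlation_thresholds),
    k_max = if (is.null(y$k_max)) 5L else y$k_max,
    simulate = y$simulate,
    paths = y$paths
  )
}

#' Run the full two-step workflow
#'
#' For each distance threshold: build the reference network, prune it with
#' the expression data, and write both as TSV. Then: network summaries,
#' edge-set comparison across the pruned networks, connectance reports
#' against the interaction network (the truth-derived co-regulation network
#' for simulated inputs, the supplied `ppi` otherwise), co-expression
#' reports, correlation-network sizes at each threshold, and -- for
#' simulated inputs -- edge precision/recall against the truth. A
#' `manifest.json` lists every file with the configuration hash and seed.
#'
#' @param config a [pipeline_config()]
#' @param outdir output directory (created if needed)
#' @param quiet suppress progress messages
#' @return (invisibly) list with the manifest and the in-memory results
#' @export
run_pipeline <- function(config, outdir, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message("[grnprune] ", ...)
  files <- character()
  add_file <- function(name, path) files[[name]] <<- basename(path)

  # --- inputs -------------------------------------------------------------
  if (!is.null(config$simulate)) {
    sa <- config$simulate
    n_samples <- if (is.null(sa$n_samples)) 400L else as.integer(sa$n_samples)
    sa$n_samples <- NULL
    if (is.null(sa$seed)) sa$seed <- config$pruning$seed
    say("simulating genome and expression (seed ", sa$seed, ")")
    sim <- do.call(simulate_genome, sa)
    expr <- simulate_expression(sim$truth, n_samples = n_samples,
                                seed = sa$seed)
    genes <- sim$genes
    peaks <- sim$peaks
    tf_list <- sim$truth$tf_ids
    ppi <- truth_coregulation_network(sim$truth)
    truth <- sim$truth
  } else {
    p <- config$paths
    say("reading inputs")
    tf_list <- read_gene_list(p$tf_list)
    genes <- read_annotation(p$annotation, tf_list = tf_list)
    pk <- p$peaks
    peaks <- if (length(pk) == 1L && is.null(names(pk))) {
      read_peaks(pk, name_column = 4L)
    } else {
      rbindlist(lapply(names(pk), function(tf) read_peaks(pk[[tf]], tf_id = tf)))
    }
    expr <- read_expression(p$expression)
    ppi <- if (!is.null(p$ppi)) read_interaction_network(p$ppi, label = "ppi") else NULL
    truth <- NULL
  }

  # --- per-threshold reference + pruned networks --------------------------
  refs <- list(); pruned <- list(); summaries <- list()
  for (thr in config$thresholds) {
    tag <- format(thr, scientific = FALSE)
    say("threshold ", tag, " nt: assigning TFs")
    ref <- assign_tfs(peaks, genes, threshold = thr)
    say("threshold ", tag, " nt: pruning ", length(target_ids(ref)), " targets")
    pr <- prune_grn(ref, expr, config$pruning)
    f_ref <- file.path(outdir, paste0("reference_", tag, ".tsv"))
    f_pr <- file.path(outdir, paste0("pruned_", tag, ".tsv"))
    write_grn(ref, f_ref, "tsv")
    write_grn(pr, f_pr, "tsv")
    add_file(paste0("reference_", tag), f_ref)
    add_file(paste0("pruned_", tag), f_pr)
    refs[[tag]] <- ref
    pruned[[tag]] <- pr
    summaries[[length(summaries) + 1L]] <-
      cbind(threshold = thr, stage = "reference", summarize_grn(ref))
    summaries[[length(summaries) + 1L]] <-
      cbind(threshold = thr, stage = "pruned", summarize_grn(pr))
  }
  summary_dt <- rbindlist(summaries)
  f <- file.path(outdir, "network_summaries.tsv")
  fwrite(summary_dt, f, sep = "\t")
  add_file("network_summaries", f)

  # --- edge-set comparison ------------------------------------------------
  edge_cmp <- NULL
  if (length(pruned) >= 2L) {
    edge_cmp <- compare_edge_sets(unname(pruned), names = names(pruned))
    f <- file.path(outdir, "edge_regions.tsv")
    fwrite(data.table(region = names(edge_cmp$regions),
                      n_edges = edge_cmp$regions), f, sep = "\t")
    add_file("edge_regions", f)
  }

  # --- connectance --------------------------------------------------------
  connectance_reports <- list()
  if (!is.null(ppi)) {
    rows <- list()
    for (tag in names(refs)) {
      rep <- compare_connectance(refs[[tag]], pruned[[tag]], ppi)
      connectance_reports[[tag]] <- rep
      rows[[tag]] <- data.table(
        threshold = tag, better = rep$fractions[["better"]],
        worse = rep$fractions[["worse"]], equal = rep$fractions[["equal"]],
        n_comparable = rep$n_comparable, n_undefined = rep$n_undefined
      )
      f <- file.path(outdir, paste0("connectance_", tag, ".tsv"))
      fwrite(rep$per_gene, f, sep = "\t")
      add_file(paste0("connectance_", tag), f)
    }
    f <- file.path(outdir, "connectance_fractions.tsv")
    fwrite(rbindlist(rows), f, sep = "\t")
    add_file("connectance_fractions", f)
  }

  # --- co-expression of co-regulated pairs --------------------------------
  coexpr_reports <- list()
  for (tag in names(refs)) {
    rep <- coexpression_comparison(refs[[tag]], pruned[[tag]], expr,
                                   k_max = config$k_max)
    coexpr_reports[[tag]] <- rep
    f <- file.path(outdir, paste0("coexpression_", tag, ".tsv"))
    fwrite(rep, f, sep = "\t")
    add_file(paste0("coexpression_", tag), f)
  }

  # --- TF correlation networks --------------------------------------------
  corr_rows <- lapply(config$correlation_thresholds, function(ct) {
    cn <- suppressWarnings(correlation_network(expr, tf_list, ct))
    data.table(threshold = ct, n_nodes = length(cn$nodes),
               n_edges = nrow(cn$edges))
  })
  f <- file.path(outdir, "correlation_networks.tsv")
  fwrite(rbindlist(corr_rows), f, sep = "\t")
  add_file("correlation_networks", f)

  # --- recovery against simulated truth -----------------------------------
  recovery <- NULL
  if (!is.null(truth)) {
    recovery <- rbindlist(lapply(names(pruned), function(tag) {
      pr <- evaluate_recovery(pruned[[tag]], truth)
      rf <- evaluate_recovery(refs[[tag]], truth)
      data.table(threshold = tag,
                 reference_precision = rf[["precision"]],
                 pruned_precision = pr[["precision"]],
                 pruned_recall = pr[["recall"]])
    }))
    f <- file.path(outdir, "recovery.tsv")
    fwrite(recovery, f, sep = "\t")
    add_file("recovery", f)
  }

  manifest <- list(
    config_hash = config_hash(config),
    seed = config$pruning$seed,
    thresholds = config$thresholds,
    files = as.list(files)
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  say("done: ", length(files), " output files in ", outdir)
  invisible(list(manifest = manifest, reference = refs, pruned = pruned,
                 summaries = summary_dt, edge_regions = edge_cmp,
                 connectance = connectance_reports, coexpression = coexpr_reports,
                 recovery = recovery))
}

config_hash <- function(config) {
  sprintf("%08x", hash_string(paste(deparse(config), collapse = "\n")))
}
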