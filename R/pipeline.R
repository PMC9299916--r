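#' Run the full multiple-resistance analysis pipeline
#'
#' Composes the stages end to end: ingest (or simulate) -> consolidate
#' (MoA-group merge + species/MoA filters) -> Jaccard proximity ->
#' complete-linkage clustering with k selection -> prevalence and proximity
#' networks with their correlation -> summary statistics. Any stage whose
#' inputs are unavailable for a given entry point is skipped and recorded as
#' such in the report.
#'
#' @param input one of:
#'   * a scenario preset name (see [scenario_presets()]), simulated at
#'     `seed`;
#'   * `"table1"` — enter at the proximity stage with the bundled published
#'     proximity matrix ([table1_proximity()]); the canonical way to
#'     reproduce the published clustering, since the species-level matrix
#'     behind it is not redistributable;
#'   * a path to a records CSV (see [read_records()]);
#'   * an [incidence_matrix] or `proximity_matrix` object.
#' @param outdir optional directory: when given, all artifacts are written
#'   there (matrices, proximity CSV, Newick tree, schedule, partition,
#'   GraphML/GEXF/edge-list exports, JSON report).
#' @param seed integer; overrides the preset's seed for simulated input and
#'   is recorded in the report. Ignored for deterministic entry points.
#' @param map [merge_map()] applied before filtering (matrix entry points
#'   only).
#' @param policy [filter_policy()] for consolidation.
#' @param rule [selection_rule()] for choosing the number of clusters.
#' @return list of class `run_report`. Key elements: `k`, `partition`,
#'   `schedule`, `merges`, `network_correlation`, `stats`, `dims`.
#'   Identical input, config and seed give an identical report.
#' @examples
#' rep <- run_pipeline("table1")
#' rep$k
#' split(names(rep$partition), rep$partition)
#' @export
run_pipeline <- function(input = "paperlike", outdir = NULL, seed = NULL,
                         map = merge_map(), policy = filter_policy(),
                         rule = selection_rule()) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  input_desc <- if (is.character(input)) input else class(input)[1L]
  mat <- NULL; prox <- NULL; truth <- NULL; config <- NULL

  if (is.character(input) && length(input) == 1L) {
    presets <- scenario_presets()
    if (input == "table1") {
      prox <- stage("proximity", table1_proximity())
    } else if (input %in% names(presets)) {
      config <- presets[[input]]
      if (!is.null(seed)) config$seed <- as.integer(seed)
      sim <- stage("simulate", generate_incidence(config))
      mat <- sim$matrix
      truth <- sim$truth
    } else if (file.exists(input)) {
      mat <- stage("ingest", records_to_matrix(read_records(input)))
    } else {
      stop("unknown input: not a preset, 'table1', or an existing file",
           call. = FALSE)
    }
  } else if (inherits(input, "incidence_matrix")) {
    mat <- input
  } else if (inherits(input, "proximity_matrix")) {
    prox <- input
  } else {
    stop("unsupported input type", call. = FALSE)
  }

  dims <- list(); summary_tab <- NULL; filtered <- NULL; freport <- NULL
  if (!is.null(mat)) {
    merged <- stage("consolidate", merge_moa_groups(mat, map))
    summary_tab <- moa_summary(merged)
    filtered <- stage("consolidate", filter_matrix(merged, policy))
    freport <- filter_report(filtered)
    dims <- list(before = dim(mat), merged = dim(merged),
                 after = dim(filtered))
    prox <- stage("proximity", proximity_matrix(filtered))
  } else {
    dims <- list(before = dim(prox), after = dim(prox))
  }

  dend <- stage("cluster", agglomerate(to_distance(prox)))
  sched <- agglomeration_schedule(dend)
  sel <- stage("cluster", select_k(dend, rule))
  part <- cut_dendrogram(dend, sel$k)
  merges <- lapply(seq_along(dend$height), function(s) {
    list(step = s,
         left = dend$members[[s]]$left,
         right = dend$members[[s]]$right,
         height = dend$height[s])
  })

  prox_net <- stage("network",
                    build_proximity_network(
                      prox, partition = part,
                      prevalence = if (!is.null(filtered))
                        rowSums(filtered)))
  prev_net <- NULL; net_cor <- NULL
  if (!is.null(filtered)) {
    prev_net <- stage("network",
                      build_prevalence_network(filtered, partition = part))
    net_cor <- stage("network", tryCatch(
      correlate_networks(prev_net, prox_net),
      error = function(e) NULL))
  }

  stats_out <- list()
  if (!is.null(filtered)) {
    counts <- species_moa_counts(filtered)
    stats_out$moa_counts_by_growth_form <- growth_form_summary(counts)
    stats_out$median_moas <- median(counts$n_moas)
    two <- split(counts$n_moas, counts$growth_form)
    two <- two[names(two) %in% c("monocot", "dicot")]
    stats_out$median_test <- if (length(two) == 2L &&
                                 all(lengths(two) > 0L)) {
      tryCatch(mood_median_test(two), error = function(e) NULL)
    }
    stats_out$prevalence_vs_multiresistance <- tryCatch(
      prevalence_vs_multiresistance(summary_tab), error = function(e) NULL)
  }

  report <- structure(list(
    input = input_desc,
    seed = if (!is.null(config)) config$seed else seed,
    dims = dims,
    filter_report = freport,
    moa_summary = summary_tab,
    schedule = sched,
    merges = merges,
    k = sel$k,
    k_method = sel$method,
    k_diagnostics = sel$diagnostics,
    partition = part,
    network_correlation = net_cor,
    stats = stats_out,
    versions = list(moaclust = as.character(packageVersion("moaclust")))),
    class = "run_report")

  if (!is.null(outdir)) {
    write_run_artifacts(report, outdir,
                        matrix = mat, filtered = filtered, prox = prox,
                        dend = dend, prox_net = prox_net,
                        prev_net = prev_net, truth = truth, config = config)
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("run_report:", x$input, "\n")
  if (length(x$dims$before)) {
    cat(sprintf("  matrix: %s -> %s (MoAs x species)\n",
                paste(x$dims$before, collapse = " x "),
                paste(x$dims$after, collapse = " x ")))
  }
  cat(sprintf("  k = %d (%s); clusters: %s\n", x$k, x$k_method,
              paste(vapply(split(names(x$partition), x$partition),
                           function(m) paste0("{", paste(m, collapse = ","), "}"),
                           character(1)), collapse = " ")))
  if (!is.null(x$network_correlation)) {
    nc <- x$network_correlation
    cat(sprintf("  prevalence~proximity: r = %.3f (df %d, P = %.3g, R2 = %.2f)\n",
                nc$estimate, nc$df, nc$p_value, nc$r_squared))
  }
  invisible(x)
}

# write every serializable artifact of a run; file set is fixed so reruns
# are byte-identical
write_run_artifacts <- function(report, outdir, matrix, filtered, prox,
                                dend, prox_net, prev_net, truth, config) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(outdir, f)
  if (!is.null(matrix)) write_matrix_csv(matrix, p("matrix_full.csv"),
                                         p("growth_forms.csv"))
  if (!is.null(filtered)) {
    write_matrix_csv(filtered, p("matrix_consolidated.csv"))
    write_filter_report(filter_report(filtered), p("filter_report.json"))
  }
  write_proximity_csv(prox, p("proximity.csv"))
  as_newick(dend, p("dendrogram.nwk"))
  write.csv(report$schedule, p("schedule.csv"), row.names = FALSE)
  write.csv(data.frame(moa = names(report$partition),
                       cluster = unname(report$partition)),
            p("partition.csv"), row.names = FALSE)
  write_network_graphml(prox_net, p("proximity_network.graphml"))
  write_network_gexf(prox_net, p("proximity_network.gexf"))
  write_network_edgelist(prox_net, p("proximity_network_edges.csv"))
  if (!is.null(prev_net)) {
    write_network_graphml(prev_net, p("prevalence_network.graphml"))
    write_network_gexf(prev_net, p("prevalence_network.gexf"))
    write_network_edgelist(prev_net, p("prevalence_network_edges.csv"))
  }
  if (!is.null(truth)) write_truth_json(truth, p("ground_truth.json"))
  if (!is.null(config)) write_config_yaml(config, p("config.yaml"))
  write_report_json(report, p("report.json"))
  invisible(outdir)
}

#' Serialize a run report as JSON
#'
#' Deterministic: the same report always yields the same bytes.
#'
#' @param report a `run_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  unres <- function(x) if (inherits(x, "stat_result")) unclass(x) else x
  out <- unclass(report)
  out$partition <- as.list(report$partition)
  out$network_correlation <- unres(out$network_correlation)
  out$stats <- lapply(out$stats, unres)
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = 10, na = "null")
  invisible(path)
}
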