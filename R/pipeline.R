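#' Run the full collaboration-pattern analysis pipeline
#'
#' Executes, in order: the patient-selection funnel, discipline-log
#' construction, trace clustering, per-cluster collaborative networks and
#' indices, pattern classification, HbA1c outcome segmentation, the
#' pattern-by-segment contingency table, and the subgroup-versus-cohort
#' proportion comparisons. The analysis set is the eligible patients with at
#' least one in-window CVPA. The pipeline itself draws no random numbers, so
#' a rerun on the same inputs yields a bit-identical report.
#'
#' @param encounters CVPA encounter data frame (see [read_encounters()]).
#' @param measurements validated HbA1c measurement data frame.
#' @param patients patient table with comorbidity counts.
#' @param min_tests,tolerance_months,window_center,window_halfwidth funnel
#'   parameters (see [run_funnel()]).
#' @param clustering a [clustering_config()].
#' @param thresholds a [pattern_thresholds()].
#' @param alpha,variant,fisher_threshold,reference,adjust statistics options
#'   (see [run_all_comparisons()]).
#' @param tie_break same-day discipline tie-break order.
#' @return object of class `collab_run`: list with `funnel`, `log`,
#'   `clusters`, `networks`, `cluster_labels`, `patterns`, `segments`,
#'   `contingency`, `comparisons`, `config` (echo of every parameter) and
#'   `version`.
#' @export
run_pipeline <- function(encounters, measurements, patients,
                         min_tests = 2, tolerance_months = 4,
                         window_center = 18, window_halfwidth = 8,
                         clustering = clustering_config(),
                         thresholds = pattern_thresholds(),
                         alpha = 0.05, variant = "z", fisher_threshold = 5,
                         reference = "total", adjust = "none",
                         tie_break = DISCIPLINES) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline failed at the ", name, " stage: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  measurements <- stage("input-validation", validate_measurements(measurements))
  funnel <- stage("selection-funnel",
                  run_funnel(patients, measurements, min_tests,
                             tolerance_months, window_center, window_halfwidth))
  if (length(funnel$eligible) == 0) {
    stop("pipeline failed at the discipline-log stage: no eligible patients")
  }
  log <- stage("discipline-log",
               build_discipline_log(encounters, funnel$windows, tie_break))
  windows <- funnel$windows[funnel$windows$patient_id %in%
                            names(log$sequences), , drop = FALSE]
  clusters <- stage("trace-clustering", cluster_traces(log, clustering))
  networks <- stage("cluster-networks", cluster_networks(clusters, log))
  labels <- stage("pattern-classification",
                  classify_clusters(networks, thresholds))
  patterns <- stage("pattern-assignment",
                    assign_patient_patterns(clusters, labels))
  segments <- stage("outcome-segmentation",
                    classify_segments(measurements, windows))
  tab <- stage("contingency", build_contingency(patterns, segments))
  comparisons <- stage("proportion-tests",
                       run_all_comparisons(tab, alpha = alpha,
                                           variant = variant,
                                           fisher_threshold = fisher_threshold,
                                           reference = reference,
                                           adjust = adjust))
  structure(list(
    funnel = funnel, log = log, clusters = clusters, networks = networks,
    cluster_labels = labels, patterns = patterns, segments = segments,
    contingency = tab, comparisons = comparisons,
    config = list(min_tests = min_tests, tolerance_months = tolerance_months,
                  window_center = window_center,
                  window_halfwidth = window_halfwidth,
                  clustering = unclass(clustering),
                  thresholds = unclass(thresholds), alpha = alpha,
                  variant = variant, fisher_threshold = fisher_threshold,
                  reference = reference, adjust = adjust,
                  tie_break = tie_break),
    version = as.character(packageVersion("triadminer"))
  ), class = "collab_run")
}

#' @export
print.collab_run <- function(x, ...) {
  print(x$funnel)
  print(x$clusters)
  cat("Cluster patterns:\n")
  for (nm in names(x$cluster_labels)) {
    lab <- x$cluster_labels[[nm]]
    cat(sprintf("  %-12s %s%s\n", nm, lab$label,
                if (is.na(lab$leader)) "" else paste0(" (leader ", lab$leader, ")")))
  }
  cat("Segments:\n")
  print(segment_counts(x$segments))
  sig <- x$comparisons[x$comparisons$significant, , drop = FALSE]
  cat(nrow(sig), "significant subgroup comparison(s) at alpha =",
      x$config$alpha, "\n")
  invisible(x)
}

run_report_list <- function(run) {
  perc <- contingency_percentages(run$contingency)
  list(
    version = run$version,
    config = run$config,
    funnel = as.list(run$funnel$counts),
    clusters = list(
      sizes = as.list(table(run$clusters$cluster_id[!run$clusters$is_outlier])),
      n_outliers = sum(run$clusters$is_outlier)
    ),
    cluster_labels = lapply(run$cluster_labels, function(l) {
      list(label = l$label, leader = l$leader)
    }),
    cluster_indices = lapply(run$networks, function(cl) {
      list(participation = as.list(round(cl$metrics$participation, 4)),
           self_referral = as.list(round(cl$metrics$self_referral, 4)),
           is_outlier = cl$is_outlier)
    }),
    segments = segment_counts(run$segments),
    contingency = list(counts = run$contingency$counts,
                       row_percent = perc$rows, total_percent = perc$total),
    comparisons = run$comparisons
  )
}

#' Write all artifacts of a pipeline run
#'
#' Writes the funnel JSON, cluster assignment and label CSVs, per-cluster
#' GraphML and DOT networks, the segment CSV, the contingency and comparison
#' CSVs, a machine-readable `report.json` and a human-readable `report.md`.
#' Output is deterministic for a fixed run object.
#'
#' @param run a `collab_run`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run_report <- function(run, dir) {
  stopifnot(inherits(run, "collab_run"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(as.list(run$funnel$counts), file.path(dir, "funnel.json"),
                       auto_unbox = TRUE)
  assignments <- merge(as.data.frame(run$clusters), run$patterns,
                       by = "patient_id", sort = TRUE)
  write.csv(assignments, file.path(dir, "assignments.csv"), row.names = FALSE)
  labels <- data.frame(
    cluster = names(run$cluster_labels),
    label = vapply(run$cluster_labels, `[[`, "", "label"),
    leader = vapply(run$cluster_labels, function(l) l$leader %||% NA_character_,
                    NA_character_)
  )
  write.csv(labels, file.path(dir, "cluster_labels.csv"), row.names = FALSE)
  write.csv(run$segments, file.path(dir, "segments.csv"), row.names = FALSE)
  write.csv(as.data.frame(run$contingency$counts),
            file.path(dir, "contingency_counts.csv"))
  write.csv(run$comparisons, file.path(dir, "comparisons.csv"),
            row.names = FALSE)
  net_dir <- file.path(dir, "networks")
  dir.create(net_dir, showWarnings = FALSE)
  for (nm in names(run$networks)) {
    export_network(run$networks[[nm]]$network,
                   file.path(net_dir, paste0(nm, ".graphml")), "graphml")
    export_network(run$networks[[nm]]$network,
                   file.path(net_dir, paste0(nm, ".dot")), "dot")
  }
  jsonlite::write_json(run_report_list(run), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  md <- c(
    "# Collaboration-pattern analysis report", "",
    "## Selection funnel",
    paste0("- ", names(run$funnel$counts), ": ", run$funnel$counts), "",
    "## Clusters and patterns",
    paste0("- ", labels$cluster, ": ", labels$label,
           ifelse(is.na(labels$leader), "", paste0(" (leader ", labels$leader, ")"))),
    paste0("- outliers: ", sum(run$clusters$is_outlier), " patient(s)"), "",
    "## Outcome segments",
    paste0("- ", SEGMENT_LEVELS, ": ",
           segment_counts(run$segments)$n, " (",
           segment_counts(run$segments)$pct, "%)"), "",
    "## Significant subgroup comparisons",
    if (any(run$comparisons$significant)) {
      with(run$comparisons[run$comparisons$significant, ],
           sprintf("- %s x %s: %.0f%% vs %.0f%% (p = %.3f, %s)",
                   pattern, segment, sub_pct, ref_pct, p_value, method))
    } else "- none"
  )
  writeLines(md, file.path(dir, "report.md"))
  invisible(dir)
}
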