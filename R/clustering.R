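#' Trace-clustering parameters
#'
#' `similarity_threshold` is the maximum dissimilarity tolerated inside a
#' cluster (0.15 means members of one cluster differ by at most 15% under
#' complete linkage). `outlier_fraction` sets the minimum viable cluster size
#' as `ceiling(outlier_fraction * n)`; smaller clusters are pooled into a
#' single outlier group.
#'
#' @param similarity_threshold dissimilarity cut, in (0, 1]; default 0.15.
#' @param outlier_fraction minimum cluster-size fraction, in (0, 1);
#'   default 0.03.
#' @param linkage agglomeration rule; `"complete"` (default) guarantees the
#'   within-cluster dissimilarity bound, `"average"` is available as a looser
#'   alternative.
#' @return object of class `clustering_config`.
#' @export
clustering_config <- function(similarity_threshold = 0.15,
                              outlier_fraction = 0.03,
                              linkage = c("complete", "average")) {
  linkage <- match.arg(linkage)
  if (!is.numeric(similarity_threshold) || length(similarity_threshold) != 1 ||
      similarity_threshold <= 0 || similarity_threshold > 1) {
    stop("similarity_threshold must be a single number in (0, 1]")
  }
  if (!is.numeric(outlier_fraction) || length(outlier_fraction) != 1 ||
      outlier_fraction <= 0 || outlier_fraction >= 1) {
    stop("outlier_fraction must be a single number in (0, 1)")
  }
  structure(list(similarity_threshold = similarity_threshold,
                 outlier_fraction = outlier_fraction, linkage = linkage),
            class = "clustering_config")
}

#' Normalised edit distance between two discipline sequences
#'
#' Levenshtein distance divided by the longer sequence length, so the result
#' lies in \[0, 1\], is symmetric, and is 0 iff the sequences are identical.
#' This is the care-trajectory dissimilarity used for trace clustering; it is
#' deliberately pluggable (see [cluster_traces()]) so other sequence
#' dissimilarities can be swapped in.
#'
#' @param seq_a,seq_b non-empty character vectors over `c("P","N","D")` (or
#'   already-collapsed single strings).
#' @return dissimilarity in \[0, 1\].
#' @export
trace_distance <- function(seq_a, seq_b) {
  a <- paste(seq_a, collapse = "")
  b <- paste(seq_b, collapse = "")
  if (nchar(a) == 0 || nchar(b) == 0) stop("empty discipline sequence")
  as.numeric(adist(a, b)) / max(nchar(a), nchar(b))
}

#' Pairwise trace-distance matrix of a discipline log
#'
#' @param log a `discipline_log`.
#' @return symmetric matrix of normalised edit distances, rows/columns ordered
#'   by patient id.
#' @export
trace_distance_matrix <- function(log) {
  stopifnot(inherits(log, "discipline_log"))
  ids <- sort(names(log$sequences))
  strs <- vapply(log$sequences[ids], paste, "", collapse = "")
  if (any(nchar(strs) == 0)) stop("empty discipline sequence")
  d <- adist(strs) / outer(nchar(strs), nchar(strs), pmax)
  dimnames(d) <- list(ids, ids)
  d
}

#' Group patients by care-trajectory similarity
#'
#' Agglomerative clustering on the normalised edit distance between
#' discipline sequences, cut at `similarity_threshold`. Clusters smaller than
#' `ceiling(outlier_fraction * n)` are merged into a single outlier group.
#' The result is deterministic: patients are processed in lexicographic id
#' order and non-outlier clusters are numbered by decreasing size (ties by
#' smallest member id).
#'
#' @param log a `discipline_log` with at least 2 patients (a single-patient
#'   log yields one cluster with a warning).
#' @param config a [clustering_config()].
#' @param distance_matrix optional precomputed dissimilarity matrix (rows and
#'   columns named by patient id); defaults to [trace_distance_matrix()].
#' @return object of class `trace_clusters`: data frame with columns
#'   `patient_id`, `cluster_id` (integer, `NA` for outliers) and `is_outlier`.
#' @export
cluster_traces <- function(log, config = clustering_config(),
                           distance_matrix = NULL) {
  stopifnot(inherits(log, "discipline_log"), inherits(config, "clustering_config"))
  ids <- sort(names(log$sequences))
  n <- length(ids)
  if (n == 0) stop("empty discipline log")
  if (n == 1) {
    warning("fewer than 2 patients; returning a single cluster")
    out <- data.frame(patient_id = ids, cluster_id = 1L, is_outlier = FALSE)
    return(structure(out, class = c("trace_clusters", "data.frame"),
                     config = config))
  }
  d <- distance_matrix %||% trace_distance_matrix(log)
  d <- d[ids, ids]
  hc <- hclust(as.dist(d), method = config$linkage)
  raw <- cutree(hc, h = config$similarity_threshold)
  min_size <- ceiling(config$outlier_fraction * n)
  sizes <- table(raw)
  small <- as.integer(names(sizes)[sizes < min_size])
  is_outlier <- raw %in% small
  cluster_id <- rep(NA_integer_, n)
  kept <- setdiff(unique(raw), small)
  if (length(kept)) {
    ord <- order(-as.integer(sizes[as.character(kept)]),
                 vapply(kept, function(k) min(ids[raw == k]), ""))
    for (j in seq_along(ord)) cluster_id[raw == kept[ord[j]]] <- j
  }
  out <- data.frame(patient_id = ids, cluster_id = cluster_id,
                    is_outlier = is_outlier)
  structure(out, class = c("trace_clusters", "data.frame"), config = config)
}

#' @export
print.trace_clusters <- function(x, ...) {
  k <- length(unique(x$cluster_id[!x$is_outlier]))
  cat("Trace clustering:", nrow(x), "patients,", k, "cluster(s),",
      sum(x$is_outlier), "outlier(s)\n")
  invisible(x)
}

#' Per-cluster collaborative networks and indices
#'
#' Builds a [collab_network][build_network] and its [network_metrics()] for
#' every cluster; the outlier group (if non-empty) gets a network too, flagged
#' `is_outlier`.
#'
#' @param clusters a `trace_clusters` object.
#' @param log the `discipline_log` that was clustered.
#' @return named list (`"cluster_1"`, ..., `"outliers"`) of lists with
#'   elements `network`, `metrics`, `members`, `is_outlier`.
#' @export
cluster_networks <- function(clusters, log) {
  stopifnot(inherits(clusters, "trace_clusters"), inherits(log, "discipline_log"))
  if (!setequal(clusters$patient_id, names(log$sequences))) {
    stop("clusters do not partition the log's patients")
  }
  out <- list()
  ks <- sort(unique(clusters$cluster_id[!clusters$is_outlier]))
  groups <- lapply(ks, function(k) clusters$patient_id[!clusters$is_outlier &
                                                       clusters$cluster_id == k])
  names(groups) <- paste0("cluster_", ks)
  if (any(clusters$is_outlier)) {
    groups$outliers <- clusters$patient_id[clusters$is_outlier]
  }
  for (nm in names(groups)) {
    sub <- new_discipline_log(log$sequences[groups[[nm]]], log$tie_break)
    net <- build_network(sub)
    out[[nm]] <- list(network = net, metrics = network_metrics(net),
                      members = groups[[nm]],
                      is_outlier = identical(nm, "outliers"))
  }
  out
}
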