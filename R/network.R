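#' Construct a discipline log from per-patient sequences
#'
#' A discipline log maps each patient to the time-ordered sequence of
#' disciplines (physician `P`, nurse `N`, dietitian `D`) that attended their
#' cardiovascular periodic appointments (CVPAs).
#'
#' @param sequences named list of non-empty character vectors over
#'   `c("P", "N", "D")`; names are patient ids.
#' @param tie_break discipline order used to resolve same-day visits.
#' @return object of class `discipline_log`.
#' @export
new_discipline_log <- function(sequences, tie_break = DISCIPLINES) {
  stopifnot(is.list(sequences))
  if (length(sequences) && is.null(names(sequences))) {
    stop("sequences must be named by patient id")
  }
  for (id in names(sequences)) {
    s <- sequences[[id]]
    if (!length(s)) stop("empty discipline sequence for patient ", id)
    if (!all(s %in% DISCIPLINES)) {
      stop("sequence for patient ", id, " contains disciplines outside {P, N, D}")
    }
  }
  structure(list(sequences = sequences, alphabet = DISCIPLINES,
                 tie_break = tie_break),
            class = "discipline_log")
}

#' Build the discipline log of a cohort
#'
#' Restricts each patient's CVPA encounters to their study window
#' (`t0 <= date <= t_end`), orders them by date (same-day ties broken by the
#' `tie_break` discipline order), deduplicates repeated (date, discipline)
#' rows, and emits one sequence per patient. Patients with no in-window CVPA
#' are dropped with a warning.
#'
#' @param encounters data frame with columns `patient_id`, `date`,
#'   `discipline`.
#' @param windows study-window data frame from [run_funnel()] /
#'   [define_study_windows()].
#' @param tie_break discipline order for same-day ties (default P, N, D).
#' @return a `discipline_log`.
#' @export
build_discipline_log <- function(encounters, windows, tie_break = DISCIPLINES) {
  stopifnot(is.data.frame(encounters), is.data.frame(windows))
  if (!setequal(tie_break, DISCIPLINES)) {
    stop("tie_break must be a permutation of P, N, D")
  }
  enc <- encounters
  enc$patient_id <- as.character(enc$patient_id)
  enc$date <- as.Date(enc$date)
  if (!all(enc$discipline %in% DISCIPLINES)) {
    stop("encounters contain disciplines outside {P, N, D}; ",
         "use read_encounters() to normalise raw extracts")
  }
  sequences <- list()
  empty <- character(0)
  for (i in seq_len(nrow(windows))) {
    id <- windows$patient_id[i]
    sub <- enc[enc$patient_id == id &
               enc$date >= windows$t0[i] & enc$date <= windows$t_end[i], ,
               drop = FALSE]
    sub <- sub[!duplicated(sub[c("date", "discipline")]), , drop = FALSE]
    if (nrow(sub) == 0) {
      empty <- c(empty, id)
      next
    }
    ord <- order(sub$date, match(sub$discipline, tie_break))
    sequences[[id]] <- sub$discipline[ord]
  }
  if (length(empty)) {
    warning("patient(s) with no in-window CVPA excluded from the log: ",
            paste(empty, collapse = ", "))
  }
  if (!length(sequences)) {
    stop("no in-window CVPAs; cannot build a discipline log")
  }
  new_discipline_log(sequences, tie_break)
}

#' @export
print.discipline_log <- function(x, ...) {
  cat("Discipline log:", length(x$sequences), "patients,",
      sum(lengths(x$sequences)), "CVPAs\n")
  invisible(x)
}

#' Build the collaborative network of a discipline log
#'
#' The collaborative network is a directed multigraph over the disciplines.
#' Each consecutive pair (a, b) in a patient's sequence contributes one arc
#' a -> b (self-loops allowed); a patient's final CVPA emits no arc. Node
#' counts tally the CVPAs attended by each discipline, so the arc total always
#' equals the CVPA total minus the number of patients.
#'
#' @param log a `discipline_log`.
#' @return object of class `collab_network` with elements `arc_counts`
#'   (3 x 3 matrix, rows = referring discipline), `node_counts` (named CVPA
#'   counts) and `n_patients`.
#' @export
build_network <- function(log) {
  stopifnot(inherits(log, "discipline_log"))
  if (!length(log$sequences)) stop("cannot build a network from an empty log")
  arcs <- matrix(0, 3, 3, dimnames = list(DISCIPLINES, DISCIPLINES))
  nodes <- setNames(numeric(3), DISCIPLINES)
  for (s in log$sequences) {
    tab <- table(factor(s, levels = DISCIPLINES))
    nodes <- nodes + as.numeric(tab)
    if (length(s) > 1) {
      from <- s[-length(s)]
      to <- s[-1]
      pair <- table(factor(from, levels = DISCIPLINES),
                    factor(to, levels = DISCIPLINES))
      arcs <- arcs + unclass(pair)
    }
  }
  stopifnot(sum(arcs) == sum(nodes) - length(log$sequences))
  structure(list(arc_counts = arcs, node_counts = nodes,
                 n_patients = length(log$sequences)),
            class = "collab_network")
}

#' @export
print.collab_network <- function(x, ...) {
  cat("Collaborative network:", sum(x$node_counts), "CVPAs,",
      sum(x$arc_counts), "referral arcs,", x$n_patients, "patients\n")
  cat("CVPAs per discipline:\n")
  print(x$node_counts)
  cat("Arc counts (row = referring discipline):\n")
  print(x$arc_counts)
  invisible(x)
}

#' Participation index
#'
#' Percentage of all CVPAs performed by each discipline.
#'
#' @param network a `collab_network`.
#' @param discipline optional single discipline; if omitted the full named
#'   vector is returned.
#' @return percent value(s) in \[0, 100\]; the vector sums to 100.
#' @export
participation_index <- function(network, discipline = NULL) {
  stopifnot(inherits(network, "collab_network"))
  total <- sum(network$node_counts)
  if (total == 0) stop("network has no CVPAs")
  idx <- 100 * network$node_counts / total
  if (is.null(discipline)) idx else idx[[discipline]]
}

#' Self-referral index
#'
#' Percentage of a discipline's outgoing referrals that return to the same
#' discipline. Undefined (returned as `NA`) for a discipline with no outgoing
#' arcs; this is a distinguished "no referrals" value, never 0.
#'
#' @inheritParams participation_index
#' @return percent value(s); `NA` where the discipline makes no referrals.
#' @export
self_referral_index <- function(network, discipline = NULL) {
  stopifnot(inherits(network, "collab_network"))
  out <- rowSums(network$arc_counts)
  idx <- ifelse(out > 0, 100 * diag(network$arc_counts) / out, NA_real_)
  names(idx) <- DISCIPLINES
  if (is.null(discipline)) idx else idx[[discipline]]
}

#' Referral index
#'
#' Percentage of `from`'s outgoing referrals directed to a different
#' discipline `to`. Undefined (`NA`) when `from` makes no referrals.
#'
#' @param network a `collab_network`.
#' @param from,to distinct disciplines; if both omitted the full 3 x 3
#'   outgoing-share matrix is returned (diagonal = self-referral).
#' @return percent value or matrix.
#' @export
referral_index <- function(network, from = NULL, to = NULL) {
  stopifnot(inherits(network, "collab_network"))
  out <- rowSums(network$arc_counts)
  mat <- 100 * sweep(network$arc_counts, 1, out, "/")
  mat[out == 0, ] <- NA_real_
  if (is.null(from) && is.null(to)) return(mat)
  if (identical(from, to)) stop("use self_referral_index() for from == to")
  mat[from, to]
}

#' All three collaboration indices of a network
#'
#' @param network a `collab_network`.
#' @return object of class `network_metrics`: `participation` (named percent
#'   vector), `self_referral` (named, `NA` where undefined), `referral`
#'   (3 x 3 outgoing-share matrix), `present` (disciplines with at least one
#'   CVPA), `arc_counts` and `total_cvpas`.
#' @export
network_metrics <- function(network) {
  stopifnot(inherits(network, "collab_network"))
  part <- participation_index(network)
  structure(list(
    participation = part,
    self_referral = self_referral_index(network),
    referral = referral_index(network),
    present = DISCIPLINES[part > 0],
    arc_counts = network$arc_counts,
    total_cvpas = sum(network$node_counts)
  ), class = "network_metrics")
}

#' @export
print.network_metrics <- function(x, ...) {
  cat("Collaboration indices (percent, rounded):\n")
  cat("  participation:", paste(sprintf("%s %d", DISCIPLINES,
                                        round(x$participation)), collapse = ", "), "\n")
  sr <- ifelse(is.na(x$self_referral), "-", as.character(round(x$self_referral)))
  cat("  self-referral:", paste(sprintf("%s %s", DISCIPLINES, sr), collapse = ", "), "\n")
  invisible(x)
}

#' Convert a collaborative network to an igraph graph
#'
#' Nodes carry CVPA counts and participation percentages; arcs carry counts
#' and outgoing-share percentages.
#'
#' @param network a `collab_network`.
#' @return an igraph directed graph (self-loops retained).
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "collab_network"))
  g <- igraph::graph_from_adjacency_matrix(network$arc_counts, mode = "directed",
                                           weighted = TRUE, diag = TRUE)
  igraph::V(g)$cvpas <- as.numeric(network$node_counts[igraph::V(g)$name])
  igraph::V(g)$participation <- as.numeric(participation_index(network)[igraph::V(g)$name])
  ref <- referral_index(network)
  if (igraph::ecount(g) > 0) {
    ends <- igraph::ends(g, igraph::E(g))
    igraph::E(g)$share <- ref[cbind(ends[, 1], ends[, 2])]
  }
  g
}

#' Export a collaborative network to GraphML or DOT
#'
#' @param network a `collab_network`.
#' @param file output path.
#' @param format `"graphml"` or `"dot"`.
#' @return `file`, invisibly.
#' @export
export_network <- function(network, file, format = c("graphml", "dot")) {
  format <- match.arg(format)
  igraph::write_graph(as_igraph(network), file, format = format)
  invisible(file)
}
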