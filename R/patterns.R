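#' Thresholds of the collaboration-pattern decision rules
#'
#' All classification decisions flow through these thresholds; the classifier
#' body contains no literal numbers. Defaults are distilled from the index
#' values that separate the reference clusters: a leading discipline exceeds
#' 65% participation, a supporting discipline refers over 70% of its CVPAs to
#' the leader, equitable two-discipline participation sits in the 40--60%
#' band with cross-referral majorities over 60%, three-discipline equitable
#' participation peaks at 40% (45 leaves margin below the 51--54% centred
#' clusters), a dominant physician exceeds 70% participation with over 65%
#' self-referral while the most minor discipline stays at or below 5%, and
#' "almost no nurse--dietitian interaction" is operationalised as their mutual
#' referrals making up less than 10% of their combined outgoing arcs.
#'
#' @param leader_participation_min two-discipline leader participation floor.
#' @param shared_band two-element percent interval for equitable
#'   two-discipline participation.
#' @param participatory_max_participation ceiling on the maximum participation
#'   of an equitable three-discipline cluster.
#' @param dominant_participation_min,dominant_self_referral_min physician
#'   dominance floors for the self-referred leader pattern.
#' @param minor_participation_max ceiling on the most minor discipline's
#'   participation in the self-referred leader pattern.
#' @param cross_referral_majority floor on both cross-referral indices of a
#'   shared cluster.
#' @param support_referral_min floor on the supporting discipline's referrals
#'   to the leader in a tacit-leader cluster.
#' @param nd_interaction_min nurse--dietitian interaction share separating
#'   equitably from hierarchically centred clusters.
#' @return object of class `pattern_thresholds`.
#' @export
pattern_thresholds <- function(leader_participation_min = 65,
                               shared_band = c(40, 60),
                               participatory_max_participation = 45,
                               dominant_participation_min = 70,
                               dominant_self_referral_min = 65,
                               minor_participation_max = 5,
                               cross_referral_majority = 60,
                               support_referral_min = 70,
                               nd_interaction_min = 10) {
  th <- list(leader_participation_min = leader_participation_min,
             shared_band = shared_band,
             participatory_max_participation = participatory_max_participation,
             dominant_participation_min = dominant_participation_min,
             dominant_self_referral_min = dominant_self_referral_min,
             minor_participation_max = minor_participation_max,
             cross_referral_majority = cross_referral_majority,
             support_referral_min = support_referral_min,
             nd_interaction_min = nd_interaction_min)
  vals <- unlist(th)
  if (any(vals < 0 | vals > 100)) stop("pattern thresholds must lie in [0, 100]")
  if (length(shared_band) != 2 || shared_band[1] >= shared_band[2]) {
    stop("shared_band must be an increasing percent interval")
  }
  structure(th, class = "pattern_thresholds")
}

# Share of nurse- and dietitian-outgoing referrals exchanged between nurse
# and dietitian (their mutual integration, in percent).
nd_interaction <- function(metrics) {
  arcs <- metrics$arc_counts
  denom <- sum(arcs["N", ]) + sum(arcs["D", ])
  if (denom == 0) return(0)
  100 * (arcs["N", "D"] + arcs["D", "N"]) / denom
}

#' Classify a cluster's collaboration pattern
#'
#' Decision tree over the cluster's collaboration indices, most specific
#' rules first:
#'
#' 1. one present discipline: *self-contained*;
#' 2. two disciplines: *tacit leader* when one dominates participation and the
#'    other refers the bulk of its CVPAs to it; *shared* when participation is
#'    balanced and both disciplines mostly refer across; otherwise
#'    *unclassified*;
#' 3. three disciplines: *self-referred leader* when the physician dominates
#'    participation and self-referral while the most minor discipline is
#'    marginal; *participatory* when no discipline's participation exceeds the
#'    equitability ceiling; otherwise, with the physician leading
#'    participation, *equitably centered* when nurse and dietitian interact
#'    and *hierarchically centered* when they do not; anything else is
#'    *unclassified*.
#'
#' @param metrics a [network_metrics()] object (or a `collab_network`).
#' @param thresholds a [pattern_thresholds()] object.
#' @return object of class `pattern_label`: list with `label` and `leader`
#'   (a discipline for leader-bearing patterns, otherwise `NA`).
#' @export
classify_pattern <- function(metrics, thresholds = pattern_thresholds()) {
  if (inherits(metrics, "collab_network")) metrics <- network_metrics(metrics)
  stopifnot(inherits(metrics, "network_metrics"),
            inherits(thresholds, "pattern_thresholds"))
  if (metrics$total_cvpas == 0) stop("metrics describe a network with no CVPAs")
  part <- metrics$participation
  present <- metrics$present
  ref <- metrics$referral
  label <- "unclassified"
  leader <- NA_character_

  if (length(present) == 1) {
    label <- "self-contained"
    leader <- present
  } else if (length(present) == 2) {
    lead <- present[which.max(part[present])]
    other <- setdiff(present, lead)
    to_leader <- ref[other, lead]
    cross_ab <- ref[present[1], present[2]]
    cross_ba <- ref[present[2], present[1]]
    if (part[[lead]] >= thresholds$leader_participation_min &&
        isTRUE(to_leader >= thresholds$support_referral_min)) {
      label <- "tacit leader"
      leader <- lead
    } else if (all(part[present] >= thresholds$shared_band[1] &
                   part[present] <= thresholds$shared_band[2]) &&
               isTRUE(cross_ab >= thresholds$cross_referral_majority) &&
               isTRUE(cross_ba >= thresholds$cross_referral_majority)) {
      label <- "shared"
    }
  } else {
    selfr <- metrics$self_referral
    if (part[["P"]] >= thresholds$dominant_participation_min &&
        isTRUE(selfr[["P"]] >= thresholds$dominant_self_referral_min) &&
        min(part) <= thresholds$minor_participation_max) {
      label <- "self-referred leader"
      leader <- "P"
    } else if (max(part) <= thresholds$participatory_max_participation) {
      label <- "participatory"
    } else if (names(part)[which.max(part)] == "P") {
      label <- if (nd_interaction(metrics) >= thresholds$nd_interaction_min) {
        "equitably centered"
      } else {
        "hierarchically centered"
      }
      leader <- "P"
    }
  }
  structure(list(label = label, leader = leader), class = "pattern_label")
}

#' @export
print.pattern_label <- function(x, ...) {
  cat(x$label)
  if (!is.na(x$leader)) cat(" (leader:", x$leader, ")")
  cat("\n")
  invisible(x)
}

#' Classify every non-outlier cluster of a pipeline run
#'
#' @param networks output of [cluster_networks()].
#' @param thresholds a [pattern_thresholds()] object.
#' @return named list of `pattern_label`s, one per non-outlier cluster.
#' @export
classify_clusters <- function(networks, thresholds = pattern_thresholds()) {
  keep <- names(networks)[!vapply(networks, `[[`, logical(1), "is_outlier")]
  labels <- lapply(networks[keep], function(cl) {
    classify_pattern(cl$metrics, thresholds)
  })
  labels
}

#' Propagate cluster labels to patients
#'
#' Every member of a labelled cluster inherits the cluster's pattern label;
#' members of the outlier group are labelled `"outlier"`.
#'
#' @param clusters a `trace_clusters` object.
#' @param cluster_labels named list of `pattern_label`s as returned by
#'   [classify_clusters()]; names are `"cluster_<id>"`.
#' @return data frame with columns `patient_id`, `pattern`, `leader`.
#' @export
assign_patient_patterns <- function(clusters, cluster_labels) {
  stopifnot(inherits(clusters, "trace_clusters"))
  ks <- sort(unique(clusters$cluster_id[!clusters$is_outlier]))
  missing <- setdiff(paste0("cluster_", ks), names(cluster_labels))
  if (length(missing)) {
    stop("unlabelled non-outlier cluster(s): ", paste(missing, collapse = ", "))
  }
  pattern <- character(nrow(clusters))
  leader <- rep(NA_character_, nrow(clusters))
  pattern[clusters$is_outlier] <- "outlier"
  for (k in ks) {
    lab <- cluster_labels[[paste0("cluster_", k)]]
    sel <- !clusters$is_outlier & clusters$cluster_id == k
    pattern[sel] <- lab$label
    leader[sel] <- lab$leader
  }
  data.frame(patient_id = clusters$patient_id, pattern = pattern,
             leader = leader)
}
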