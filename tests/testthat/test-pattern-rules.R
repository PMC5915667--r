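test_that("single-discipline clusters are self-contained", {
  net <- fake_network(c(P = 10), data.frame(from = "P", to = "P", n = 8))
  lab <- classify_pattern(net)
  expect_equal(lab$label, "self-contained")
  expect_equal(lab$leader, "P")
  nurse_only <- fake_network(c(N = 6), data.frame(from = "N", to = "N", n = 5))
  expect_equal(classify_pattern(nurse_only)$label, "self-contained")
})

test_that("two-discipline clusters split into tacit leader, shared, unclassified", {
  # physician leads with 68% participation, self-refers about half, and the
  # nurse refers three quarters of her CVPAs back to the physician
  tacit <- fake_network(
    c(P = 68, N = 32),
    data.frame(from = c("P", "P", "N", "N"), to = c("P", "N", "P", "N"),
               n = c(26, 24, 30, 10))
  )
  lab <- classify_pattern(tacit)
  expect_equal(lab$label, "tacit leader")
  expect_equal(lab$leader, "P")

  # balanced participation (59/41) with cross-referral majorities
  shared <- fake_network(
    c(P = 59, N = 41),
    data.frame(from = c("P", "P", "N", "N"), to = c("N", "P", "P", "N"),
               n = c(30, 18, 25, 10))
  )
  expect_equal(classify_pattern(shared)$label, "shared")

  # dominant participation without a supporting referral majority
  odd <- fake_network(
    c(P = 70, N = 30),
    data.frame(from = c("P", "N", "N"), to = c("P", "N", "P"),
               n = c(40, 15, 10))
  )
  expect_equal(classify_pattern(odd)$label, "unclassified")
})

test_that("three-discipline clusters follow the most-specific-first tree", {
  # physician dominates participation and self-referral; nurse marginal
  srl <- fake_network(
    c(P = 76, N = 4, D = 20),
    data.frame(from = c("P", "P", "P", "D", "N"), to = c("P", "D", "N", "P", "P"),
               n = c(49, 18, 3, 18, 3))
  )
  lab <- classify_pattern(srl)
  expect_equal(lab$label, "self-referred leader")
  expect_equal(lab$leader, "P")

  # equitable three-way participation, max 40%
  part <- fake_network(
    c(P = 40, N = 35, D = 25),
    data.frame(from = c("P", "P", "N", "N", "D", "D"),
               to = c("N", "D", "P", "D", "P", "N"),
               n = c(20, 15, 20, 10, 15, 8))
  )
  expect_equal(classify_pattern(part)$label, "participatory")

  # physician-centred with nurse-dietitian interaction
  equit <- fake_network(
    c(P = 52, N = 24, D = 24),
    data.frame(from = c("P", "P", "P", "N", "N", "D", "D"),
               to = c("P", "N", "D", "P", "D", "P", "N"),
               n = c(24, 12, 12, 14, 8, 14, 8))
  )
  lab <- classify_pattern(equit)
  expect_equal(lab$label, "equitably centered")
  expect_equal(lab$leader, "P")

  # physician-centred, nurse and dietitian never exchange referrals
  hier <- fake_network(
    c(P = 54, N = 30, D = 16),
    data.frame(from = c("P", "P", "P", "N", "N", "D"),
               to = c("P", "N", "D", "P", "N", "P"),
               n = c(25, 16, 8, 14, 14, 14))
  )
  lab <- classify_pattern(hier)
  expect_equal(lab$label, "hierarchically centered")
  expect_equal(lab$leader, "P")

  # nurse-led three-discipline clusters fall outside the seven patterns
  odd <- fake_network(
    c(P = 20, N = 60, D = 20),
    data.frame(from = c("N", "N"), to = c("N", "P"), n = c(30, 20))
  )
  expect_equal(classify_pattern(odd)$label, "unclassified")
})

test_that("thresholds are the only tuning surface", {
  borderline <- fake_network(
    c(P = 60, N = 40),
    data.frame(from = c("P", "P", "N"), to = c("P", "N", "P"), n = c(20, 20, 30))
  )
  default_lab <- classify_pattern(borderline)
  lowered <- classify_pattern(borderline,
                              pattern_thresholds(leader_participation_min = 55))
  expect_equal(default_lab$label, "unclassified")
  expect_equal(lowered$label, "tacit leader")
  expect_error(pattern_thresholds(leader_participation_min = 120), "\\[0, 100\\]")
  expect_error(classify_pattern(fake_network(c(P = 0), NULL)), "no CVPAs")
})

test_that("all seven archetypes classify to their planted pattern", {
  set.seed(19)
  arch <- pattern_archetypes("reference")
  gen <- function(a, n_visits) {
    s <- character(n_visits)
    s[1] <- sample(c("P", "N", "D"), 1, prob = a$init)
    for (i in seq_len(n_visits - 1)) {
      s[i + 1] <- sample(c("P", "N", "D"), 1, prob = a$transition[s[i], ])
    }
    s
  }
  for (pattern in names(arch)) {
    seqs <- lapply(1:150, function(i) gen(arch[[pattern]], 10))
    names(seqs) <- sprintf("h%03d", 1:150)
    net <- build_network(new_discipline_log(seqs))
    lab <- classify_pattern(net)
    expect_equal(lab$label, pattern,
                 label = paste("pooled archetype network for", pattern))
  }
})

test_that("cluster labels propagate to patients, outliers stay apart", {
  clusters <- structure(
    data.frame(patient_id = c("a", "b", "c", "d", "e"),
               cluster_id = c(1L, 1L, 2L, NA, NA),
               is_outlier = c(FALSE, FALSE, FALSE, TRUE, TRUE)),
    class = c("trace_clusters", "data.frame")
  )
  labels <- list(
    cluster_1 = structure(list(label = "shared", leader = NA_character_),
                          class = "pattern_label"),
    cluster_2 = structure(list(label = "shared", leader = NA_character_),
                          class = "pattern_label")
  )
  res <- assign_patient_patterns(clusters, labels)
  expect_equal(res$pattern, c("shared", "shared", "shared", "outlier", "outlier"))
  # two clusters with the same label pool into one pattern
  expect_equal(sum(res$pattern == "shared"), 3)
  expect_error(assign_patient_patterns(clusters, labels["cluster_1"]),
               "cluster_2")
})
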