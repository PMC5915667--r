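# Independent oracles used to cross-check the implementation. These are
# deliberately written as plain, slow reference algorithms.

# Textbook dynamic-programming Levenshtein distance over two vectors.
oracle_levenshtein <- function(a, b) {
  n <- length(a)
  m <- length(b)
  d <- matrix(0L, n + 1, m + 1)
  d[, 1] <- 0:n
  d[1, ] <- 0:m
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      cost <- if (a[i] == b[j]) 0L else 1L
      d[i + 1, j + 1] <- min(d[i, j + 1] + 1L, d[i + 1, j] + 1L, d[i, j] + cost)
    }
  }
  d[n + 1, m + 1]
}

# Brute-force pair enumeration of a discipline log's network and indices.
oracle_network_indices <- function(sequences) {
  nodes <- c(P = 0, N = 0, D = 0)
  arcs <- matrix(0, 3, 3, dimnames = list(c("P", "N", "D"), c("P", "N", "D")))
  for (s in sequences) {
    for (d in s) nodes[d] <- nodes[d] + 1
    if (length(s) > 1) {
      for (i in 1:(length(s) - 1)) arcs[s[i], s[i + 1]] <- arcs[s[i], s[i + 1]] + 1
    }
  }
  participation <- 100 * nodes / sum(nodes)
  self_referral <- c(P = NA_real_, N = NA_real_, D = NA_real_)
  referral <- matrix(NA_real_, 3, 3, dimnames = dimnames(arcs))
  for (d in c("P", "N", "D")) {
    out <- sum(arcs[d, ])
    if (out > 0) {
      self_referral[d] <- 100 * arcs[d, d] / out
      for (e in c("P", "N", "D")) referral[d, e] <- 100 * arcs[d, e] / out
    }
  }
  list(nodes = nodes, arcs = arcs, participation = participation,
       self_referral = self_referral, referral = referral)
}

# Two-sided Fisher exact p-value by exhaustive enumeration of the
# hypergeometric distribution over tables with the observed margins,
# using binomial coefficients directly.
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b
  r2 <- c + d
  c1 <- a + c
  n <- r1 + r2
  xs <- max(0, c1 - r2):min(r1, c1)
  logp <- lchoose(r1, xs) + lchoose(r2, c1 - xs) - lchoose(n, c1)
  p <- exp(logp)
  sum(p[p <= p[xs == a] * (1 + 1e-7)])
}

# Adjusted Rand index between two label vectors.
oracle_ari <- function(x, y) {
  tab <- table(x, y)
  sum_ij <- sum(choose(tab, 2))
  sum_i <- sum(choose(rowSums(tab), 2))
  sum_j <- sum(choose(colSums(tab), 2))
  total <- choose(sum(tab), 2)
  expected <- sum_i * sum_j / total
  maxidx <- (sum_i + sum_j) / 2
  if (maxidx == expected) return(1)
  (sum_ij - expected) / (maxidx - expected)
}

random_sequence <- function(max_len = 8, min_len = 1) {
  sample(c("P", "N", "D"), sample(min_len:max_len, 1), replace = TRUE)
}

random_log <- function(max_patients = 6, max_len = 8) {
  n <- sample(1:max_patients, 1)
  seqs <- lapply(seq_len(n), function(i) random_sequence(max_len))
  names(seqs) <- sprintf("h%02d", seq_len(n))
  new_discipline_log(seqs)
}

# Collaborative network stub with prescribed arc and node counts, for unit
# tests of the pattern classifier.
fake_network <- function(nodes, arcs) {
  node_counts <- c(P = 0, N = 0, D = 0)
  node_counts[names(nodes)] <- nodes
  arc_counts <- matrix(0, 3, 3, dimnames = list(c("P", "N", "D"), c("P", "N", "D")))
  if (!is.null(arcs)) {
    for (k in seq_len(nrow(arcs))) {
      arc_counts[arcs$from[k], arcs$to[k]] <- arcs$n[k]
    }
  }
  structure(list(arc_counts = arc_counts, node_counts = node_counts,
                 n_patients = max(1, sum(nodes) - sum(arc_counts))),
            class = "collab_network")
}

# Measurement table from per-patient (month, value) series; dates are day
# offsets from an arbitrary origin, rounded like real records.
measurements_from_months <- function(series, origin = as.Date("2014-01-01")) {
  rows <- lapply(names(series), function(id) {
    s <- series[[id]]
    data.frame(patient_id = id, date = origin + round(s$month * 30.44),
               value = s$value)
  })
  validate_measurements(do.call(rbind, rows))
}
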