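# Independent oracles used across the suite. All are deliberately naive
# (loops, textbook formulas, enumeration) and must stay independent of the
# package's implementation paths.

# Textbook Pearson correlation matrix via explicit sums.
oracle_pearson <- function(X) {
  n <- ncol(X); T <- nrow(X)
  R <- diag(1, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    x <- X[, i]; y <- X[, j]
    sxy <- sum(x * y) - T * mean(x) * mean(y)
    sxx <- sum(x^2) - T * mean(x)^2
    syy <- sum(y^2) - T * mean(y)^2
    R[i, j] <- R[j, i] <- sxy / sqrt(sxx * syy)
  }
  R
}

# Brute-force top-k selection of pairs by |r| (ties: lexicographic i, j).
oracle_topk_abs <- function(conn, k) {
  n <- nrow(conn)
  out <- NULL
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    out <- rbind(out, data.frame(i = i, j = j, r = conn[i, j]))
  out <- out[order(-abs(out$r), out$i, out$j), ]
  out[seq_len(k), , drop = FALSE]
}

# Per-node neighbor fields via explicit loops over the adjacency.
oracle_fields <- function(states, adj, pi_p, pi_n, strict = FALSE) {
  n <- length(states)
  phi_p <- phi_n <- integer(n)
  cmp <- if (strict) `>` else `>=`
  for (v in seq_len(n)) {
    pos <- which(adj[v, ] > 0)
    neg <- which(adj[v, ] < 0)
    ap <- if (length(pos)) mean(states[pos] == 2L) else 0
    an <- if (length(neg)) mean(states[neg] == 2L) else 0
    phi_p[v] <- as.integer(cmp(ap, pi_p))
    phi_n[v] <- as.integer(cmp(an, pi_n))
  }
  list(phi_s = as.integer(states == 1L), phi_p = phi_p, phi_n = phi_n)
}

# Exact one-step next-state distribution per node from the rule table.
# Returns an n x 3 matrix of probabilities over (S, E, R).
oracle_transition_dist <- function(states, adj, sop, nep, pi_p, pi_n) {
  f <- oracle_fields(states, adj, pi_p, pi_n)
  n <- length(states)
  P <- matrix(0, n, 3, dimnames = list(NULL, c("S", "E", "R")))
  for (v in seq_len(n)) {
    if (states[v] == 2L) {                       # E -> R
      P[v, "R"] <- 1
    } else if (states[v] == 3L) {                # R -> S w.p. nep
      P[v, "S"] <- nep; P[v, "R"] <- 1 - nep
    } else if (f$phi_p[v] == 1L && f$phi_n[v] == 0L) {   # forced on
      P[v, "E"] <- 1
    } else if (f$phi_p[v] == 0L && f$phi_n[v] == 1L) {   # held off
      P[v, "S"] <- 1
    } else {                                     # spontaneous
      P[v, "E"] <- sop; P[v, "S"] <- 1 - sop
    }
  }
  P
}

# Friedman statistic for tables without ties, by the closed form
# 12/(bk(k+1)) * sum_j R_j^2 - 3b(k+1).
oracle_friedman_noties <- function(x) {
  b <- nrow(x); k <- ncol(x)
  Rj <- colSums(t(apply(x, 1, rank)))
  12 / (b * k * (k + 1)) * sum(Rj^2) - 3 * b * (k + 1)
}

# Random symmetric correlation-like fixture matrix with distinct entries.
random_conn <- function(n, seed) {
  set.seed(seed)
  m <- matrix(stats::runif(n * n, -1, 1), n)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  diag(m) <- 1
  conn_matrix(m)
}

# Small hand-built signed network from an edge list (i, j, sign).
edges_network <- function(n, edges) {
  adj <- matrix(0L, n, n)
  for (e in edges) {
    adj[e[1], e[2]] <- as.integer(e[3])
    adj[e[2], e[1]] <- as.integer(e[3])
  }
  dimnames(adj) <- list(paste0("R", 1:n), paste0("R", 1:n))
  structure(adj, scheme = "manual", positive_cost = NA, negative_cost = NA,
            class = c("signed_network", "matrix", "array"))
}

# Small synthetic study used by several files (kept tiny for speed).
tiny_study <- function(seed = 5, n_regions = 30) {
  synthetic_study(fixture_spec(n_subjects = 8, n_timepoints = 100,
                               n_regions = n_regions, seed = seed))
}
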