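# Independent, loop-based oracles used to cross-check the package's
# vectorised implementations. Deliberately written in the plainest possible
# style and kept free of package internals.

# remove hypothesis at position `pos` from (w, G); explicit double loop
oracle_remove <- function(w, G, pos) {
  m <- length(w)
  keep <- setdiff(seq_len(m), pos)
  w2 <- numeric(length(keep))
  G2 <- matrix(0, length(keep), length(keep))
  for (a in seq_along(keep)) {
    j <- keep[a]
    w2[a] <- w[j] + w[pos] * G[pos, j]
    for (b in seq_along(keep)) {
      k <- keep[b]
      if (j == k) next
      d <- 1 - G[j, pos] * G[pos, j]
      G2[a, b] <- if (d > 1e-12) (G[j, k] + G[j, pos] * G[pos, k]) / d else 0
    }
  }
  list(w = w2, G = G2, labels = keep)
}

# weights w_J for subset `J` (integer positions), removing I \ J in the
# given order (a permutation of the complement; default as-is)
oracle_weights_for_subset <- function(graph, J, order = NULL) {
  labels <- seq_along(graph$w)
  w <- unname(graph$w)
  G <- unname(graph$G)
  out <- setdiff(labels, J)
  if (!is.null(order)) out <- out[order]
  for (l in out) {
    pos <- match(l, labels)
    r <- oracle_remove(w, G, pos)
    w <- r$w
    G <- r$G
    labels <- labels[r$labels]
  }
  full <- numeric(length(graph$w))
  full[labels] <- w
  full
}

# exhaustive closed weighted Bonferroni test straight from the definition
oracle_closure <- function(p, graph, alpha) {
  m <- length(graph$w)
  psi <- rep(TRUE, m)
  for (J in seq_len(2^m - 1)) {
    memb <- which(bitwAnd(bitwShiftR(J, 0:(m - 1)), 1L) == 1L)
    wJ <- oracle_weights_for_subset(graph, memb)
    if (!any(p[memb] <= wJ[memb] * alpha)) psi[memb] <- FALSE
  }
  psi
}

# one-sided z-test conditional error, written directly from the formula
oracle_pce <- function(z1, level, t) {
  if (level <= 0) return(0)
  if (level >= 1) return(1)
  1 - pnorm((qnorm(1 - level) - z1 * sqrt(t)) / sqrt(1 - t))
}

# gamma solving sum_j A(z1_j, w2_j * gamma, t) = B via stats::uniroot
oracle_gamma <- function(z1, w2, B, alpha, t) {
  pos <- which(w2 > 0)
  f <- function(g) {
    sum(vapply(pos, function(j) oracle_pce(z1[j], min(w2[j] * g, 1), t), 0)) - B
  }
  stats::uniroot(f, c(0, 1 / max(w2[pos])), tol = 1e-12)$root
}

# exhaustive adaptive closed test: per subset, B from the preplanned
# weights, eq8 fractions from the second-stage weights, strict comparison
oracle_agmtp <- function(z1, q, graph, graph2, alpha, t) {
  m <- length(graph$w)
  psi <- rep(TRUE, m)
  for (J in seq_len(2^m - 1)) {
    memb <- which(bitwAnd(bitwShiftR(J, 0:(m - 1)), 1L) == 1L)
    wJ <- oracle_weights_for_subset(graph, memb)
    B <- sum(vapply(
      memb,
      function(j) oracle_pce(z1[j], wJ[j] * alpha, t), 0
    ))
    if (B >= 1) next # rejected at interim
    w2J <- oracle_weights_for_subset(graph2, memb)
    rejJ <- FALSE
    if (any(w2J[memb] > 0) && B > 0) {
      g <- oracle_gamma(z1, w2J, B, alpha, t)
      for (j in memb[w2J[memb] > 0]) {
        v <- oracle_pce(z1[j], min(w2J[j] * g, 1), t) / B
        if (q[j] < v * B) rejJ <- TRUE
      }
    }
    if (!rejJ) psi[memb] <- FALSE
  }
  psi
}

# random valid hypothesis graph
random_graph <- function(m, full_rows = FALSE) {
  w <- stats::runif(m)
  w <- w / sum(w) * stats::runif(1, 0.3, 1)
  G <- matrix(stats::runif(m * m), m, m)
  diag(G) <- 0
  rs <- rowSums(G)
  scale <- if (full_rows) 1 else stats::runif(m, 0.2, 1)
  G <- G / rs * scale
  diag(G) <- 0
  hyp_graph(w, G)
}

case_graph <- function() graph_two_arm_hierarchy()
case_plan <- function() stage_plan(0.025, n = 116, n1 = 58)
case_z1 <- function() c(1.66, 1.42, 1.90, 0.79)
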