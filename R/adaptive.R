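#' Adjusted second-stage level for an intersection hypothesis
#'
#' After an interim change of the weighting strategy, the conditional level
#' `B_J` (sum of partial conditional error rates of the preplanned tests) is
#' re-expressed on the scale of the new second-stage weights: `gamma_J`
#' solves
#' `sum_j A(z1[j], w2[j] * gamma, t) = B_J`
#' over the hypotheses with positive second-stage weight. The sum is
#' continuous and nondecreasing in `gamma` and reaches at least 1 at
#' `gamma = 1 / max(w2)` (where the largest local level is 1), so a bracketed
#' bisection on `[0, 1 / max(w2)]` always finds a solution for `B_J < 1`.
#' If the second-stage weights equal the preplanned weights, the solution is
#' `gamma_J = alpha`. For discontinuous conditional-error functions
#' (discrete test statistics) the bisection returns the largest bracketed
#' `gamma` with sum at most `B_J`.
#'
#' @param z1 First-stage z-scores (length m).
#' @param w2 Second-stage weight vector for the subset (length m,
#'   non-negative, zero outside J and for dropped hypotheses, sum at most 1).
#'   At least one entry must be positive.
#' @param B Sum of partial conditional error rates `B_J` in \[0, 1).
#' @param plan A [stage_plan()].
#' @param pce Conditional-error function `(z1, level, t)`; default
#'   [ztest_pce()].
#' @param tol Absolute tolerance on the sum; default 1e-10.
#' @return The adjusted level `gamma_J` (a nonnegative scalar, possibly
#'   larger than `alpha`).
#' @examples
#' plan <- stage_plan(0.025, n = 116, n1 = 58)
#' # weights unchanged: gamma equals alpha
#' solve_gamma(
#'   z1 = c(1.66, 1.42), w2 = c(1 / 2, 1 / 2),
#'   B = sum(ztest_pce(c(1.66, 1.42), 0.0125, 0.5)), plan = plan
#' )
#' @export
solve_gamma <- function(z1, w2, B, plan, pce = ztest_pce, tol = 1e-10) {
  stopifnot(inherits(plan, "stage_plan"))
  w2 <- ifelse(is.na(w2), 0, w2)
  if (all(w2 <= 0)) {
    stop("all second-stage weights are zero; gamma is undefined", call. = FALSE)
  }
  if (!is.numeric(B) || length(B) != 1 || is.na(B) || B < 0) {
    stop("`B` must be a single nonnegative number", call. = FALSE)
  }
  if (B >= 1) {
    stop("B >= 1: the intersection hypothesis is rejected at interim; no gamma needed",
      call. = FALSE
    )
  }
  pos <- which(w2 > 0)
  f <- function(gamma) {
    sum(pce(z1[pos], pmin(w2[pos] * gamma, 1), plan$t))
  }
  hi <- 1 / max(w2[pos])
  if (f(hi) < B - tol) {
    # only possible for conditional-error functions not reaching 1 at level 1
    return(hi)
  }
  lo <- 0
  for (iter in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) <= B) lo <- mid else hi <- mid
    if (hi - lo < tol * max(1, hi) && abs(f(lo) - B) < tol) break
  }
  lo
}

#' Conditional error allocation fractions
#'
#' Translates second-stage weights into fractions of the conditional level
#' `B_J` assigned to each hypothesis. Three strategies:
#' \describe{
#'   \item{`"eq8"` (default)}{`v[j] = A(z1[j], w2[j] * gamma_J, t) / B_J` with
#'     `gamma_J` from [solve_gamma()]; zero where `w2[j] = 0`. The fractions
#'     sum to 1 and reproduce the preplanned conditional levels when the
#'     weights are unchanged.}
#'   \item{`"equal_recycling"`}{`v[j] = (A[j] + sum of dropped A / #continued)
#'     / B_J` for continued j in J: each continued hypothesis keeps its own
#'     partial conditional error and receives an equal share of the dropped
#'     hypotheses' errors.}
#'   \item{`"direct"`}{`v = w2` as given. Valid (familywise error control
#'     holds for any fixed fractions summing to at most 1) but does not
#'     reproduce the preplanned conditional levels even for unchanged
#'     weights.}
#' }
#'
#' @inheritParams solve_gamma
#' @param A Vector of preplanned partial conditional errors `A[j, J]`
#'   (length m, zero outside J); required for `"equal_recycling"`.
#' @param continued Indices (or logical mask) of hypotheses carried to the
#'   second stage; required for `"equal_recycling"`.
#' @param strategy One of `"eq8"`, `"equal_recycling"`, `"direct"`.
#' @return Numeric vector `v` of length m with `v[j] = 0` outside J and for
#'   dropped hypotheses.
#' @export
allocation_fractions <- function(z1, w2, B, plan,
                                 strategy = c("eq8", "equal_recycling", "direct"),
                                 A = NULL, continued = NULL,
                                 pce = ztest_pce) {
  strategy <- match.arg(strategy)
  w2 <- ifelse(is.na(w2), 0, w2)
  m <- length(w2)
  if (strategy == "direct") {
    return(w2)
  }
  if (strategy == "equal_recycling") {
    if (is.null(A) || is.null(continued)) {
      stop("`A` and `continued` are required for equal_recycling", call. = FALSE)
    }
    return(equal_recycling_fractions(A, continued))
  }
  v <- numeric(m)
  if (B <= 0 || all(w2 <= 0)) {
    return(v)
  }
  gamma <- solve_gamma(z1, w2, B, plan, pce = pce)
  pos <- which(w2 > 0)
  v[pos] <- pce(z1[pos], pmin(w2[pos] * gamma, 1), plan$t) / B
  v
}

#' Equal recycling of dropped hypotheses' conditional errors
#'
#' Allocation fractions that give each continued hypothesis its own partial
#' conditional error plus an equal share of the errors of the dropped
#' hypotheses, all as a fraction of `B_J = sum(A)`:
#' `v[j] = (A[j] + sum(A[dropped]) / #continued) / B_J` for continued j with
#' `A[j]` defined (j in J), and 0 otherwise. The continued fractions sum
#' to 1, and `v[j] * B_J >= A[j]` with strict inequality whenever a dropped
#' hypothesis had positive weight.
#'
#' @param A Partial conditional errors `A[j, J]` for one subset (length m;
#'   `NA` allowed outside J and treated as absent).
#' @param continued Indices or logical mask of continued hypotheses.
#' @return Numeric vector `v` of length m.
#' @export
equal_recycling_fractions <- function(A, continued) {
  m <- length(A)
  if (is.logical(continued)) continued <- which(continued)
  in_J <- !is.na(A)
  A0 <- ifelse(in_J, A, 0)
  cont_J <- intersect(which(in_J), continued)
  if (length(cont_J) == 0) {
    stop("no continued hypothesis in the subset", call. = FALSE)
  }
  B <- sum(A0)
  if (B <= 0) {
    stop("B = 0: allocation fractions are undefined", call. = FALSE)
  }
  dropped_J <- setdiff(which(in_J), continued)
  share <- sum(A0[dropped_J]) / length(cont_J)
  v <- numeric(m)
  v[cont_J] <- (A0[cont_J] + share) / B
  v
}

#' Adapted weighted Bonferroni test of one intersection hypothesis
#'
#' Second-stage decision for H_J given the conditional level `B_J` and
#' allocation fractions `v`: if `B_J >= 1` the intersection hypothesis is
#' rejected already on the interim data; otherwise it is rejected iff some
#' second-stage p-value satisfies `q[j] < v[j] * B_J` (strict comparison; a
#' measure-zero difference from the non-strict preplanned rule for
#' continuous statistics).
#'
#' @param q Second-stage p-values (length m; `1` for hypotheses without
#'   second-stage data).
#' @param v Allocation fractions for the subset (length m).
#' @param B Conditional level `B_J` (may exceed 1).
#' @return `1L` (reject) or `0L`.
#' @export
adapted_intersection_decision <- function(q, v, B) {
  .check_pvalues(q, "q")
  v <- ifelse(is.na(v), 0, v)
  if (B >= 1) {
    return(1L)
  }
  as.integer(any(v > 0 & q < v * B))
}

#' Build an adapted two-stage design at the interim analysis
#'
#' Combines the interim information into the object needed for the final
#' analysis: the partial conditional error table of the preplanned graph, the
#' second-stage weights derived from the (possibly modified) second-stage
#' graph, and per-subset adjusted levels `gamma_J` and allocation fractions
#' `v[j, J]`. Hypotheses dropped at interim must carry zero node and edge
#' weights in `graph2`; they receive allocation fraction 0 in every subset.
#'
#' @param data A data frame with columns `hypothesis` and `z1`, or a numeric
#'   vector of first-stage z-scores in graph order.
#' @param graph Preplanned [hyp_graph()].
#' @param graph2 Second-stage strategy chosen at interim: a [hyp_graph()]
#'   with zero node and edge weights for dropped hypotheses, or a
#'   `subset_weights` table from [derive_weights()] (or edited from one) for
#'   strategies not expressible as a graph, e.g. zeroing the preplanned
#'   per-subset weights of dropped hypotheses. Defaults to `graph` (no
#'   change of strategy).
#' @param plan A [stage_plan()].
#' @param continued Labels or indices of hypotheses carried to the second
#'   stage; defaults to those with a positive node or incoming edge weight in
#'   `graph2`, i.e. all hypotheses when the strategy is unchanged.
#' @param strategy Allocation-fraction strategy, see
#'   [allocation_fractions()].
#' @param pce Conditional-error function; default [ztest_pce()].
#' @return An object of class `adapted_design`: list with the `pce_table`,
#'   second-stage `subset_weights`, matrices `v` (allocation fractions) and
#'   vectors `gamma`, `B` indexed by subset bitmask, plus the inputs.
#' @examples
#' pre <- hyp_graph(
#'   w = c(1/2, 1/2, 0, 0),
#'   G = rbind(c(0, 0, 1, 0), c(0, 0, 0, 1), c(0, 1, 0, 0), c(1, 0, 0, 0))
#' )
#' post <- hyp_graph(w = c(1, 0, 0, 0), G = rbind(
#'   c(0, 0, 1, 0), c(0, 0, 0, 0), c(0, 0, 0, 0), c(0, 0, 0, 0)
#' ))
#' adapt_design(c(1.66, 1.42, 1.90, 0.79), pre, post,
#'   plan = stage_plan(0.025, 116, 58), continued = c("H1", "H3")
#' )
#' @export
adapt_design <- function(data, graph, graph2 = graph, plan,
                         continued = NULL,
                         strategy = c("eq8", "equal_recycling", "direct"),
                         pce = ztest_pce) {
  stopifnot(inherits(graph, "hyp_graph"))
  strategy <- match.arg(strategy)
  is_graph2 <- inherits(graph2, "hyp_graph")
  if (!is_graph2 && !inherits(graph2, "subset_weights")) {
    stop("`graph2` must be a hyp_graph or a subset_weights table", call. = FALSE)
  }
  nm2 <- if (is_graph2) graph2$names else attr(graph2, "hypotheses")
  if (!identical(graph$names, nm2)) {
    stop("`graph` and `graph2` must share the same hypotheses", call. = FALSE)
  }
  m <- length(graph$w)
  weights <- derive_weights(graph)
  pt <- pce_table(data, weights, plan, pce = pce)
  z1 <- attr(pt, "z1")
  A <- attr(pt, "A_matrix")
  B <- attr(pt, "B")
  weights2 <- if (is_graph2) derive_weights(graph2) else graph2
  W2 <- .weight_matrix(weights2)

  if (is.null(continued)) {
    continued <- which(colSums(W2) > 0)
  } else if (is.character(continued)) {
    continued <- match(continued, graph$names)
  } else {
    continued <- as.integer(continued)
  }
  dropped <- setdiff(seq_len(m), continued)
  if (any(W2[, dropped] > 0)) {
    stop("dropped hypotheses must have zero second-stage weight",
      call. = FALSE
    )
  }

  n_sub <- nrow(W2)
  V <- matrix(0, n_sub, m, dimnames = dimnames(W2))
  gamma <- rep(NA_real_, n_sub)
  for (J in seq_len(n_sub)) {
    w2J <- W2[J, ]
    if (B[J] >= 1 || B[J] <= 0 || all(w2J <= 0)) next
    if (strategy == "eq8") {
      gamma[J] <- solve_gamma(z1, w2J, B[J], plan, pce = pce)
      pos <- which(w2J > 0)
      V[J, pos] <- pce(z1[pos], pmin(w2J[pos] * gamma[J], 1), plan$t) / B[J]
    } else if (strategy == "equal_recycling") {
      memb <- .bit_members(J, m)
      AJ <- ifelse(memb, A[J, ], NA_real_)
      if (length(intersect(which(memb), continued)) > 0) {
        V[J, ] <- equal_recycling_fractions(AJ, continued)
      }
    } else {
      V[J, ] <- w2J
    }
  }
  structure(
    list(
      pce = pt, weights2 = weights2, v = V, gamma = gamma, B = B,
      continued = continued, dropped = dropped, strategy = strategy,
      graph = graph, graph2 = graph2, plan = plan, pce_fun = pce
    ),
    class = "adapted_design"
  )
}

#' @export
print.adapted_design <- function(x, ...) {
  m <- length(x$graph$w)
  cat("<adapted_design> ", m, " hypotheses, strategy ", x$strategy, "\n", sep = "")
  cat(
    "continued:", paste(x$graph$names[x$continued], collapse = ", "),
    if (length(x$dropped)) paste0("| dropped: ", paste(x$graph$names[x$dropped], collapse = ", ")),
    "\n"
  )
  cat("min B_J over subsets:", signif(min(x$B), 4), "\n")
  invisible(x)
}

#' Adaptive graph-based closed test (agMTP)
#'
#' Final-analysis decisions of the adaptive closed test: every intersection
#' hypothesis H_J is tested by its adapted weighted Bonferroni test
#' ([adapted_intersection_decision()]) at conditional level `B_J`, and an
#' elementary hypothesis is rejected iff all intersections containing it are
#' rejected. The full closure over all `2^m - 1` subsets is evaluated: the
#' adaptive test is in general not consonant, so no sequentially rejective
#' shortcut exists. Subsets in which every hypothesis was dropped (all
#' allocation fractions zero) are rejected iff `B_J >= 1`.
#'
#' @param data A data frame with columns `hypothesis` and `q` (second-stage
#'   p-values; use 1 for hypotheses without second-stage data), or a numeric
#'   vector in graph order.
#' @param design An [adapt_design()] object.
#' @return A tibble with columns `hypothesis`, `q`, `rejected`, carrying the
#'   per-subset table as attribute `intersections` (tibble with `bitmask`,
#'   `subset`, `B`, `gamma`, `decision`).
#' @examples
#' pre <- hyp_graph(
#'   w = c(1/2, 1/2, 0, 0),
#'   G = rbind(c(0, 0, 1, 0), c(0, 0, 0, 1), c(0, 1, 0, 0), c(1, 0, 0, 0))
#' )
#' post <- hyp_graph(w = c(1, 0, 0, 0), G = rbind(
#'   c(0, 0, 1, 0), c(0, 0, 0, 0), c(0, 0, 0, 0), c(0, 0, 0, 0)
#' ))
#' des <- adapt_design(c(1.66, 1.42, 1.90, 0.79), pre, post,
#'   plan = stage_plan(0.025, 116, 58), continued = c("H1", "H3")
#' )
#' agmtp_closed_test(c(0.059, 1, 0.031, 1), des)
#' @export
agmtp_closed_test <- function(data, design) {
  stopifnot(inherits(design, "adapted_design"))
  m <- length(design$graph$w)
  qd <- .as_p_data(data, design$graph$names, value_col = "q")
  .check_pvalues(qd$value, "q")
  q <- qd$value
  n_sub <- length(design$B)
  dec <- integer(n_sub)
  for (J in seq_len(n_sub)) {
    dec[J] <- adapted_intersection_decision(q, design$v[J, ], design$B[J])
  }
  psi <- vapply(seq_len(m), function(i) {
    all(dec[.bitmask_contains(seq_len(n_sub), i)] == 1L)
  }, logical(1))
  out <- tibble::tibble(
    hypothesis = qd$hypothesis,
    q = q,
    rejected = psi
  )
  attr(out, "intersections") <- tibble::tibble(
    bitmask = seq_len(n_sub),
    subset = vapply(
      seq_len(n_sub),
      function(J) .subset_label(which(.bit_members(J, m))), character(1)
    ),
    B = design$B,
    gamma = design$gamma,
    decision = dec
  )
  out
}

#' Simple adaptive comparator: saMTP / graph-based partitioning algorithm
#'
#' The strictly conservative alternative to the adaptive closed test: compute
#' inverse-normal combination p-values for the continued hypotheses with the
#' preplanned stage weights, set the p-values of dropped hypotheses to 1, and
#' run the preplanned sequentially rejective graph procedure unchanged. With
#' preplanned z-tests and no sample-size change this equals setting dropped
#' p-values to 1 in the fixed-sample test (saMTP); with combination tests it
#' is the graph-based partitioning algorithm (gPA).
#'
#' @param data A data frame with columns `hypothesis`, `q1` (first-stage
#'   p-values) and `q` (second-stage p-values), or a list/two vectors via
#'   `q1`, `q` arguments.
#' @param graph Preplanned [hyp_graph()].
#' @param dropped Labels or indices of hypotheses dropped at interim (their
#'   combined p-values are set to 1).
#' @param plan A [stage_plan()].
#' @param q1,q Alternative to `data`: numeric vectors in graph order.
#' @return A tibble with columns `hypothesis`, `p` (combined p-value) and
#'   `rejected`.
#' @export
samtp_gpa <- function(data = NULL, graph, dropped = integer(0), plan,
                      q1 = NULL, q = NULL) {
  stopifnot(inherits(graph, "hyp_graph"), inherits(plan, "stage_plan"))
  if (!is.null(data)) {
    if (!all(c("q1", "q") %in% names(data))) {
      stop("`data` must have `q1` and `q` columns", call. = FALSE)
    }
    o <- if ("hypothesis" %in% names(data)) {
      match(graph$names, as.character(data$hypothesis))
    } else {
      seq_along(graph$names)
    }
    q1 <- as.numeric(data$q1)[o]
    q <- as.numeric(data$q)[o]
  }
  if (is.character(dropped)) dropped <- match(dropped, graph$names)
  dropped <- as.integer(dropped)
  if (anyNA(dropped) || any(dropped < 1 | dropped > length(graph$w))) {
    stop("`dropped` must identify hypotheses of `graph`", call. = FALSE)
  }
  p <- inverse_normal_pvalue(q1, q, plan$t)
  p[dropped] <- 1
  sequentially_rejective(p, graph, plan$alpha)
}

#' Run the full adaptive analysis pipeline
#'
#' Convenience wrapper tying the interim and final analyses together:
#' derives the preplanned and second-stage weight tables, computes partial
#' conditional errors from the first-stage z-scores, solves for the
#' allocation fractions and applies the adaptive closed test to the
#' second-stage p-values.
#'
#' @inheritParams adapt_design
#' @param q Second-stage p-values (vector in graph order, or data frame with
#'   `hypothesis` and `q`); 1 for hypotheses without second-stage data.
#' @return An object of class `agmtp` wrapping the decisions tibble, the
#'   design and the per-subset table; supports [generics::tidy()],
#'   [generics::glance()] and `print()`.
#' @examples
#' pre <- hyp_graph(
#'   w = c(1/2, 1/2, 0, 0),
#'   G = rbind(c(0, 0, 1, 0), c(0, 0, 0, 1), c(0, 1, 0, 0), c(1, 0, 0, 0))
#' )
#' post <- hyp_graph(w = c(1, 0, 0, 0), G = rbind(
#'   c(0, 0, 1, 0), c(0, 0, 0, 0), c(0, 0, 0, 0), c(0, 0, 0, 0)
#' ))
#' fit <- agmtp(
#'   z1 = c(1.66, 1.42, 1.90, 0.79), q = c(0.059, 1, 0.031, 1),
#'   graph = pre, graph2 = post, plan = stage_plan(0.025, 116, 58),
#'   continued = c("H1", "H3")
#' )
#' fit
#' @export
agmtp <- function(z1, q, graph, graph2 = graph, plan, continued = NULL,
                  strategy = c("eq8", "equal_recycling", "direct"),
                  pce = ztest_pce) {
  design <- adapt_design(z1, graph, graph2,
    plan = plan, continued = continued,
    strategy = strategy, pce = pce
  )
  decisions <- agmtp_closed_test(q, design)
  structure(
    list(
      decisions = decisions,
      design = design,
      intersections = attr(decisions, "intersections")
    ),
    class = "agmtp"
  )
}

#' @export
print.agmtp <- function(x, ...) {
  cat("<agmtp> adaptive graph-based closed test\n")
  rej <- x$decisions$hypothesis[x$decisions$rejected]
  cat(
    "rejected:",
    if (length(rej)) paste(rej, collapse = ", ") else "(none)", "\n"
  )
  print(x$decisions)
  invisible(x)
}
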