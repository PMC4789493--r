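#' Weighted Bonferroni test of a single intersection hypothesis
#'
#' Rejects the intersection hypothesis H_J if any unadjusted p-value falls at
#' or below its weighted critical boundary, i.e. if `p[j] <= w[j] * alpha`
#' for some j in J (non-strict comparison; ties have probability zero for
#' continuous test statistics).
#'
#' @param p Numeric vector of m marginal unadjusted p-values in \[0, 1\]
#'   (`1` acts as a "no data" placeholder).
#' @param w Numeric weight vector for the subset: non-negative, zero outside
#'   J, summing to at most 1. `NA` entries (hypotheses outside J) are treated
#'   as zero.
#' @param alpha One-sided familywise error level in (0, 1).
#' @return `1L` if H_J is rejected, `0L` otherwise.
#' @examples
#' intersection_decision(c(0.02, 0.001), w = c(1, 0), alpha = 0.025)
#' @export
intersection_decision <- function(p, w, alpha) {
  .check_alpha(alpha)
  .check_pvalues(p)
  w <- ifelse(is.na(w), 0, w)
  as.integer(any(w > 0 & p <= w * alpha))
}

.check_alpha <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1 || is.na(alpha) ||
    alpha <= 0 || alpha >= 1) {
    stop("`alpha` must be a single number in (0, 1)", call. = FALSE)
  }
}

.check_pvalues <- function(p, what = "p") {
  if (anyNA(p) || any(p < 0 | p > 1)) {
    stop("`", what, "` must lie in [0, 1]", call. = FALSE)
  }
}

#' Closed weighted Bonferroni test
#'
#' Applies the closed testing principle: elementary hypothesis H_i is
#' rejected iff every intersection hypothesis H_J with i in J is rejected by
#' its weighted Bonferroni test ([intersection_decision()]). Strongly
#' controls the familywise error rate at `alpha`.
#'
#' @param data A data frame with columns `hypothesis` and `p` (one row per
#'   hypothesis, in graph order), or a bare numeric vector of p-values.
#' @param weights A `subset_weights` table from [derive_weights()] covering
#'   all `2^m - 1` subsets.
#' @param alpha One-sided familywise error level in (0, 1).
#' @return A tibble with columns `hypothesis`, `p` and `rejected` (logical),
#'   carrying the per-subset decisions as attribute `intersections` (a tibble
#'   with `bitmask`, `subset`, `decision`).
#' @examples
#' g <- hyp_graph(w = c(1/2, 1/2), G = rbind(c(0, 1), c(1, 0)))
#' closed_test(c(0.001, 0.03), derive_weights(g), alpha = 0.025)
#' @export
closed_test <- function(data, weights, alpha) {
  .check_alpha(alpha)
  W <- .weight_matrix(weights)
  m <- ncol(W)
  pd <- .as_p_data(data, colnames(W), value_col = "p")
  .check_pvalues(pd$value)
  dec <- .closure_decisions(matrix(pd$value, nrow = 1), W, alpha)
  psi <- .closure_elementary(dec, m)
  out <- tibble::tibble(
    hypothesis = pd$hypothesis,
    p = pd$value,
    rejected = as.logical(psi[1, ])
  )
  attr(out, "intersections") <- tibble::tibble(
    bitmask = seq_len(nrow(W)),
    subset = vapply(
      seq_len(nrow(W)),
      function(J) .subset_label(which(.bit_members(J, m))), character(1)
    ),
    decision = as.integer(dec[1, ])
  )
  out
}

# coerce data-frame-or-vector input into (hypothesis, value)
.as_p_data <- function(data, hyp_names, value_col) {
  m <- length(hyp_names)
  if (is.data.frame(data)) {
    if (!value_col %in% names(data)) {
      stop("`data` must have a `", value_col, "` column", call. = FALSE)
    }
    v <- as.numeric(data[[value_col]])
    h <- if ("hypothesis" %in% names(data)) as.character(data$hypothesis) else hyp_names
    if (!setequal(h, hyp_names) || length(h) != m) {
      stop("`data$hypothesis` must match the graph's hypotheses", call. = FALSE)
    }
    v <- v[match(hyp_names, h)]
  } else {
    v <- as.numeric(data)
    if (length(v) != m) {
      stop("expected ", m, " values, got ", length(v), call. = FALSE)
    }
  }
  tibble::tibble(hypothesis = hyp_names, value = v)
}

# vectorised closure: P is reps x m matrix of p-values, W is (2^m - 1) x m;
# returns reps x (2^m - 1) intersection decisions
.closure_decisions <- function(P, W, alpha) {
  n_sub <- nrow(W)
  reps <- nrow(P)
  dec <- matrix(FALSE, reps, n_sub)
  for (J in seq_len(n_sub)) {
    wj <- W[J, ]
    pos <- which(wj > 0)
    if (length(pos) == 0) next
    hit <- P[, pos, drop = FALSE] <= rep(wj[pos] * alpha, each = reps)
    dec[, J] <- rowSums(hit) > 0
  }
  dec
}

# elementary decisions: psi_i = min over J containing i
.closure_elementary <- function(dec, m) {
  reps <- nrow(dec)
  psi <- matrix(TRUE, reps, m)
  for (i in seq_len(m)) {
    Js <- which(.bitmask_contains(seq_len(ncol(dec)), i))
    psi[, i] <- rowSums(!dec[, Js, drop = FALSE]) == 0
  }
  psi
}

.bitmask_contains <- function(J, i) {
  bitwAnd(bitwShiftR(J, i - 1L), 1L) == 1L
}

#' Sequentially rejective graph-based test
#'
#' The shortcut of the closed weighted Bonferroni test for graph-generated
#' weights: repeatedly reject any hypothesis with `p[i] <= w[i] * alpha`,
#' remove its node (reallocating its weight along the graph's edges via
#' [remove_node()]) and retest, until no further rejection is possible. The
#' decisions coincide with [closed_test()] applied to
#' [derive_weights()]`(graph)`.
#'
#' @inheritParams closed_test
#' @param graph A [hyp_graph()].
#' @return A tibble with columns `hypothesis`, `p`, `rejected`.
#' @examples
#' g <- hyp_graph(
#'   w = c(1/2, 1/2, 0, 0),
#'   G = rbind(c(0, 0, 1, 0), c(0, 0, 0, 1), c(0, 1, 0, 0), c(1, 0, 0, 0))
#' )
#' sequentially_rejective(c(0.001, 0.5, 0.01, 0.5), g, alpha = 0.025)
#' @export
sequentially_rejective <- function(data, graph, alpha) {
  stopifnot(inherits(graph, "hyp_graph"))
  .check_alpha(alpha)
  pd <- .as_p_data(data, graph$names, value_col = "p")
  .check_pvalues(pd$value)
  rejected <- character(0)
  g <- graph
  p <- stats::setNames(pd$value, graph$names)
  repeat {
    hit <- names(g$w)[g$w > 0 & p[names(g$w)] <= g$w * alpha]
    if (length(hit) == 0) break
    rejected <- c(rejected, hit)
    if (length(hit) == length(g$w)) break
    # several hypotheses may qualify in one pass: remove them one at a time
    # (the reduced graph does not depend on the order)
    for (h in hit) g <- remove_node(g, h)
  }
  tibble::tibble(
    hypothesis = pd$hypothesis,
    p = pd$value,
    rejected = pd$hypothesis %in% rejected
  )
}
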