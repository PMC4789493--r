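#' Hypothesis graphs for graph-based multiple testing procedures
#'
#' A hypothesis graph encodes a weighted Bonferroni testing strategy for m
#' elementary null hypotheses: node weights `w` give the initial allocation of
#' the significance level (as fractions of alpha) and the directed edge-weight
#' matrix `G` prescribes how a rejected hypothesis' level is propagated to the
#' remaining hypotheses.
#'
#' Constraints checked (with numerical tolerance 1e-9, values within tolerance
#' of a bound are clamped to the bound):
#' * `w[i] >= 0` and `sum(w) <= 1`,
#' * `G[i, j] >= 0`, `diag(G) == 0`, and every row sum of `G` is at most 1.
#'
#' @param names Character vector of unique hypothesis labels. Defaults to
#'   `H1, ..., Hm`.
#' @param w Numeric vector of m node weights.
#' @param G Numeric m x m matrix of transition (edge) weights.
#' @return An object of class `hyp_graph`: a list with elements `names`, `w`
#'   and `G`.
#' @examples
#' # Two treatments, hierarchical primary -> secondary endpoints, symmetric
#' # between treatments:
#' g <- hyp_graph(
#'   w = c(1/2, 1/2, 0, 0),
#'   G = rbind(
#'     c(0, 0, 1, 0),
#'     c(0, 0, 0, 1),
#'     c(0, 1, 0, 0),
#'     c(1, 0, 0, 0)
#'   ),
#'   names = c("H1", "H2", "H3", "H4")
#' )
#' g
#' @export
hyp_graph <- function(w, G, names = NULL) {
  w <- as.numeric(w)
  m <- length(w)
  if (m < 1) stop("a hypothesis graph needs at least one node", call. = FALSE)
  G <- as.matrix(G)
  storage.mode(G) <- "double"
  if (!all(dim(G) == c(m, m))) {
    stop(sprintf("`G` must be a %d x %d matrix to match `w`", m, m), call. = FALSE)
  }
  if (is.null(names)) names <- paste0("H", seq_len(m))
  names <- as.character(names)
  if (length(names) != m || anyDuplicated(names)) {
    stop("`names` must be ", m, " unique labels", call. = FALSE)
  }
  if (anyNA(w) || anyNA(G)) stop("weights must be finite, not NA", call. = FALSE)

  tol <- .agmtp_tol
  if (any(w < -tol)) stop("node weights must be non-negative", call. = FALSE)
  w <- pmax(w, 0)
  if (sum(w) > 1 + tol) {
    stop(sprintf("node weights sum to %.6g > 1", sum(w)), call. = FALSE)
  }
  if (sum(w) > 1) w <- w / sum(w)

  if (any(G < -tol)) stop("edge weights must be non-negative", call. = FALSE)
  G[G < 0] <- 0
  if (any(abs(diag(G)) > tol)) {
    stop("diagonal of `G` must be zero (no self-edges)", call. = FALSE)
  }
  diag(G) <- 0
  rs <- rowSums(G)
  if (any(rs > 1 + tol)) {
    stop(sprintf(
      "edge weights of row %d sum to %.6g > 1",
      which.max(rs), max(rs)
    ), call. = FALSE)
  }
  over <- rs > 1
  if (any(over)) G[over, ] <- G[over, , drop = FALSE] / rs[over]

  dimnames(G) <- list(names, names)
  structure(
    list(names = names, w = stats::setNames(w, names), G = G),
    class = "hyp_graph"
  )
}

.agmtp_tol <- 1e-9
# weights this small are snapped to exact zero so that "zero weight" logic
# (e.g. v = 0 for dropped hypotheses) stays exact after repeated updates
.agmtp_snap <- 1e-12

#' @export
print.hyp_graph <- function(x, ...) {
  cat("<hyp_graph> ", length(x$w), " hypotheses\n", sep = "")
  cat("node weights:\n")
  print(round(x$w, 6))
  cat("transitions:\n")
  print(round(x$G, 6))
  invisible(x)
}

#' @export
length.hyp_graph <- function(x) length(x$w)

#' Remove a node from a hypothesis graph
#'
#' Removes hypothesis `drop` from the graph, reallocating its node weight to
#' its graph neighbours in proportion to the outgoing edge weights and
#' rewiring the remaining edges:
#' `w'[j] = w[j] + w[l] * G[l, j]` and
#' `G'[j, k] = (G[j, k] + G[j, l] * G[l, k]) / (1 - G[j, l] * G[l, j])`,
#' with `G'[j, k] = 0` when `G[j, l] * G[l, j] = 1`. This is the standard
#' update of sequentially rejective graphical procedures; applied repeatedly
#' it generates the weighted Bonferroni weights of every intersection
#' hypothesis (see [derive_weights()]).
#'
#' @param graph A [hyp_graph()].
#' @param drop Hypothesis to remove: a label or a position.
#' @return A `hyp_graph` over the remaining hypotheses.
#' @examples
#' g <- hyp_graph(w = c(1, 0), G = rbind(c(0, 1), c(0, 0)))
#' remove_node(g, "H1") # fixed sequence: all weight moves to H2
#' @export
remove_node <- function(graph, drop) {
  stopifnot(inherits(graph, "hyp_graph"))
  m <- length(graph$w)
  if (m < 2) stop("cannot remove a node from a singleton graph", call. = FALSE)
  l <- if (is.character(drop)) match(drop, graph$names) else as.integer(drop)
  if (is.na(l) || l < 1 || l > m) {
    stop("`drop` is not a hypothesis of this graph", call. = FALSE)
  }
  upd <- .remove_node_core(graph$w, graph$G, l)
  hyp_graph(upd$w, upd$G, names = graph$names[-l])
}

# core update on raw (w, G); index l removed, no validation
.remove_node_core <- function(w, G, l) {
  keep <- setdiff(seq_along(w), l)
  w2 <- w[keep] + w[l] * G[l, keep]
  gl_out <- G[l, keep] # edges leaving l
  gl_in <- G[keep, l] # edges entering l
  # G'[j,k] = (G[j,k] + G[j,l] G[l,k]) / (1 - G[j,l] G[l,j]); the denominator
  # is row-specific and vanishes only when j and l form a closed loop, in
  # which case the whole row is set to zero
  d <- 1 - gl_in * gl_out
  G2 <- (G[keep, keep, drop = FALSE] + outer(gl_in, gl_out)) /
    ifelse(abs(d) < .agmtp_snap, 1, d)
  G2[abs(d) < .agmtp_snap, ] <- 0
  diag(G2) <- 0
  G2[G2 < .agmtp_snap] <- 0
  w2[w2 < .agmtp_snap] <- 0
  list(w = w2, G = G2)
}

#' Weighted Bonferroni weights for all intersection hypotheses
#'
#' Expands a hypothesis graph into the full closed-test weight table: for
#' every non-empty subset J of the m hypotheses, the weight vector `w_J`
#' obtained by removing the hypotheses outside J one at a time via the
#' graphical update rule (the result does not depend on the removal order).
#' These are the weights of the weighted Bonferroni test of each intersection
#' hypothesis in the closed testing procedure.
#'
#' @param graph A [hyp_graph()].
#' @return A tibble with one row per non-empty subset, columns:
#'   \describe{
#'     \item{bitmask}{integer subset encoding; bit `i - 1` set iff hypothesis
#'       `i` is in J}
#'     \item{subset}{label such as `"{1,3,4}"` (1-based positions)}
#'     \item{size}{number of hypotheses in J}
#'     \item{one column per hypothesis}{its weight `w[j, J]`, `NA` for
#'       hypotheses outside J}
#'   }
#'   The tibble carries attributes `m`, `hypotheses` and `weight_matrix` (a
#'   dense `(2^m - 1) x m` matrix indexed by bitmask, zeros outside J) and
#'   class `subset_weights`.
#' @examples
#' g <- hyp_graph(w = c(1, 0), G = rbind(c(0, 1), c(0, 0)))
#' derive_weights(g)
#' @export
derive_weights <- function(graph) {
  stopifnot(inherits(graph, "hyp_graph"))
  m <- length(graph$w)
  if (m > 16) {
    stop("full subset enumeration is limited to m <= 16 hypotheses", call. = FALSE)
  }
  n_sub <- bitwShiftL(1L, m) - 1L
  W <- matrix(0, nrow = n_sub, ncol = m, dimnames = list(NULL, graph$names))
  # DP over subsets by decreasing size: obtain (w_J, G_J) from the parent
  # J u {l} with l the largest missing index
  G_store <- vector("list", n_sub)
  full <- n_sub
  W[full, ] <- graph$w
  G_store[[full]] <- graph$G
  ord <- order(vapply(seq_len(n_sub), .popcount, integer(1)), decreasing = TRUE)
  for (J in ord) {
    if (J == full) next
    missing <- which(!.bit_members(J, m))
    l <- missing[length(missing)]
    parent <- bitwOr(J, bitwShiftL(1L, l - 1L))
    members_par <- which(.bit_members(parent, m))
    pos_l <- match(l, members_par)
    upd <- .remove_node_core(W[parent, members_par], G_store[[parent]], pos_l)
    members <- members_par[-pos_l]
    W[J, members] <- upd$w
    G_store[[J]] <- upd$G
  }
  W[W < .agmtp_snap] <- 0

  members <- lapply(seq_len(n_sub), function(J) which(.bit_members(J, m)))
  tbl <- tibble::as_tibble(W)
  for (j in seq_len(m)) {
    out_j <- !vapply(members, function(mm) j %in% mm, logical(1))
    tbl[[j]][out_j] <- NA_real_
  }
  out <- dplyr::bind_cols(
    tibble::tibble(
      bitmask = seq_len(n_sub),
      subset = vapply(members, .subset_label, character(1)),
      size = lengths(members)
    ),
    tbl
  )
  out <- dplyr::arrange(out, dplyr::desc(.data$size), .data$bitmask)
  attr(out, "m") <- m
  attr(out, "hypotheses") <- graph$names
  attr(out, "weight_matrix") <- W
  class(out) <- c("subset_weights", class(out))
  out
}

.popcount <- function(x) {
  n <- 0L
  while (x > 0L) {
    n <- n + bitwAnd(x, 1L)
    x <- bitwShiftR(x, 1L)
  }
  n
}

.bit_members <- function(J, m) {
  bitwAnd(bitwShiftR(J, seq_len(m) - 1L), 1L) == 1L
}

.subset_label <- function(members) {
  paste0("{", paste(members, collapse = ","), "}")
}

# dense (2^m - 1) x m weight matrix from a subset_weights tibble (or pass-through)
.weight_matrix <- function(weights) {
  W <- attr(weights, "weight_matrix")
  if (is.null(W)) stop("`weights` must come from derive_weights()", call. = FALSE)
  W
}

#' Read and write hypothesis graphs as JSON
#'
#' The JSON dialect is `{"names": [...], "weights": [...],
#' "transitions": [[...], ...]}` with the transition matrix in row-major
#' order. `read_graph_json()` validates on read; the pair round-trips exactly.
#'
#' @param path File path.
#' @param graph A [hyp_graph()].
#' @return `read_graph_json()` returns a `hyp_graph`; `write_graph_json()`
#'   returns `path` invisibly.
#' @export
read_graph_json <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (is.null(x$weights) || is.null(x$transitions)) {
    stop("graph JSON needs `weights` and `transitions` fields", call. = FALSE)
  }
  G <- x$transitions
  if (is.list(G)) G <- do.call(rbind, G)
  hyp_graph(w = x$weights, G = G, names = x$names)
}

#' @rdname read_graph_json
#' @export
write_graph_json <- function(graph, path) {
  stopifnot(inherits(graph, "hyp_graph"))
  jsonlite::write_json(
    list(
      names = graph$names,
      weights = unname(graph$w),
      transitions = apply(unname(graph$G), 1, identity, simplify = FALSE)
    ),
    path,
    auto_unbox = FALSE, digits = NA
  )
  invisible(path)
}
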