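#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the elementary decisions of an adaptive closed test
#'
#' @param x An [agmtp()] fit.
#' @param ... Unused.
#' @return A tibble with one row per elementary hypothesis: `hypothesis`,
#'   `q` (second-stage p-value), `own_level` (the conditional level
#'   `v * B` the hypothesis' own elementary test receives, i.e. for the
#'   singleton intersection), `n_blocking` (number of intersection
#'   hypotheses containing it that were not rejected) and `rejected`.
#'   Because the adaptive closed test is not consonant, the effective
#'   critical value for `q` depends on which other hypotheses clear their
#'   intersections; the per-subset table in `x$intersections` has the full
#'   picture.
#' @export
tidy.agmtp <- function(x, ...) {
  m <- length(x$design$graph$w)
  inter <- x$intersections
  own <- vapply(seq_len(m), function(i) {
    J <- bitwShiftL(1L, i - 1L)
    if (x$design$B[J] >= 1) 1 else x$design$v[J, i] * x$design$B[J]
  }, numeric(1))
  blocking <- vapply(seq_len(m), function(i) {
    sum(inter$decision == 0L & .bitmask_contains(inter$bitmask, i))
  }, numeric(1))
  tibble::tibble(
    hypothesis = x$decisions$hypothesis,
    q = x$decisions$q,
    own_level = own,
    n_blocking = as.integer(blocking),
    rejected = x$decisions$rejected
  )
}

#' One-row summary of an adaptive closed test
#'
#' @param x An [agmtp()] fit.
#' @param ... Unused.
#' @return A one-row tibble: `m`, `n_continued`, `n_rejected`, `min_B`
#'   (smallest conditional level over all intersections), `alpha`.
#' @export
glance.agmtp <- function(x, ...) {
  tibble::tibble(
    m = length(x$design$graph$w),
    n_continued = length(x$design$continued),
    n_rejected = sum(x$decisions$rejected),
    min_B = min(x$design$B),
    alpha = x$design$plan$alpha
  )
}

#' Plot Monte Carlo operating characteristics
#'
#' Bar chart of the per-hypothesis rejection probabilities and the overall
#' probability of at least one rejection, faceted by procedure when several
#' [operating_characteristics()] results are row-bound together.
#'
#' @param object An `agmtp_oc` tibble (possibly several rows).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.agmtp_oc <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object),
    cols = c("pi", "pi_1", "pi_2", "pi_3", "pi_4"),
    names_to = "quantity", values_to = "percent"
  )
  long$quantity <- factor(
    long$quantity,
    levels = c("pi", "pi_1", "pi_2", "pi_3", "pi_4"),
    labels = c("any", "H1", "H2", "H3", "H4")
  )
  ggplot2::ggplot(
    long,
    ggplot2::aes(x = .data$quantity, y = .data$percent, fill = .data$procedure)
  ) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~rule) +
    ggplot2::labs(
      x = NULL, y = "rejection probability (%)",
      title = "Simulated operating characteristics"
    ) +
    ggplot2::theme_minimal()
}

#' Plot the partial conditional error decomposition
#'
#' Stacked bars of the partial conditional error rates `A[j, J]` per
#' intersection hypothesis, with the bar height equal to the conditional
#' level `B_J`.
#'
#' @param object A `pce_table` from [pce_table()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pce_table <- function(object, ...) {
  hyp <- attr(object, "hypotheses")
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object),
    cols = dplyr::all_of(paste0("A_", hyp)),
    names_to = "hypothesis", values_to = "A", names_prefix = "A_"
  )
  long <- dplyr::filter(long, !is.na(.data$A))
  ggplot2::ggplot(
    long,
    ggplot2::aes(
      x = stats::reorder(.data$subset, .data$B),
      y = .data$A, fill = .data$hypothesis
    )
  ) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(
      x = "intersection hypothesis", y = "partial conditional error",
      title = "Conditional level B per intersection"
    ) +
    ggplot2::theme_minimal()
}
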