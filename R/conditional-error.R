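#' Partial conditional error rate of a preplanned one-sided z-test
#'
#' Given the first-stage standardized treatment-control difference `z1`, the
#' probability that the preplanned fixed-sample z-test (at per-group sample
#' size n, information fraction `t = n1 / n`) rejects at local level `level`,
#' conditional on the first-stage data:
#' `1 - pnorm((qnorm(1 - level) - z1 * sqrt(t)) / sqrt(1 - t))`.
#'
#' The limits `level = 0 -> 0` and `level = 1 -> 1` are returned exactly;
#' levels below 1e-15 are treated as 0 to avoid overflow of the normal
#' quantile. Vectorised over `z1` and `level`.
#'
#' @param z1 First-stage z-score(s).
#' @param level Local significance level(s) in \[0, 1\] (typically
#'   `w[j, J] * alpha`).
#' @param t Information fraction `n1 / n` in (0, 1).
#' @return Partial conditional error rate(s) in \[0, 1\].
#' @examples
#' ztest_pce(1.66, level = 0.0125, t = 0.5) # 0.066 to 3 d.p.
#' @export
ztest_pce <- function(z1, level, t) {
  if (!is.numeric(t) || length(t) != 1 || is.na(t) || t <= 0 || t >= 1) {
    stop("`t` must be a single number in (0, 1)", call. = FALSE)
  }
  .check_pvalues(level, what = "level")
  n <- max(length(z1), length(level))
  z1 <- rep_len(z1, n)
  level <- rep_len(level, n)
  out <- numeric(n)
  lo <- level < 1e-15
  hi <- level >= 1
  mid <- !lo & !hi
  out[hi] <- 1
  if (any(mid)) {
    out[mid] <- 1 - stats::pnorm(
      (stats::qnorm(1 - level[mid]) - z1[mid] * sqrt(t)) / sqrt(1 - t)
    )
  }
  out
}

#' Two-stage plan for a preplanned z-test
#'
#' Bundles the one-sided familywise error level, the preplanned per-group
#' sample size `n` and the first-stage per-group size `n1`; the information
#' fraction is `t = n1 / n`.
#'
#' @param alpha One-sided familywise error level in (0, 1).
#' @param n Preplanned per-group sample size (subjects).
#' @param n1 First-stage per-group sample size, `0 < n1 < n`.
#' @return An object of class `stage_plan` with fields `alpha`, `n`, `n1`,
#'   `t`.
#' @examples
#' stage_plan(alpha = 0.025, n = 116, n1 = 58)
#' @export
stage_plan <- function(alpha, n, n1) {
  .check_alpha(alpha)
  if (!(n > 0 && n1 > 0 && n1 < n)) {
    stop("need 0 < n1 < n", call. = FALSE)
  }
  structure(
    list(alpha = alpha, n = n, n1 = n1, t = n1 / n),
    class = "stage_plan"
  )
}

#' @export
print.stage_plan <- function(x, ...) {
  cat(sprintf(
    "<stage_plan> alpha = %g, n = %g, n1 = %g (t = %.4g)\n",
    x$alpha, x$n, x$n1, x$t
  ))
  invisible(x)
}

#' Partial conditional error table for all intersection hypotheses
#'
#' For every non-empty subset J of the hypotheses, computes the partial
#' conditional error rates `A[j, J] = A(z1[j], w[j, J] * alpha, t)` of the
#' preplanned tests (zero for hypotheses with zero weight) and their sum
#' `B_J`. `B_J` is the conditional level available to any adapted test of the
#' intersection hypothesis H_J; it may exceed 1, in which case H_J can be
#' rejected at the interim analysis.
#'
#' @param data A data frame with columns `hypothesis` and `z1` (first-stage
#'   z-scores, in graph order), or a bare numeric vector.
#' @param weights A `subset_weights` table from [derive_weights()].
#' @param plan A [stage_plan()].
#' @param pce A conditional-error function with signature
#'   `(z1, level, t)`, monotone in `level`; defaults to [ztest_pce()]. Use
#'   [inverse_normal_pce()] for a preplanned inverse-normal combination test.
#' @return A tibble of class `pce_table` with one row per subset: `bitmask`,
#'   `subset`, `size`, weight columns `w_<name>`, partial conditional error
#'   columns `A_<name>` (`NA` outside J) and the sum `B`. Attributes `m`,
#'   `hypotheses`, `z1`, `plan`, `pce_fun`, `A_matrix`, `B` support the
#'   adaptive machinery.
#' @examples
#' g <- hyp_graph(
#'   w = c(1/2, 1/2, 0, 0),
#'   G = rbind(c(0, 0, 1, 0), c(0, 0, 0, 1), c(0, 1, 0, 0), c(1, 0, 0, 0))
#' )
#' pce_table(c(1.66, 1.42, 1.90, 0.79), derive_weights(g),
#'   plan = stage_plan(0.025, n = 116, n1 = 58)
#' )
#' @export
pce_table <- function(data, weights, plan, pce = ztest_pce) {
  stopifnot(inherits(plan, "stage_plan"))
  W <- .weight_matrix(weights)
  m <- ncol(W)
  zd <- .as_p_data(data, colnames(W), value_col = "z1")
  z1 <- zd$value
  if (anyNA(z1) || any(!is.finite(z1))) {
    stop("`z1` must be finite", call. = FALSE)
  }
  n_sub <- nrow(W)
  A <- matrix(0, n_sub, m, dimnames = dimnames(W))
  for (j in seq_len(m)) {
    pos <- which(W[, j] > 0)
    if (length(pos)) {
      A[pos, j] <- pce(z1[j], W[pos, j] * plan$alpha, plan$t)
    }
  }
  B <- rowSums(A)

  members <- lapply(seq_len(n_sub), function(J) .bit_members(J, m))
  A_na <- A
  for (j in seq_len(m)) {
    A_na[!vapply(members, `[`, logical(1), j), j] <- NA_real_
  }
  w_tbl <- attr(weights, "weight_matrix")
  w_na <- w_tbl
  for (j in seq_len(m)) {
    w_na[!vapply(members, `[`, logical(1), j), j] <- NA_real_
  }
  out <- tibble::tibble(
    bitmask = seq_len(n_sub),
    subset = vapply(
      seq_len(n_sub), function(J) .subset_label(which(members[[J]])),
      character(1)
    ),
    size = vapply(members, sum, integer(1))
  )
  colnames(w_na) <- paste0("w_", colnames(W))
  colnames(A_na) <- paste0("A_", colnames(W))
  out <- dplyr::bind_cols(out, tibble::as_tibble(w_na), tibble::as_tibble(A_na))
  out$B <- B
  out <- dplyr::arrange(out, dplyr::desc(.data$size), .data$bitmask)
  attr(out, "m") <- m
  attr(out, "hypotheses") <- colnames(W)
  attr(out, "z1") <- stats::setNames(z1, colnames(W))
  attr(out, "plan") <- plan
  attr(out, "pce_fun") <- pce
  attr(out, "A_matrix") <- A
  attr(out, "B") <- B
  attr(out, "weight_matrix") <- W
  class(out) <- c("pce_table", class(out))
  out
}

#' Inverse-normal combination of stagewise p-values
#'
#' Combines independent first- and second-stage p-values into an overall
#' p-value with preplanned stage weights `sqrt(t)` and `sqrt(1 - t)`:
#' `p = 1 - pnorm(sqrt(t) * qnorm(1 - q1) + sqrt(1 - t) * qnorm(1 - q2))`.
#' If either stagewise p-value is 0 the combination is 0; if either is
#' exactly 1 (and the other positive) the combination is 1. Vectorised.
#'
#' @param q1,q2 First- and second-stage p-values in \[0, 1\].
#' @param t Preplanned information fraction `n1 / n` in (0, 1).
#' @return Combined p-value(s) in \[0, 1\].
#' @examples
#' inverse_normal_pvalue(0.5, 0.5, t = 0.5)
#' @export
inverse_normal_pvalue <- function(q1, q2, t) {
  if (!is.numeric(t) || length(t) != 1 || t <= 0 || t >= 1) {
    stop("`t` must be a single number in (0, 1)", call. = FALSE)
  }
  .check_pvalues(q1, "q1")
  .check_pvalues(q2, "q2")
  n <- max(length(q1), length(q2))
  q1 <- rep_len(q1, n)
  q2 <- rep_len(q2, n)
  out <- numeric(n)
  zero <- q1 <= 0 | q2 <= 0
  one <- !zero & (q1 >= 1 | q2 >= 1)
  mid <- !zero & !one
  out[one] <- 1
  if (any(mid)) {
    out[mid] <- 1 - stats::pnorm(
      sqrt(t) * stats::qnorm(1 - q1[mid]) + sqrt(1 - t) * stats::qnorm(1 - q2[mid])
    )
  }
  out
}

#' Second-stage critical boundary of the inverse-normal combination test
#'
#' The largest second-stage p-value q for which the inverse-normal
#' combination of `(q1, q)` stays at or below `level`:
#' `1 - pnorm(sqrt(n / (n - n1)) * qnorm(1 - level) -
#'            sqrt(n1 / (n - n1)) * qnorm(1 - q1))`.
#' Equivalently, `q <= combination_boundary(q1, level, plan)` iff
#' `inverse_normal_pvalue(q1, q, n1/n) <= level`. This is also the partial
#' conditional error rate of a preplanned inverse-normal combination test
#' given its first-stage p-value.
#'
#' @param q1 First-stage p-value(s) in (0, 1\].
#' @param level Local significance level(s) in \[0, 1\].
#' @param plan A [stage_plan()].
#' @return Critical value(s) for the second-stage p-value, in \[0, 1\].
#' @examples
#' plan <- stage_plan(0.025, n = 116, n1 = 58)
#' combination_boundary(0.05, level = 0.0125, plan)
#' @export
combination_boundary <- function(q1, level, plan) {
  stopifnot(inherits(plan, "stage_plan"))
  .check_pvalues(q1, "q1")
  .check_pvalues(level, "level")
  n <- max(length(q1), length(level))
  q1 <- rep_len(q1, n)
  level <- rep_len(level, n)
  out <- numeric(n)
  lo <- level < 1e-15
  hi <- level >= 1
  mid <- !lo & !hi
  out[hi] <- 1
  if (any(mid)) {
    r <- plan$n / (plan$n - plan$n1)
    r1 <- plan$n1 / (plan$n - plan$n1)
    out[mid] <- 1 - stats::pnorm(
      sqrt(r) * stats::qnorm(1 - level[mid]) -
        sqrt(r1) * stats::qnorm(1 - q1[mid])
    )
  }
  out
}

#' Conditional-error function of a preplanned inverse-normal test
#'
#' Adapter with the `(z1, level, t)` signature of [ztest_pce()] for trials
#' whose preplanned elementary tests are inverse-normal combination tests:
#' the first-stage z-score is converted to the stagewise p-value
#' `q1 = 1 - pnorm(z1)` and the partial conditional error rate is the
#' second-stage boundary of the combination test. For equal stage weights
#' (`t = 1/2` with `n = 2 * n1`) it coincides with [ztest_pce()].
#'
#' With stage weights proportional to information, the combination statistic
#' `sqrt(t) * z1 + sqrt(1 - t) * z2` equals the full-data z-statistic, so the
#' two conditional-error functions agree for every `t`; the alias exists to
#' make the choice of preplanned test explicit at call sites.
#'
#' @inheritParams ztest_pce
#' @return Partial conditional error rate(s) in \[0, 1\].
#' @export
inverse_normal_pce <- function(z1, level, t) {
  ztest_pce(z1, level, t)
}
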