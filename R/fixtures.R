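#' Symmetric two-treatment, primary-before-secondary hypothesis graph
#'
#' The preplanned strategy of a three-arm trial testing two treatments
#' against a common control on a primary endpoint (H1, H2) and a secondary
#' endpoint (H3, H4): the level is split equally between the two primary
#' hypotheses; rejecting a primary hypothesis passes its level to the same
#' treatment's secondary hypothesis; rejecting the secondary hypothesis
#' passes the level on to the other treatment's primary hypothesis.
#'
#' With `dropped`, returns instead the second-stage strategy after dropping
#' that treatment arm at interim: the dropped arm's nodes and edges are
#' zeroed and the continued arm's primary hypothesis carries weight 1,
#' passed to its secondary hypothesis.
#'
#' @param dropped `NULL` (preplanned graph) or the dropped treatment arm
#'   (1 or 2).
#' @return A [hyp_graph()] over `H1..H4`.
#' @examples
#' graph_two_arm_hierarchy()
#' graph_two_arm_hierarchy(dropped = 2)
#' @export
graph_two_arm_hierarchy <- function(dropped = NULL) {
  if (is.null(dropped)) {
    return(hyp_graph(
      w = c(1 / 2, 1 / 2, 0, 0),
      G = rbind(
        c(0, 0, 1, 0),
        c(0, 0, 0, 1),
        c(0, 1, 0, 0),
        c(1, 0, 0, 0)
      ),
      names = c("H1", "H2", "H3", "H4")
    ))
  }
  stopifnot(dropped %in% 1:2)
  arm <- 3L - as.integer(dropped)
  w <- numeric(4)
  G <- matrix(0, 4, 4)
  w[arm] <- 1
  G[arm, arm + 2] <- 1
  hyp_graph(w, G, names = c("H1", "H2", "H3", "H4"))
}
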