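# TF core-network strength statistic (out-degree minus in-degree) and
# two-population network comparison.

#' Construct a TF regulatory network
#'
#' @param edges data.frame(regulator, target). Self-loops are dropped;
#'   parallel edges are collapsed unless \code{weighted}.
#' @param expression Optional named numeric vector of per-TF expression.
#' @param weighted Keep edge multiplicities (motif-count weighting).
#' @return A \code{tf_network} object.
#' @export
tf_network <- function(edges, expression = NULL, weighted = FALSE) {
  stopifnot(all(c("regulator", "target") %in% names(edges)))
  self <- edges$regulator == edges$target
  if (any(self)) edges <- edges[!self, , drop = FALSE]
  if (!weighted) edges <- unique(edges)
  nodes <- sort(unique(c(edges$regulator, edges$target, names(expression))))
  structure(list(nodes = nodes, edges = edges, expression = expression,
                 weighted = weighted),
            class = "tf_network")
}

#' Per-TF regulatory strength
#'
#' Strength is the number of outbound edges (TFs regulated) minus the
#' number of inbound edges (TFs targeting). Over any network the
#' strengths sum to zero, as every edge contributes +1 and -1.
#'
#' @param net A \code{tf_network} (or an edge data.frame).
#' @return Named numeric vector of strengths, one per node.
#' @export
tf_strength <- function(net) {
  if (!inherits(net, "tf_network")) net <- tf_network(net)
  out <- table(factor(net$edges$regulator, levels = net$nodes))
  inn <- table(factor(net$edges$target, levels = net$nodes))
  stats::setNames(as.numeric(out - inn), net$nodes)
}

#' Rank TFs by regulatory strength
#'
#' Descending strength, ties broken alphabetically; expression is carried
#' along when available.
#'
#' @param strengths Named numeric vector from \code{tf_strength}.
#' @param expression Optional named per-TF expression values.
#' @return data.frame(tf, strength, rank, expression).
#' @export
rank_tfs <- function(strengths, expression = NULL) {
  ord <- order(-strengths, names(strengths))
  out <- data.frame(tf = names(strengths)[ord],
                    strength = as.numeric(strengths)[ord],
                    rank = seq_along(strengths))
  out$expression <- if (is.null(expression)) NA_real_ else
    as.numeric(expression[out$tf])
  out
}

#' Compare two TF networks over their shared TFs
#'
#' Reports the shared-TF fraction (over the node union), per-TF strength
#' pairs with deltas, and an ordinary-least-squares fit of network B
#' strength on network A strength with 95% confidence intervals.
#' Regression is refused with fewer than 3 shared TFs.
#'
#' @param netA,netB \code{tf_network} objects.
#' @return List with \code{shared_fraction}, \code{table} (tf,
#'   strength_a, strength_b, delta), \code{slope}, \code{intercept},
#'   \code{ci} and \code{regression_refused}.
#' @export
compare_networks <- function(netA, netB) {
  sA <- tf_strength(netA)
  sB <- tf_strength(netB)
  shared <- intersect(names(sA), names(sB))
  uni <- union(names(sA), names(sB))
  tab <- data.frame(tf = shared, strength_a = as.numeric(sA[shared]),
                    strength_b = as.numeric(sB[shared]),
                    delta = as.numeric(sA[shared] - sB[shared]))
  res <- list(shared_fraction = length(shared) / length(uni), table = tab,
              slope = NA_real_, intercept = NA_real_, ci = NULL,
              regression_refused = TRUE)
  if (length(shared) >= 3 && stats::sd(tab$strength_a) > 0) {
    fit <- stats::lm(strength_b ~ strength_a, data = tab)
    res$slope <- unname(stats::coef(fit)[2])
    res$intercept <- unname(stats::coef(fit)[1])
    res$ci <- stats::confint(fit, level = 0.95)
    res$regression_refused <- FALSE
  }
  res
}
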