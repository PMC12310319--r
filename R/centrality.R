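centrality_table <- function(labels, metric, raw, exploratory = FALSE,
                             note = NA_character_) {
  degenerate <- sd(raw) == 0
  data.frame(node = labels, metric = metric, raw = as.numeric(raw),
             z = standardize_scores(raw),
             exploratory = exploratory,
             degenerate = degenerate,
             row.names = NULL)
}

#' Strength centrality
#'
#' Sum of absolute edge weights incident to each node, with z-standardised
#' values (population SD) alongside the raw sums.  An empty network yields
#' all-zero raw values and is flagged `degenerate` (standardised values are
#' reported as 0).
#'
#' @param net an [ising_network()].
#' @return A centrality data.frame: node, metric, raw, z, flags.
#' @export
strength <- function(net) {
  stopifnot(inherits(net, "ising_network"))
  s <- rowSums(abs(net$weights))
  centrality_table(net$item_labels, "strength", s)
}

#' Expected influence (one-step, undirected)
#'
#' Signed sum of a node's edge weights; equals strength when all edges are
#' positive.
#'
#' @param net an [ising_network()].
#' @return A centrality data.frame.
#' @export
expected_influence <- function(net) {
  stopifnot(inherits(net, "ising_network"))
  centrality_table(net$item_labels, "expected_influence",
                   rowSums(net$weights))
}

#' Out- and in-expected influence of a cross-lagged network
#'
#' out-EI of node i is the signed sum of its outgoing cross-lagged effects
#' (row i of the coefficient matrix); in-EI of node j is the signed sum of
#' its incoming effects (column j).  Autoregressive loops are excluded by
#' default — out-EI indexes how strongly a symptom at Wave 1 predicts the
#' *other* symptoms at Wave 2.
#'
#' @param net a [clpn_network()].
#' @param include_loops include the autoregressive diagonal in the sums?
#'   Default `FALSE`.
#' @return A centrality data.frame with both metrics stacked.
#' @export
out_in_ei <- function(net, include_loops = FALSE) {
  stopifnot(inherits(net, "clpn_network"))
  B <- net$coefficients
  if (!include_loops) diag(B) <- 0
  rbind(centrality_table(net$item_labels, "out_ei", rowSums(B)),
        centrality_table(net$item_labels, "in_ei", colSums(B)))
}

#' Closeness and betweenness centrality (exploratory)
#'
#' Shortest-path metrics on the weighted graph with edge distances
#' 1/|weight|.  Closeness is 1 over the sum of shortest-path distances to
#' all other nodes; on disconnected graphs the harmonic variant (mean of
#' reciprocal distances, unreachable = 0) is substituted and flagged.
#' Betweenness is the fraction of shortest paths passing through a node.
#' Both are reported for completeness only: shortest-path metrics are
#' unstable in cross-sectional psychopathology networks and should not
#' drive substantive conclusions.
#'
#' @param net an [ising_network()].
#' @return A centrality data.frame with both metrics stacked, marked
#'   exploratory.
#' @export
closeness_betweenness <- function(net) {
  stopifnot(inherits(net, "ising_network"))
  w <- abs(net$weights)
  p <- nrow(w)
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  dist <- if (igraph::ecount(g) > 0) {
    igraph::distances(g, weights = 1 / igraph::E(g)$weight)
  } else {
    d <- matrix(Inf, p, p); diag(d) <- 0; d
  }
  disconnected <- any(!is.finite(dist[upper.tri(dist)]))
  clo <- if (disconnected) {
    # harmonic closeness: unreachable pairs contribute zero
    inv <- 1 / dist
    diag(inv) <- 0
    rowSums(inv) / (p - 1)
  } else {
    1 / rowSums(dist)
  }
  btw <- if (igraph::ecount(g) > 0) {
    igraph::betweenness(g, weights = 1 / igraph::E(g)$weight)
  } else {
    rep(0, p)
  }
  btw <- btw / ((p - 1) * (p - 2) / 2)
  out <- rbind(
    centrality_table(net$item_labels, "closeness", clo, exploratory = TRUE),
    centrality_table(net$item_labels, "betweenness", btw, exploratory = TRUE))
  attr(out, "harmonic_closeness") <- disconnected
  out
}
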