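#' Forward-sample a dataset from a Bayesian network
#'
#' Ancestral sampling: nodes are visited in topological order and each is
#' drawn from its CPT row given the already-sampled parent states. Column
#' order of the result matches the network's node order; the draw is fully
#' reproducible from `seed`.
#'
#' @param network A validated `bn` object.
#' @param n Number of cases to draw (>= 1).
#' @param seed Integer seed.
#' @return A tibble of factors, `n` rows, one column per node.
#' @examples
#' d <- forward_sample(asia_network(), 1000, seed = 1)
#' dplyr::count(d, either)
#' @export
forward_sample <- function(network, n, seed = 1L) {
  validate_bn(network)
  stopifnot(n >= 1L)
  nodes <- network$nodes
  g <- igraph::graph_from_data_frame(
    bn_edges(network), directed = TRUE, vertices = data.frame(name = nodes))
  topo <- names(igraph::topo_sort(g))
  drawn <- stats::setNames(vector("list", length(nodes)), nodes)
  withr::with_seed(seed, {
    for (v in topo) {
      ps <- network$parents[[v]]
      cpt <- network$cpts[[v]]
      r <- length(network$states[[v]])
      if (!length(ps)) {
        st <- sample.int(r, n, replace = TRUE, prob = cpt[1, ])
      } else {
        j <- rep(0L, n)
        for (p in ps) {
          j <- j * length(network$states[[p]]) + (drawn[[p]] - 1L)
        }
        j <- j + 1L
        st <- integer(n)
        for (jj in unique(j)) {
          idx <- which(j == jj)
          st[idx] <- sample.int(r, length(idx), replace = TRUE, prob = cpt[jj, ])
        }
      }
      drawn[[v]] <- st
    }
  })
  out <- purrr::imap(drawn[nodes], function(st, v) {
    factor(network$states[[v]][st], levels = network$states[[v]])
  })
  tibble::as_tibble(out)
}

#' Shuffle dataset columns with a seeded permutation
#'
#' Reproduces the benchmark protocol of randomizing the variable order
#' before learning, so no method can exploit a topologically sorted input.
#' Variable names travel with their columns; the applied permutation is
#' attached as attribute `"permutation"` for later alignment.
#'
#' @param data A data frame.
#' @param seed Integer seed.
#' @return The column-permuted tibble.
#' @export
shuffle_columns <- function(data, seed = 1L) {
  perm <- withr::with_seed(seed, sample.int(ncol(data)))
  out <- tibble::as_tibble(data)[perm]
  attr(out, "permutation") <- perm
  out
}

#' Exact joint distribution of a small Bayesian network
#'
#' Brute-force enumeration of the joint probability over all state
#' combinations, as the product of CPT entries. Exponential in the node
#' count; meant for validating samplers and information measures on tiny
#' networks.
#'
#' @param network A `bn` object (keep it to a handful of nodes).
#' @return A tibble with one column per node plus `prob`.
#' @export
bn_joint <- function(network) {
  validate_bn(network)
  nodes <- network$nodes
  grid <- expand.grid(purrr::map(network$states[nodes], seq_along),
                      KEEP.OUT.ATTRS = FALSE)
  names(grid) <- nodes
  prob <- rep(1, nrow(grid))
  for (v in nodes) {
    ps <- network$parents[[v]]
    j <- rep(0L, nrow(grid))
    for (p in ps) j <- j * length(network$states[[p]]) + (grid[[p]] - 1L)
    prob <- prob * network$cpts[[v]][cbind(j + 1L, grid[[v]])]
  }
  out <- purrr::imap(grid, function(ix, v) {
    factor(network$states[[v]][ix], levels = network$states[[v]])
  })
  dplyr::mutate(tibble::as_tibble(out), prob = prob)
}
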