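#' Construct a discrete Bayesian network
#'
#' A Bayesian network couples a DAG over discrete variables with one
#' conditional probability table (CPT) per node: the joint distribution is
#' the product over nodes of `p(X_i | Pa(X_i))`. CPT rows index parent
#' configurations in mixed-radix order with the last-listed parent varying
#' fastest; columns index the child's states.
#'
#' @param nodes Character vector of node names (defines column order for
#'   sampled data).
#' @param states Named list: per node, the character vector of its states
#'   (arity >= 2).
#' @param parents Named list: per node, the character vector of its parents
#'   (possibly empty), in CPT row order.
#' @param cpts Named list: per node, a `q x r` numeric matrix of
#'   probabilities, `q` the product of parent arities and `r` the node's
#'   arity; each row must sum to 1 within 1e-9.
#' @return An object of class `bn`.
#' @export
bn <- function(nodes, states, parents, cpts) {
  net <- structure(list(nodes = nodes, states = states,
                        parents = parents, cpts = cpts),
                   class = "bn")
  validate_bn(net)
}

#' Validate a Bayesian network object
#'
#' Checks that the edge set is acyclic, that every CPT has one row per
#' parent configuration and one column per child state, and that each row
#' sums to 1 within 1e-9.
#'
#' @param network A `bn` object.
#' @return The network, invisibly usable, after passing all checks.
#' @export
validate_bn <- function(network) {
  stopifnot(inherits(network, "bn"))
  nodes <- network$nodes
  if (!setequal(names(network$states), nodes) ||
      !setequal(names(network$parents), nodes) ||
      !setequal(names(network$cpts), nodes)) {
    rlang::abort("`states`, `parents` and `cpts` must be named by the nodes.")
  }
  for (v in nodes) {
    if (length(network$states[[v]]) < 2L) {
      rlang::abort(paste0("node ", v, " needs at least 2 states."))
    }
    if (!all(network$parents[[v]] %in% nodes)) {
      rlang::abort(paste0("unknown parent for node ", v, "."))
    }
  }
  if (!topological_check(bn_edges(network), nodes)) {
    rlang::abort("the edge set must be acyclic.")
  }
  for (v in nodes) {
    r <- length(network$states[[v]])
    q <- prod(vapply(network$parents[[v]],
                     function(p) length(network$states[[p]]), numeric(1)))
    q <- if (length(network$parents[[v]])) q else 1
    cpt <- network$cpts[[v]]
    if (!is.matrix(cpt) || nrow(cpt) != q || ncol(cpt) != r) {
      rlang::abort(paste0("CPT for ", v, " must be ", q, " x ", r, "."))
    }
    if (any(cpt < 0) || any(abs(rowSums(cpt) - 1) > 1e-9)) {
      rlang::abort(paste0("CPT rows for ", v, " must be probabilities summing to 1."))
    }
  }
  network
}

#' Edge table of a Bayesian network
#'
#' @param network A `bn` object.
#' @return A tibble of directed edges (`from`, `to`).
#' @export
bn_edges <- function(network) {
  rows <- purrr::imap(network$parents, function(ps, child) {
    if (length(ps)) tibble::tibble(from = ps, to = child) else NULL
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) tibble::tibble(from = character(), to = character()) else out
}

#' @export
tidy.bn <- function(x, ...) bn_edges(x)

#' @export
print.bn <- function(x, ...) {
  cat("Discrete Bayesian network:", length(x$nodes), "nodes,",
      nrow(bn_edges(x)), "edges\n")
  cat("  nodes:", paste(x$nodes, collapse = ", "), "\n")
  invisible(x)
}

#' The 8-node ASIA network fixture
#'
#' The classic chest-clinic network (Lauritzen--Spiegelhalter
#' parameterization): a recent visit to Asia and smoking influence
#' tuberculosis, lung cancer and bronchitis; tuberculosis-or-cancer drives
#' the X-ray finding and, with bronchitis, dyspnoea. 8 nodes, 8 edges, all
#' binary. Used as the self-contained simulation benchmark.
#'
#' @return A `bn` object.
#' @examples
#' net <- asia_network()
#' bn_edges(net)
#' @export
asia_network <- function() {
  yn <- c("yes", "no")
  nodes <- c("asia", "tub", "smoke", "lung", "bronc", "either", "xray", "dysp")
  states <- stats::setNames(rep(list(yn), 8), nodes)
  parents <- list(
    asia = character(), tub = "asia", smoke = character(), lung = "smoke",
    bronc = "smoke", either = c("tub", "lung"), xray = "either",
    dysp = c("bronc", "either")
  )
  row2 <- function(p) cbind(yes = p, no = 1 - p)
  cpts <- list(
    asia  = row2(0.01),
    tub   = row2(c(0.05, 0.01)),          # rows: asia = yes, no
    smoke = row2(0.5),
    lung  = row2(c(0.10, 0.01)),          # rows: smoke = yes, no
    bronc = row2(c(0.60, 0.30)),
    either = row2(c(1, 1, 1, 0)),         # rows: (tub,lung) = yy, yn, ny, nn
    xray  = row2(c(0.98, 0.05)),
    dysp  = row2(c(0.90, 0.80, 0.70, 0.10)) # rows: (bronc,either) = yy, yn, ny, nn
  )
  bn(nodes, states, parents, cpts)
}

#' Generate a random Bayesian network
#'
#' Draws a random DAG (random topological order, random parent choices) and
#' CPT rows that place probability mass at least `strength` on one randomly
#' chosen state per row, giving controllable dependence strength. Intended
#' for property tests and simulation studies.
#'
#' @param n_nodes Number of nodes (>= 2).
#' @param max_parents Maximum parents per node.
#' @param arity States per node (>= 2).
#' @param seed Integer seed (only a private stream is used).
#' @param strength Minimum mass on the favoured state of each CPT row, in
#'   (0, 1]; `strength = 1` gives deterministic CPTs.
#' @return A `bn` object.
#' @export
random_network <- function(n_nodes, max_parents = 2L, arity = 2L, seed = 1L,
                           strength = 0.9) {
  stopifnot(n_nodes >= 2L, max_parents >= 0L, arity >= 2L,
            strength > 0, strength <= 1)
  withr::with_seed(seed, {
    nodes <- sprintf("V%02d", seq_len(n_nodes))
    topo <- sample(nodes)
    states <- stats::setNames(rep(list(as.character(seq_len(arity))), n_nodes),
                              nodes)
    parents <- stats::setNames(vector("list", n_nodes), nodes)
    cpts <- stats::setNames(vector("list", n_nodes), nodes)
    for (p in seq_len(n_nodes)) {
      v <- topo[p]
      avail <- topo[seq_len(p - 1L)]
      k <- if (length(avail)) sample(0:min(max_parents, length(avail)), 1L) else 0L
      parents[[v]] <- if (k > 0L) sort(sample(avail, k)) else character()
      q <- arity^k
      cpt <- matrix(0, q, arity)
      for (row in seq_len(q)) {
        peak <- sample.int(arity, 1L)
        rest <- stats::runif(arity)
        rest <- rest / sum(rest) * (1 - strength)
        rest[peak] <- rest[peak] + strength
        cpt[row, ] <- rest
      }
      colnames(cpt) <- states[[v]]
      cpts[[v]] <- cpt
    }
    bn(nodes, states, parents, cpts)
  })
}
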