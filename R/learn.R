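#' Rank candidate edges by mutual information
#'
#' Scores every unordered variable pair by empirical mutual information,
#' drops pairs below the threshold `alpha`, and sorts the survivors by MI,
#' largest first. Ties are broken by column-index pair order, so ranking is
#' deterministic for a given dataset.
#'
#' @param data A discrete dataset with at least two variables.
#' @param alpha MI threshold in bits; pairs with `mi < alpha` are excluded.
#'   The default 1e-4 is the heuristic used throughout the package.
#' @return A tibble with columns `x`, `y` (variable names) and `mi` (bits),
#'   sorted by decreasing `mi`.
#' @export
rank_edges <- function(data, alpha = 1e-4) {
  comp <- if (inherits(data, "dd_compiled")) data else dd_compile(data)
  n <- length(comp$names)
  if (n < 2L) rlang::abort("need at least two variables to rank edges.")
  pairs <- utils::combn(n, 2)
  mi <- vapply(seq_len(ncol(pairs)),
               function(p) mi_idx(comp, pairs[1, p], pairs[2, p]),
               numeric(1))
  keep <- mi >= alpha
  ord <- order(-mi[keep], pairs[1, keep], pairs[2, keep])
  tibble::tibble(
    x = comp$names[pairs[1, keep]][ord],
    y = comp$names[pairs[2, keep]][ord],
    mi = mi[keep][ord]
  )
}

#' Classify a candidate edge against the current skeleton
#'
#' A candidate pair is `"triangle"` when its endpoints already share at
#' least one skeleton neighbour, `"cycle"` when they are connected by some
#' longer skeleton path (adding the edge would close a cycle), and
#' `"plain"` otherwise. A triangle is also a cycle; the triangle label takes
#' precedence.
#'
#' @param skeleton Existing edges as a data frame (`from`, `to`); direction
#'   is ignored.
#' @param pair Character vector of length 2, the candidate endpoints; must
#'   not already be connected.
#' @param nodes Optional node universe.
#' @return One of `"triangle"`, `"cycle"`, `"plain"`.
#' @export
classify_case <- function(skeleton, pair, nodes = NULL) {
  stopifnot(length(pair) == 2L)
  skeleton <- as_edge_df(skeleton)
  if (is.null(nodes)) nodes <- unique(c(skeleton$from, skeleton$to, pair))
  adj <- matrix(FALSE, length(nodes), length(nodes),
                dimnames = list(nodes, nodes))
  if (nrow(skeleton)) {
    adj[cbind(skeleton$from, skeleton$to)] <- TRUE
    adj[cbind(skeleton$to, skeleton$from)] <- TRUE
  }
  i <- match(pair[1], nodes); j <- match(pair[2], nodes)
  if (adj[i, j]) rlang::abort("the candidate pair is already connected.")
  classify_idx(adj, i, j)
}

classify_idx <- function(adj, i, j) {
  if (any(adj[i, ] & adj[j, ])) return("triangle")
  if (skeleton_connected(adj, i, j)) return("cycle")
  "plain"
}

# --- learner state ---------------------------------------------------------
# A mutable environment holding the compiled data, the skeleton adjacency
# (symmetric logical), the directed subgraph, the trustworthy marks and the
# tie-break RNG (a small private LCG so the global RNG is never touched).

new_learn_state <- function(comp, alpha, ci_alpha, seed, mi) {
  n <- length(comp$names)
  st <- new.env(parent = emptyenv())
  st$comp <- comp
  st$n <- n
  st$adj <- matrix(FALSE, n, n)
  st$dirmat <- matrix(FALSE, n, n)
  st$trust <- matrix(FALSE, n, n)
  st$alpha <- alpha
  st$ci_alpha <- ci_alpha
  st$mi <- mi
  st$rng <- (as.integer(seed) %% 2147483647L) + 1
  st
}

rng_pick <- function(st, k) {
  st$rng <- (st$rng * 69069 + 1) %% 2147483648
  (st$rng %% k) + 1L
}

# Direct edge a -> b, marking it trustworthy. Refuses (returning FALSE) when
# the skeleton edge is absent, already directed the other way, or when the
# direction would close a directed cycle.
st_orient <- function(st, a, b) {
  if (!st$adj[a, b]) return(FALSE)
  if (st$dirmat[b, a]) return(FALSE)
  if (!st$dirmat[a, b]) {
    st$dirmat[a, b] <- TRUE
    if (!directed_acyclic(st$dirmat)) {
      st$dirmat[a, b] <- FALSE
      return(FALSE)
    }
  }
  st$trust[a, b] <- TRUE
  TRUE
}

st_connect <- function(st, i, j) {
  st$adj[i, j] <- TRUE
  st$adj[j, i] <- TRUE
}

st_delete <- function(st, i, j) {
  st$adj[i, j] <- FALSE
  st$adj[j, i] <- FALSE
  st$dirmat[i, j] <- FALSE
  st$dirmat[j, i] <- FALSE
  st$trust[i, j] <- FALSE
  st$trust[j, i] <- FALSE
}

# Can the pattern a - b - c be oriented head-to-head at b without
# contradicting an already-fixed direction or closing a directed cycle?
# (Edges of the pattern that are not yet in the skeleton are fine: this is
# used while the candidate edge is still pending.)
orientable_collider <- function(st, a, b, c) {
  if (st$dirmat[b, a] || st$dirmat[b, c]) return(FALSE)
  saved <- st$dirmat
  st$dirmat[a, b] <- TRUE
  st$dirmat[c, b] <- TRUE
  ok <- directed_acyclic(st$dirmat)
  st$dirmat <- saved
  ok
}

# Try to orient the two-edge pattern a - b - c head-to-head at b when the
# immorality test says the collider fits strictly better.
imm_orient <- function(st, a, b, c) {
  v <- imm_test_idx(st$comp, a, b, c)
  if (v == "IMMORAL") {
    st_orient(st, a, b)
    st_orient(st, c, b)
    TRUE
  } else {
    FALSE
  }
}

# --- the three per-edge decision rules -------------------------------------

# Triangle case: the candidate (i, j) shares >= 1 neighbour k. For each
# induced triangle (ascending column order of k) the three edges are tested
# for conditional independence, each given the opposite node. Exactly one
# independent pair identifies the superfluous edge, which is removed (or the
# candidate declined when it is itself the independent pair); any other
# outcome declines the candidate. In every branch an immorality test on the
# two surviving edges may then fix their direction. The candidate must
# survive every induced triangle to be connected.
resolve_triangle <- function(st, i, j) {
  ks <- which(st$adj[i, ] & st$adj[j, ])
  connected <- TRUE
  deleted <- character()
  pending <- list()
  notes <- character()
  for (k in ks) {
    if (!(st$adj[i, k] && st$adj[j, k])) next # removed by an earlier triangle
    ind_ij <- ci_idx(st$comp, i, j, k, st$ci_alpha)
    ind_jk <- ci_idx(st$comp, j, k, i, st$ci_alpha)
    ind_ki <- ci_idx(st$comp, k, i, j, st$ci_alpha)
    n_ind <- sum(ind_ij, ind_jk, ind_ki)
    nm <- st$comp$names
    if (n_ind == 1L && ind_ij) {
      connected <- FALSE
      oriented <- imm_orient(st, i, k, j)
      notes <- c(notes, paste0("independent given ", nm[k],
                               if (oriented) "; remaining edges oriented"))
      break
    } else if (n_ind == 1L && ind_jk) {
      st_delete(st, j, k)
      deleted <- c(deleted, paste0(nm[j], "--", nm[k]))
      pending <- c(pending, list(c(j, i, k)))
    } else if (n_ind == 1L && ind_ki) {
      st_delete(st, k, i)
      deleted <- c(deleted, paste0(nm[k], "--", nm[i]))
      pending <- c(pending, list(c(i, j, k)))
    } else {
      connected <- FALSE
      oriented <- imm_orient(st, i, k, j)
      notes <- c(notes, paste0(n_ind, " independent pairs in triangle with ",
                               nm[k], if (oriented) "; remaining edges oriented"))
      break
    }
  }
  if (connected) {
    st_connect(st, i, j)
    oriented_any <- FALSE
    for (p in pending) {
      oriented_any <- imm_orient(st, p[1], p[2], p[3]) || oriented_any
    }
    action <- if (length(deleted)) "deleted_other"
      else if (oriented_any) "connected_oriented" else "connected"
    details <- paste(c(
      if (length(deleted)) paste0("deleted ", paste(deleted, collapse = ", ")),
      if (oriented_any) "oriented by immorality test"), collapse = "; ")
    list(action = action, details = details)
  } else {
    list(action = "skipped", details = paste(notes, collapse = "; "))
  }
}

# Cycle case: the candidate (i, j) closes a skeleton cycle, which a DAG can
# only accommodate through at least one head-to-head collision. Each
# existing skeleton edge incident to i or j is paired with the candidate and
# tested for immorality; no collision declines the edge, exactly one
# connects and orients it head-to-head, and several collisions are resolved
# by a seeded uniform choice. A collision whose head-to-head orientation is
# unrealizable — the existing edge is already fixed the other way, or the
# arrows would close a directed cycle — cannot justify the candidate and is
# not counted.
resolve_cycle <- function(st, i, j) {
  nm <- st$comp$names
  hits <- list()
  for (h in which(st$adj[i, ])) {
    if (h == j) next
    if (orientable_collider(st, h, i, j) &&
        imm_test_idx(st$comp, h, i, j) == "IMMORAL") {
      hits <- c(hits, list(c(h, i, j)))
    }
  }
  for (k in which(st$adj[j, ])) {
    if (k == i) next
    if (orientable_collider(st, i, j, k) &&
        imm_test_idx(st$comp, i, j, k) == "IMMORAL") {
      hits <- c(hits, list(c(i, j, k)))
    }
  }
  if (!length(hits)) {
    return(list(action = "skipped", details = "no immorality found on the cycle"))
  }
  pick <- if (length(hits) > 1L) rng_pick(st, length(hits)) else 1L
  ch <- hits[[pick]]
  st_connect(st, i, j)
  st_orient(st, ch[1], ch[2])
  st_orient(st, ch[3], ch[2])
  list(action = "connected_oriented",
       details = paste0("collider ", nm[ch[1]], "->", nm[ch[2]], "<-", nm[ch[3]],
                        if (length(hits) > 1L)
                          paste0(" (chosen among ", length(hits), ")")))
}

# Plain case: the candidate closes neither a triangle nor a cycle and is
# connected without a connection test. Orientation only: every two-edge path
# completed by the new edge whose outer pair is marginally independent (MI
# below the candidate threshold — an unshielded pattern that will never be
# revisited as a triangle) is offered to the immorality test and oriented
# head-to-head when the collider wins. This is how an isolated v-structure
# a -> b <- c with independent a, c gets its direction: the pair (a, c) is
# never a candidate edge, so no triangle or cycle would ever examine it.
resolve_plain <- function(st, i, j) {
  st_connect(st, i, j)
  nm <- st$comp$names
  oriented <- character()
  for (h in which(st$adj[i, ])) {
    if (h == j) next
    if (st$mi[h, j] < st$alpha && orientable_collider(st, h, i, j) &&
        imm_test_idx(st$comp, h, i, j) == "IMMORAL") {
      st_orient(st, h, i)
      st_orient(st, j, i)
      oriented <- c(oriented, paste0(nm[h], "->", nm[i], "<-", nm[j]))
    }
  }
  for (k in which(st$adj[j, ])) {
    if (k == i) next
    if (st$mi[i, k] < st$alpha && orientable_collider(st, i, j, k) &&
        imm_test_idx(st$comp, i, j, k) == "IMMORAL") {
      st_orient(st, i, j)
      st_orient(st, k, j)
      oriented <- c(oriented, paste0(nm[i], "->", nm[j], "<-", nm[k]))
    }
  }
  if (length(oriented)) {
    list(action = "connected_oriented",
         details = paste("collider", paste(oriented, collapse = ", ")))
  } else {
    list(action = "connected", details = "")
  }
}

# --- the single-pass learner ----------------------------------------------

#' Learn a partially directed network by MI ordering, CI and immorality tests
#'
#' Starting from the empty graph, every unordered variable pair is scored by
#' mutual information; pairs below `alpha` are discarded and the rest are
#' visited exactly once, in decreasing MI order. Each candidate is
#' classified against the current skeleton ([classify_case()]) and resolved
#' by the matching rule: triangles run conditional-independence tests to
#' drop the superfluous edge, cycles demand an immorality to justify the
#' closing edge, and plain edges are connected without a test. Orientations
#' come only from MDL immorality tests; the so-oriented edges form the
#' trustworthy network. The output is therefore a partially directed graph:
#' reliable rather than complete, with no direction guessed for edges the
#' tests cannot decide.
#'
#' @param data A discrete dataset (>= 2 variables).
#' @param alpha MI threshold in bits (default 1e-4).
#' @param ci_alpha Significance level of the G-squared CI test (default 0.05).
#' @param seed Integer seed for the one random choice the algorithm can face
#'   (several immoralities justifying a cycle-closing edge). A private
#'   generator is used; the global RNG stream is untouched.
#' @return An object of class `mici_fit` with elements `nodes`, `edges` (a
#'   tibble `from`, `to`, `directed`, `trustworthy`), `trace` (one row per
#'   candidate pair: `x`, `y`, `mi`, `case`, `action`, `details`) and
#'   `config`. Use [tidy()] for the edge table, [glance()] for a one-row
#'   summary, [autoplot()] to draw the graph.
#' @examples
#' net <- asia_network()
#' d <- forward_sample(net, 2000, seed = 1)
#' fit <- mici_learn(d)
#' tidy(fit)
#' @export
mici_learn <- function(data, alpha = 1e-4, ci_alpha = 0.05, seed = 1L) {
  if (alpha < 0) rlang::abort("`alpha` must be non-negative.")
  if (!(ci_alpha > 0 && ci_alpha < 1)) {
    rlang::abort("`ci_alpha` must lie strictly between 0 and 1.")
  }
  comp <- if (inherits(data, "dd_compiled")) data else dd_compile(data)
  n <- length(comp$names)
  if (n < 2L) rlang::abort("need at least two variables to learn a structure.")

  pairs <- utils::combn(n, 2)
  mi <- vapply(seq_len(ncol(pairs)),
               function(p) mi_idx(comp, pairs[1, p], pairs[2, p]),
               numeric(1))
  mi_mat <- matrix(0, n, n)
  mi_mat[t(pairs)] <- mi
  mi_mat[t(pairs)[, 2:1, drop = FALSE]] <- mi
  st <- new_learn_state(comp, alpha, ci_alpha, seed, mi_mat)
  keep <- which(mi >= alpha)
  ord <- keep[order(-mi[keep], pairs[1, keep], pairs[2, keep])]
  below <- setdiff(seq_len(ncol(pairs)), keep)

  trace <- vector("list", ncol(pairs))
  for (t in seq_along(ord)) {
    p <- ord[t]
    i <- pairs[1, p]; j <- pairs[2, p]
    case <- classify_idx(st$adj, i, j)
    res <- switch(case,
      triangle = resolve_triangle(st, i, j),
      cycle = resolve_cycle(st, i, j),
      plain = resolve_plain(st, i, j)
    )
    trace[[t]] <- tibble::tibble(x = comp$names[i], y = comp$names[j],
                                 mi = mi[p], case = case,
                                 action = res$action, details = res$details)
  }
  trace_below <- tibble::tibble(
    x = comp$names[pairs[1, below]], y = comp$names[pairs[2, below]],
    mi = mi[below], case = "below_threshold", action = "skipped", details = ""
  )
  trace <- dplyr::bind_rows(c(trace[seq_along(ord)], list(trace_below)))

  edges <- edges_from_state(st)
  structure(
    list(nodes = comp$names, edges = edges, trace = trace,
         config = list(alpha = alpha, ci_alpha = ci_alpha, seed = seed),
         n_obs = comp$n, n_vars = n),
    class = "mici_fit"
  )
}

edges_from_state <- function(st) {
  nm <- st$comp$names
  rows <- list()
  for (i in seq_len(st$n - 1L)) {
    for (j in seq(i + 1L, st$n)) {
      if (!st$adj[i, j]) next
      if (st$dirmat[i, j]) {
        rows <- c(rows, list(tibble::tibble(from = nm[i], to = nm[j],
                                            directed = TRUE,
                                            trustworthy = st$trust[i, j])))
      } else if (st$dirmat[j, i]) {
        rows <- c(rows, list(tibble::tibble(from = nm[j], to = nm[i],
                                            directed = TRUE,
                                            trustworthy = st$trust[j, i])))
      } else {
        rows <- c(rows, list(tibble::tibble(from = nm[i], to = nm[j],
                                            directed = FALSE,
                                            trustworthy = FALSE)))
      }
    }
  }
  if (!length(rows)) {
    return(tibble::tibble(from = character(), to = character(),
                          directed = logical(), trustworthy = logical()))
  }
  dplyr::bind_rows(rows)
}

#' @export
print.mici_fit <- function(x, ...) {
  cat("Partially directed network learned from", x$n_obs, "cases of",
      x$n_vars, "variables\n")
  cat("  edges:", nrow(x$edges),
      "(", sum(x$edges$directed), "directed,",
      sum(x$edges$trustworthy), "trustworthy )\n")
  cat("  alpha =", x$config$alpha, " CI significance =", x$config$ci_alpha, "\n")
  invisible(x)
}

#' Tidy the edge table of a learned network
#'
#' @param x A `mici_fit`.
#' @param ... Unused.
#' @return The tibble of edges with `from`, `to`, `directed`, `trustworthy`.
#' @export
tidy.mici_fit <- function(x, ...) x$edges

#' One-row summary of a learned network
#'
#' @param x A `mici_fit`.
#' @param ... Unused.
#' @return A tibble with node/edge counts, the trustworthy-edge count and
#'   the learner settings.
#' @export
glance.mici_fit <- function(x, ...) {
  tibble::tibble(
    n_vars = x$n_vars, n_obs = x$n_obs,
    n_edges = nrow(x$edges),
    n_directed = sum(x$edges$directed),
    n_trustworthy = sum(x$edges$trustworthy),
    alpha = x$config$alpha, ci_alpha = x$config$ci_alpha
  )
}

#' Plot a learned network
#'
#' Draws the mixed graph with directed edges as arrows; trustworthy edges
#' (those oriented by immorality tests) are highlighted in red, matching the
#' usual presentation of trusted sub-networks.
#'
#' @param object A `mici_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mici_fit <- function(object, ...) {
  nodes <- object$nodes
  g <- igraph::graph_from_data_frame(
    if (nrow(object$edges)) object$edges[, c("from", "to")]
    else data.frame(from = character(), to = character()),
    directed = FALSE, vertices = data.frame(name = nodes))
  xy <- igraph::layout_with_fr(g)
  lay <- tibble::tibble(name = nodes, x = xy[, 1], y = xy[, 2])
  ed <- dplyr::left_join(object$edges, lay, by = c("from" = "name"))
  ed <- dplyr::left_join(ed, lay, by = c("to" = "name"),
                         suffix = c("", "end"))
  gg <- ggplot2::ggplot()
  if (nrow(ed)) {
    und <- ed[!ed$directed, ]
    dir <- ed[ed$directed, ]
    if (nrow(und)) {
      gg <- gg + ggplot2::geom_segment(
        data = und,
        ggplot2::aes(x = .data$x, y = .data$y,
                     xend = .data$xend, yend = .data$yend),
        colour = "grey40")
    }
    if (nrow(dir)) {
      gg <- gg + ggplot2::geom_segment(
        data = dir,
        ggplot2::aes(x = .data$x, y = .data$y,
                     xend = .data$xend, yend = .data$yend,
                     colour = .data$trustworthy),
        arrow = ggplot2::arrow(length = ggplot2::unit(0.03, "npc"),
                               type = "closed"))
    }
  }
  gg +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "red", `FALSE` = "grey40"),
                                 name = "trustworthy") +
    ggplot2::geom_label(data = lay,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     label = .data$name)) +
    ggplot2::theme_void()
}
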