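#' Coerce a data frame to a discrete dataset
#'
#' A discrete dataset is a data frame of factors: one row per observed case,
#' one column per variable, every cell a state label. Character and numeric
#' columns are converted to factors whose levels follow first-appearance
#' order, so state-to-index mappings are reproducible from the raw file
#' alone. Existing factors keep their level order (this is how a declared
#' arity larger than the observed one is expressed).
#'
#' @param x A data frame (or tibble) of state labels.
#' @return A tibble in which every column is a factor.
#' @examples
#' as_discrete_data(data.frame(a = c("y", "n", "y"), b = c(0, 1, 1)))
#' @export
as_discrete_data <- function(x) {
  if (!is.data.frame(x)) {
    rlang::abort("`x` must be a data frame of discrete state labels.")
  }
  if (nrow(x) < 1L) {
    rlang::abort("a discrete dataset needs at least one row.")
  }
  out <- purrr::map(x, function(col) {
    if (anyNA(col)) {
      rlang::abort("missing values are not supported in discrete datasets.")
    }
    if (is.factor(col)) col else factor(col, levels = unique(as.character(col)))
  })
  tibble::as_tibble(out)
}

#' Read a discrete dataset from a delimited text file
#'
#' Expects a header row of variable names and one row per sample; values are
#' arbitrary state labels. The delimiter defaults to tab, or comma for
#' `.csv` paths.
#'
#' @param path File path.
#' @param delim Field delimiter; guessed from the extension when `NULL`.
#' @return A tibble of factors (see [as_discrete_data()]).
#' @export
read_discrete_data <- function(path, delim = NULL) {
  if (is.null(delim)) {
    delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                           progress = FALSE)
  as_discrete_data(raw)
}

# Compiled form used by all counting code: 1-based integer state matrix plus
# per-column arities. Everything downstream (MI, CI, MDL) works off this.
dd_compile <- function(data) {
  data <- as_discrete_data(data)
  cols <- purrr::map(data, as.integer)
  values <- do.call(cbind, cols)
  structure(
    list(
      values  = values,
      arities = unname(vapply(data, nlevels, integer(1))),
      states  = purrr::map(data, levels),
      names   = names(data),
      n       = nrow(data)
    ),
    class = "dd_compiled"
  )
}

dd_var_index <- function(comp, var) {
  if (is.character(var)) {
    idx <- match(var, comp$names)
    if (anyNA(idx)) {
      rlang::abort(paste0("unknown variable(s): ",
                          paste(var[is.na(idx)], collapse = ", ")))
    }
    idx
  } else {
    var <- as.integer(var)
    if (any(var < 1L | var > length(comp$names))) {
      rlang::abort("variable index out of range.")
    }
    var
  }
}

# Mixed-radix parent-configuration index, last-listed parent varying fastest
# (first parent most significant). Returns 1-based configuration per row.
parent_config_index <- function(comp, parents) {
  n <- comp$n
  if (length(parents) == 0L) return(rep(1L, n))
  j <- rep(0L, n)
  for (p in parents) {
    j <- j * comp$arities[p] + (comp$values[, p] - 1L)
  }
  j + 1L
}

#' Contingency counts for a child given a parent set
#'
#' Tallies `N_ijk`, the number of cases in which the child takes state `k`
#' while the parents sit in their `j`-th joint configuration, along with the
#' row totals `N_ij`. Parent configurations are enumerated in mixed-radix
#' order with the last-listed parent varying fastest; this ordering is fixed
#' so MDL scores are bit-for-bit reproducible.
#'
#' @param data A discrete dataset (data frame of factors).
#' @param child Child variable (name or column index).
#' @param parents Parent variables (names or indices); may be empty.
#' @return An object of class `contingency_counts`: a list with `child`,
#'   `parents`, the `q x r` count matrix `n_ijk` (rows are parent
#'   configurations), the row totals `n_ij`, and the sample count `n`.
#' @examples
#' d <- as_discrete_data(data.frame(p = c(0, 0, 1, 1), x = c(0, 1, 1, 1)))
#' count_contingency(d, "x", "p")
#' @export
count_contingency <- function(data, child, parents = character()) {
  comp <- if (inherits(data, "dd_compiled")) data else dd_compile(data)
  child <- dd_var_index(comp, child)
  parents <- if (length(parents)) dd_var_index(comp, parents) else integer()
  if (child %in% parents) {
    rlang::abort("`child` must not appear in `parents`.")
  }
  r <- comp$arities[child]
  q <- if (length(parents)) prod(comp$arities[parents]) else 1L
  j <- parent_config_index(comp, parents)
  k <- comp$values[, child]
  tab <- tabulate((j - 1L) * r + k, nbins = q * r)
  n_ijk <- matrix(tab, nrow = q, ncol = r, byrow = TRUE)
  colnames(n_ijk) <- comp$states[[child]]
  structure(
    list(child = comp$names[child], parents = comp$names[parents],
         n_ijk = n_ijk, n_ij = rowSums(n_ijk), n = comp$n),
    class = "contingency_counts"
  )
}

#' @export
print.contingency_counts <- function(x, ...) {
  cat("Contingency counts: ", x$child,
      if (length(x$parents)) paste0(" | ", paste(x$parents, collapse = ", ")),
      "  (N = ", x$n, ")\n", sep = "")
  print(x$n_ijk)
  invisible(x)
}

#' Test whether a directed edge set is acyclic
#'
#' @param edges A data frame with columns `from` and `to` (or a two-column
#'   matrix), or an empty edge set.
#' @param nodes Character vector of node names; defaults to the nodes
#'   mentioned in `edges`.
#' @return `TRUE` iff the directed graph has no directed cycle.
#' @examples
#' topological_check(data.frame(from = "A", to = "B"))
#' @export
topological_check <- function(edges, nodes = NULL) {
  edges <- as_edge_df(edges)
  if (is.null(nodes)) nodes <- unique(c(edges$from, edges$to))
  if (nrow(edges) == 0L) return(TRUE)
  g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                     vertices = data.frame(name = nodes))
  igraph::is_dag(g)
}

as_edge_df <- function(edges) {
  if (is.null(edges) || (is.data.frame(edges) && nrow(edges) == 0L) ||
      (!is.data.frame(edges) && length(edges) == 0L)) {
    return(tibble::tibble(from = character(), to = character()))
  }
  if (is.matrix(edges)) {
    edges <- tibble::tibble(from = as.character(edges[, 1]),
                            to = as.character(edges[, 2]))
  }
  stopifnot(is.data.frame(edges), all(c("from", "to") %in% names(edges)))
  tibble::tibble(from = as.character(edges$from), to = as.character(edges$to))
}

#' Would adding an edge close a cycle in the skeleton?
#'
#' The skeleton view treats directed and undirected edges alike as
#' undirected; the candidate closes a cycle iff its endpoints are already
#' connected by some skeleton path.
#'
#' @param skeleton A data frame of existing edges (`from`, `to`), direction
#'   ignored.
#' @param pair Character vector of length 2: the candidate edge endpoints.
#' @param nodes Optional node universe.
#' @return `TRUE` iff the endpoints are already connected.
#' @export
would_create_cycle <- function(skeleton, pair, nodes = NULL) {
  stopifnot(length(pair) == 2L)
  if (pair[1] == pair[2]) rlang::abort("self-loop candidates are not allowed.")
  skeleton <- as_edge_df(skeleton)
  if (is.null(nodes)) nodes <- unique(c(skeleton$from, skeleton$to, pair))
  adj <- matrix(FALSE, length(nodes), length(nodes),
                dimnames = list(nodes, nodes))
  if (nrow(skeleton)) {
    adj[cbind(skeleton$from, skeleton$to)] <- TRUE
    adj[cbind(skeleton$to, skeleton$from)] <- TRUE
  }
  skeleton_connected(adj, match(pair[1], nodes), match(pair[2], nodes))
}

# BFS over a symmetric logical adjacency matrix.
skeleton_connected <- function(adj, i, j) {
  n <- nrow(adj)
  seen <- logical(n)
  queue <- i
  seen[i] <- TRUE
  while (length(queue)) {
    v <- queue[1]
    queue <- queue[-1]
    nb <- which(adj[v, ] & !seen)
    if (j %in% nb) return(TRUE)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  FALSE
}

# Directed-cycle check on a logical adjacency matrix (internal hot path;
# exported topological_check goes through igraph instead).
directed_acyclic <- function(dirmat) {
  n <- nrow(dirmat)
  indeg <- colSums(dirmat)
  alive <- rep(TRUE, n)
  repeat {
    src <- which(alive & indeg == 0)
    if (!length(src)) break
    for (v in src) {
      alive[v] <- FALSE
      ch <- which(dirmat[v, ])
      indeg[ch] <- indeg[ch] - 1L
    }
  }
  !any(alive)
}
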