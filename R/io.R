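# Network serialization: a small JSON format (canonical for this package),
# a reader/writer for the BIF subset that covers the standard published
# networks (discrete variables, `table` or per-configuration probability
# rows), and a DOT exporter for mixed graphs.

#' Write a Bayesian network to JSON
#'
#' The format stores nodes with ordered state lists, the directed edge set,
#' and per-node CPTs as row lists keyed by parent order (mixed-radix, last
#' parent fastest) — everything needed to reconstruct the network exactly.
#'
#' @param network A `bn` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bn_json <- function(network, path) {
  validate_bn(network)
  obj <- list(
    nodes = purrr::map(network$nodes, function(v) {
      list(name = v, states = network$states[[v]])
    }),
    edges = purrr::pmap(bn_edges(network), function(from, to) c(from, to)),
    cpts = purrr::map(stats::setNames(network$nodes, network$nodes), function(v) {
      list(parents = network$parents[[v]],
           table = apply(network$cpts[[v]], 1, identity, simplify = FALSE))
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a Bayesian network from JSON
#'
#' @param path Path to a file written by [write_bn_json()].
#' @return A validated `bn` object.
#' @export
read_bn_json <- function(path) {
  obj <- jsonlite::read_json(path)
  nodes <- vapply(obj$nodes, function(x) x$name, character(1))
  states <- stats::setNames(
    purrr::map(obj$nodes, function(x) unlist(x$states)), nodes)
  parents <- stats::setNames(rep(list(character()), length(nodes)), nodes)
  cpts <- stats::setNames(vector("list", length(nodes)), nodes)
  for (v in nodes) {
    entry <- obj$cpts[[v]]
    parents[[v]] <- as.character(unlist(entry$parents))
    cpt <- do.call(rbind, purrr::map(entry$table, unlist))
    colnames(cpt) <- states[[v]]
    cpts[[v]] <- cpt
  }
  bn(nodes, states, parents, cpts)
}

#' Read a Bayesian network from a BIF file (discrete subset)
#'
#' Parses the subset of the Bayesian Interchange Format used by the
#' standard published networks: `variable` blocks with discrete state
#' lists, and `probability` blocks given either as `table` lines (parent
#' configurations iterated with the last parent fastest, child states
#' fastest of all) or as one `(state, ...)` row per parent configuration.
#' Properties and comments are ignored.
#'
#' @param path Path to a `.bif` file.
#' @return A validated `bn` object.
#' @export
read_bif <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  txt <- gsub("//[^\n]*", "", txt)
  nodes <- character()
  states <- list()
  parents <- list()
  cpts <- list()

  var_pat <- "variable\\s+(\"[^\"]+\"|[^\\s{]+)\\s*\\{([^}]*\\{[^}]*\\}[^}]*)\\}"
  m <- gregexpr(var_pat, txt, perl = TRUE)
  for (block in regmatches(txt, m)[[1]]) {
    name <- sub(var_pat, "\\1", regmatches(block, regexpr(var_pat, block, perl = TRUE)),
                perl = TRUE)
    name <- gsub('"', "", name)
    inner <- regmatches(block, regexpr("type\\s+discrete[^{]*\\{([^}]*)\\}", block, perl = TRUE))
    if (!length(inner)) rlang::abort(paste0("no discrete type for variable ", name))
    sts <- sub(".*\\{([^}]*)\\}.*", "\\1", inner)
    sts <- trimws(strsplit(sts, ",")[[1]])
    sts <- gsub('"', "", sts)
    nodes <- c(nodes, name)
    states[[name]] <- sts
  }

  prob_pat <- "probability\\s*\\(([^)]*)\\)\\s*\\{([^}]*)\\}"
  m <- gregexpr(prob_pat, txt, perl = TRUE)
  for (block in regmatches(txt, m)[[1]]) {
    head <- sub(prob_pat, "\\1", block, perl = TRUE)
    body <- sub(prob_pat, "\\2", block, perl = TRUE)
    head_parts <- strsplit(head, "\\|")[[1]]
    child <- gsub('"', "", trimws(head_parts[1]))
    ps <- if (length(head_parts) > 1) {
      gsub('"', "", trimws(strsplit(head_parts[2], ",")[[1]]))
    } else {
      character()
    }
    parents[[child]] <- ps
    r <- length(states[[child]])
    q <- if (length(ps)) prod(vapply(ps, function(p) length(states[[p]]), numeric(1))) else 1
    cpt <- matrix(NA_real_, q, r)
    tab <- regmatches(body, regexpr("table([^;]*);", body, perl = TRUE))
    if (length(tab)) {
      vals <- as.numeric(trimws(strsplit(sub("table(.*);", "\\1", tab), ",")[[1]]))
      if (length(vals) != q * r) {
        rlang::abort(paste0("table for ", child, " has ", length(vals),
                            " values, expected ", q * r, "."))
      }
      cpt <- matrix(vals, nrow = q, ncol = r, byrow = TRUE)
    } else {
      row_pat <- "\\(([^)]*)\\)([^;]*);"
      rm <- gregexpr(row_pat, body, perl = TRUE)
      for (row in regmatches(body, rm)[[1]]) {
        cfg <- trimws(strsplit(sub(row_pat, "\\1", row, perl = TRUE), ",")[[1]])
        cfg <- gsub('"', "", cfg)
        vals <- as.numeric(trimws(strsplit(sub(row_pat, "\\2", row, perl = TRUE), ",")[[1]]))
        j <- 0L
        for (pidx in seq_along(ps)) {
          sidx <- match(cfg[pidx], states[[ps[pidx]]])
          if (is.na(sidx)) {
            rlang::abort(paste0("unknown state ", cfg[pidx], " for parent ",
                                ps[pidx], " of ", child, "."))
          }
          j <- j * length(states[[ps[pidx]]]) + (sidx - 1L)
        }
        cpt[j + 1L, ] <- vals
      }
      if (anyNA(cpt)) {
        rlang::abort(paste0("missing CPT rows for ", child, "."))
      }
    }
    colnames(cpt) <- states[[child]]
    cpts[[child]] <- cpt
  }
  missing <- setdiff(nodes, names(cpts))
  if (length(missing)) {
    rlang::abort(paste0("no probability block for: ", paste(missing, collapse = ", ")))
  }
  bn(nodes, states, parents[nodes], cpts[nodes])
}

#' Write a Bayesian network to BIF
#'
#' Writes the same discrete subset that [read_bif()] reads, using one
#' `(state, ...)` row per parent configuration.
#'
#' @param network A `bn` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bif <- function(network, path) {
  validate_bn(network)
  out <- c("network unknown {", "}")
  for (v in network$nodes) {
    sts <- network$states[[v]]
    out <- c(out,
             paste0("variable ", v, " {"),
             paste0("  type discrete [ ", length(sts), " ] { ",
                    paste(sts, collapse = ", "), " };"),
             "}")
  }
  for (v in network$nodes) {
    ps <- network$parents[[v]]
    cpt <- network$cpts[[v]]
    if (!length(ps)) {
      out <- c(out,
               paste0("probability ( ", v, " ) {"),
               paste0("  table ", paste(format(cpt[1, ], trim = TRUE, digits = 17),
                                        collapse = ", "), ";"),
               "}")
    } else {
      out <- c(out, paste0("probability ( ", v, " | ", paste(ps, collapse = ", "), " ) {"))
      cfg_grid <- expand.grid(rev(purrr::map(ps, function(p) network$states[[p]])),
                              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
      cfg_grid <- cfg_grid[, rev(seq_along(ps)), drop = FALSE] # back to parent order
      for (row in seq_len(nrow(cpt))) {
        out <- c(out, paste0("  (", paste(unlist(cfg_grid[row, ]), collapse = ", "),
                             ") ", paste(format(cpt[row, ], trim = TRUE, digits = 17),
                                         collapse = ", "), ";"))
      }
      out <- c(out, "}")
    }
  }
  writeLines(out, path)
  invisible(path)
}

#' Export a network to Graphviz DOT
#'
#' Directed edges are drawn as arrows, undirected ones as lines
#' (`dir=none`), and trustworthy edges are flagged with `trust=true` and
#' coloured red.
#'
#' @param x A `mici_fit` or `bn` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dot <- function(x, path) {
  if (inherits(x, "bn")) {
    edges <- dplyr::mutate(bn_edges(x), directed = TRUE, trustworthy = FALSE)
    nodes <- x$nodes
  } else if (inherits(x, "mici_fit")) {
    edges <- x$edges
    nodes <- x$nodes
  } else {
    rlang::abort("`x` must be a `bn` or `mici_fit` object.")
  }
  lines <- c("digraph network {",
             paste0("  \"", nodes, "\";"))
  if (nrow(edges)) {
    attrs <- ifelse(edges$trustworthy, " [color=red, trust=true]",
                    ifelse(edges$directed, "", " [dir=none]"))
    lines <- c(lines, paste0("  \"", edges$from, "\" -> \"", edges$to, "\"",
                             attrs, ";"))
  }
  lines <- c(lines, "}")
  writeLines(lines, path)
  invisible(path)
}

#' Write an edge-decision trace to TSV
#'
#' @param fit A `mici_fit`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(fit, path) {
  stopifnot(inherits(fit, "mici_fit"))
  readr::write_tsv(fit$trace, path)
  invisible(path)
}
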