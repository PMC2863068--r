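pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

#' Compare a predicted network against the true network
#'
#' Skeleton errors are counted direction-free: a missed edge (ME) is a true
#' edge whose unordered pair is absent from the prediction, a wrong edge
#' (WE) is a predicted pair absent from the truth. Wrongly oriented edges
#' (WOE) are only meaningful for fully directed predictions (the
#' hill-climbing baseline) and are reported as `NA` otherwise, matching the
#' "n/a" convention for partially directed output. The trustworthy network
#' is scored separately: NETN is its size and CETN the number of its edges
#' matching a true edge with identical direction; accuracy is CETN/NETN
#' (`NA` when NETN = 0 rather than a silent 0).
#'
#' @param predicted A `mici_fit`, or a data frame of edges with columns
#'   `from`, `to` and optionally `directed` (default `TRUE`) and
#'   `trustworthy` (default `FALSE`).
#' @param truth A `bn` object or a data frame of true directed edges.
#' @param nodes Optional node universe; defaults to the truth's nodes. The
#'   predicted and true node sets must agree.
#' @return A one-row tibble: `me`, `we`, `woe`, `netn`, `cetn`, `accuracy`.
#' @export
compare_networks <- function(predicted, truth, nodes = NULL) {
  if (inherits(predicted, "mici_fit")) {
    pred_edges <- predicted$edges
    pred_nodes <- predicted$nodes
  } else {
    pred_edges <- tibble::as_tibble(predicted)
    if (!"directed" %in% names(pred_edges)) pred_edges$directed <- TRUE
    if (!"trustworthy" %in% names(pred_edges)) pred_edges$trustworthy <- FALSE
    pred_nodes <- nodes
  }
  if (inherits(truth, "bn")) {
    true_edges <- bn_edges(truth)
    true_nodes <- truth$nodes
  } else {
    true_edges <- as_edge_df(truth)
    true_nodes <- nodes
  }
  if (!is.null(pred_nodes) && !is.null(true_nodes) &&
      !setequal(pred_nodes, true_nodes)) {
    rlang::abort("predicted and true node sets differ.")
  }

  true_skel <- unique(pair_key(true_edges$from, true_edges$to))
  pred_skel <- unique(pair_key(pred_edges$from, pred_edges$to))
  me <- sum(!true_skel %in% pred_skel)
  we <- sum(!pred_skel %in% true_skel)

  true_dir <- paste(true_edges$from, true_edges$to, sep = "\r")
  woe <- if (nrow(pred_edges) == 0L || all(pred_edges$directed)) {
    in_skel <- pair_key(pred_edges$from, pred_edges$to) %in% true_skel
    sum(in_skel & !(paste(pred_edges$from, pred_edges$to, sep = "\r") %in% true_dir))
  } else {
    NA_integer_
  }

  tn <- pred_edges[pred_edges$trustworthy, , drop = FALSE]
  netn <- nrow(tn)
  cetn <- sum(paste(tn$from, tn$to, sep = "\r") %in% true_dir)
  tibble::tibble(
    me = me, we = we, woe = woe, netn = netn, cetn = cetn,
    accuracy = if (netn > 0) cetn / netn else NA_real_
  )
}

#' Run the simulation benchmark on a known network
#'
#' Emulates the benchmark protocol: for each replicate, forward-sample
#' `n_samples` cases from `network`, randomly permute the columns, learn a
#' structure with each requested method, and score it against the truth
#' with [compare_networks()] (alignment is by variable name, so the shuffle
#' is undone automatically). Per-dataset seeds are derived as
#' `seed + replicate`, so any single replicate can be regenerated alone.
#'
#' @param network A `bn` object (the ground truth).
#' @param n_datasets Number of replicate datasets (benchmark default 20).
#' @param n_samples Cases per dataset (benchmark default 50,000).
#' @param seed Base integer seed.
#' @param methods Subset of `c("mici", "hc")`.
#' @param alpha,ci_alpha Learner settings passed to [mici_learn()].
#' @param summarise If `TRUE` (default) return per-method averages, with
#'   the per-replicate table attached as attribute `"replicates"`;
#'   otherwise return the per-replicate table.
#' @param file Optional path; when given, the per-method averages are also
#'   written as a TSV rounded to 2 decimals.
#' @return A tibble of benchmark metrics.
#' @export
run_benchmark <- function(network, n_datasets = 20L, n_samples = 50000L,
                          seed = 1L, methods = c("mici", "hc"),
                          alpha = 1e-4, ci_alpha = 0.05,
                          summarise = TRUE, file = NULL) {
  stopifnot(n_datasets >= 1L, n_samples >= 1L)
  methods <- match.arg(methods, c("mici", "hc"), several.ok = TRUE)
  rows <- list()
  for (rep in seq_len(n_datasets)) {
    d <- forward_sample(network, n_samples, seed = seed + rep)
    d <- shuffle_columns(d, seed = seed + 10000L + rep)
    for (m in methods) {
      pred <- if (m == "mici") {
        mici_learn(d, alpha = alpha, ci_alpha = ci_alpha,
                   seed = seed + 20000L + rep)
      } else {
        tibble::tibble(hill_climb_mdl(d), directed = TRUE, trustworthy = FALSE)
      }
      res <- compare_networks(pred, network,
                              nodes = if (inherits(pred, "mici_fit")) NULL
                                      else network$nodes)
      rows <- c(rows, list(dplyr::bind_cols(
        tibble::tibble(method = m, replicate = rep), res)))
    }
  }
  replicates <- dplyr::bind_rows(rows)
  if (!summarise) return(replicates)
  out <- dplyr::summarise(
    dplyr::group_by(replicates, .data$method),
    me = mean(.data$me), we = mean(.data$we),
    woe = if (all(is.na(.data$woe))) NA_real_ else mean(.data$woe),
    netn = mean(.data$netn), cetn = mean(.data$cetn),
    accuracy = if (all(is.na(.data$accuracy))) NA_real_
               else mean(.data$accuracy, na.rm = TRUE),
    .groups = "drop"
  )
  if (!is.null(file)) {
    readr::write_tsv(dplyr::mutate(out, dplyr::across(dplyr::where(is.numeric),
                                                      ~ round(.x, 2))), file)
  }
  attr(out, "replicates") <- replicates
  out
}
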