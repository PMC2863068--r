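# Minimum-entropy (MDLP) discretization of continuous measurements against
# a discrete class label, as used to turn normalized expression intensities
# into 2-4 state variables before network learning.

class_entropy <- function(labels) {
  if (!length(labels)) return(0)
  entropy(table(labels))
}

# Best binary cut of `values` by class-conditional entropy, with the MDLP
# acceptance criterion. Returns NULL when no candidate cut is accepted.
best_mdlp_cut <- function(values, labels) {
  ord <- order(values)
  v <- values[ord]
  l <- labels[ord]
  n <- length(v)
  # candidate boundaries: midpoints between distinct adjacent values
  distinct <- which(diff(v) > 0)
  if (!length(distinct)) return(NULL)
  ent_s <- class_entropy(l)
  k <- length(unique(l))
  best <- NULL
  for (cutpos in distinct) {
    left <- l[seq_len(cutpos)]
    right <- l[seq(cutpos + 1L, n)]
    e1 <- class_entropy(left)
    e2 <- class_entropy(right)
    went <- (length(left) * e1 + length(right) * e2) / n
    if (is.null(best) || went < best$went) {
      best <- list(cut = (v[cutpos] + v[cutpos + 1L]) / 2,
                   went = went, e1 = e1, e2 = e2,
                   k1 = length(unique(left)), k2 = length(unique(right)))
    }
  }
  gain <- ent_s - best$went
  delta <- log2(3^k - 2) - (k * ent_s - best$k1 * best$e1 - best$k2 * best$e2)
  threshold <- (log2(n - 1) + delta) / n
  if (gain > threshold) best else NULL
}

#' Minimum-entropy (MDLP) discretization map
#'
#' Recursive binary splitting of a continuous variable against a discrete
#' class label: each accepted cut minimizes the weighted class-conditional
#' entropy and must pass the MDLP stopping criterion; splitting proceeds
#' best-gain-first until no admissible split remains or `max_bins` bins are
#' reached. When no split is accepted at all, a single median cut is used
#' as a 2-bin fallback (flagged in the result).
#'
#' @param values Numeric vector of measurements.
#' @param class_labels Discrete labels of the same length (the supervision
#'   signal, e.g. a group contrast).
#' @param max_bins Maximum number of bins, between 2 and 4.
#' @return An object of class `discretization_map`: a list with
#'   `cut_points` (strictly increasing), `n_bins`
#'   (`length(cut_points) + 1`), and `fallback` (`TRUE` when the median
#'   fallback was used).
#' @export
min_entropy_discretize <- function(values, class_labels, max_bins = 4L) {
  if (length(values) != length(class_labels)) {
    rlang::abort("`values` and `class_labels` must have the same length.")
  }
  if (!(max_bins >= 2L && max_bins <= 4L)) {
    rlang::abort("`max_bins` must be between 2 and 4.")
  }
  segments <- list(list(values = values, labels = class_labels))
  cuts <- numeric()
  while (length(cuts) + 1L < max_bins) {
    # evaluate the admissible split of every current segment, take the best
    props <- purrr::map(segments, function(seg) {
      best_mdlp_cut(seg$values, seg$labels)
    })
    ok <- which(!purrr::map_lgl(props, is.null))
    if (!length(ok)) break
    gains <- purrr::map_dbl(ok, function(s) {
      class_entropy(segments[[s]]$labels) - props[[s]]$went
    })
    s <- ok[which.max(gains)]
    cut <- props[[s]]$cut
    seg <- segments[[s]]
    lower <- seg$values < cut
    segments <- c(segments[-s],
                  list(list(values = seg$values[lower], labels = seg$labels[lower]),
                       list(values = seg$values[!lower], labels = seg$labels[!lower])))
    cuts <- sort(c(cuts, cut))
  }
  fallback <- FALSE
  if (!length(cuts)) {
    cuts <- stats::median(values)
    fallback <- TRUE
    if (length(unique(values)) == 1L) {
      rlang::warn("constant values: both fallback bins describe the same content.")
    }
  }
  structure(list(cut_points = cuts, n_bins = length(cuts) + 1L,
                 fallback = fallback),
            class = "discretization_map")
}

#' @export
print.discretization_map <- function(x, ...) {
  cat("Discretization map:", x$n_bins, "bins, cuts at",
      paste(signif(x$cut_points, 6), collapse = ", "),
      if (x$fallback) "(median fallback)", "\n")
  invisible(x)
}

#' Apply a discretization map
#'
#' Bin intervals are half-open `[low, high)`: a value exactly at a cut
#' point goes to the upper bin; values outside the observed range clamp to
#' the end bins.
#'
#' @param values Numeric vector.
#' @param map A `discretization_map`.
#' @return A factor of bin indices `"1" ... "n_bins"`.
#' @export
apply_discretization <- function(values, map) {
  stopifnot(inherits(map, "discretization_map"))
  bins <- findInterval(values, map$cut_points) + 1L
  factor(bins, levels = seq_len(map$n_bins))
}

#' Discretize every numeric column of a data frame
#'
#' Runs [min_entropy_discretize()] per numeric column against a shared
#' class label and applies the resulting maps. Non-numeric columns pass
#' through untouched.
#'
#' @param data A data frame with numeric measurement columns.
#' @param class_labels Discrete labels, one per row.
#' @param max_bins Maximum bins per variable (2-4).
#' @return A tibble of factors; the per-column maps are attached as
#'   attribute `"maps"`.
#' @export
discretize_data <- function(data, class_labels, max_bins = 4L) {
  maps <- list()
  out <- purrr::imap(data, function(col, nm) {
    if (!is.numeric(col)) return(col)
    map <- min_entropy_discretize(col, class_labels, max_bins)
    maps[[nm]] <<- map
    apply_discretization(col, map)
  })
  out <- tibble::as_tibble(out)
  attr(out, "maps") <- maps
  out
}
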