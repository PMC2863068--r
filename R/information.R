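#' Shannon entropy of a count vector
#'
#' `H = -sum(p * log2(p))` with `p = counts / sum(counts)`; zero counts
#' contribute nothing (the `0 * log 0 = 0` continuity convention). All
#' information quantities in this package are in bits.
#'
#' @param counts Non-negative integer (or numeric) counts over the states of
#'   one variable.
#' @return Entropy in bits.
#' @examples
#' entropy(c(5, 5)) # 1 bit
#' entropy(c(3, 1))
#' @export
entropy <- function(counts) {
  if (any(counts < 0)) rlang::abort("counts must be non-negative.")
  total <- sum(counts)
  if (total <= 0) rlang::abort("at least one count must be positive.")
  p <- counts[counts > 0] / total
  -sum(p * log2(p))
}

# Entropy of a joint configuration index vector (1-based), in bits.
ent_idx <- function(idx, nbins) {
  counts <- tabulate(idx, nbins = nbins)
  entropy(counts)
}

joint_index <- function(comp, vars) {
  j <- rep(0L, comp$n)
  for (v in vars) j <- j * comp$arities[v] + (comp$values[, v] - 1L)
  j + 1L
}

mi_idx <- function(comp, x, y) {
  rx <- comp$arities[x]; ry <- comp$arities[y]
  hx <- ent_idx(comp$values[, x], rx)
  hy <- ent_idx(comp$values[, y], ry)
  hxy <- ent_idx(joint_index(comp, c(x, y)), rx * ry)
  max(0, hx + hy - hxy)
}

cmi_idx <- function(comp, x, y, z) {
  rx <- comp$arities[x]; ry <- comp$arities[y]; rz <- comp$arities[z]
  hxz <- ent_idx(joint_index(comp, c(x, z)), rx * rz)
  hyz <- ent_idx(joint_index(comp, c(y, z)), ry * rz)
  hz <- ent_idx(comp$values[, z], rz)
  hxyz <- ent_idx(joint_index(comp, c(x, y, z)), rx * ry * rz)
  max(0, hxz + hyz - hz - hxyz)
}

#' Empirical mutual information between two variables
#'
#' `I(X;Y) = H(X) - H(X|Y)` computed from the empirical joint table, in
#' bits, clamped below at zero. Symmetric in its arguments.
#'
#' @param data A discrete dataset.
#' @param x,y Variable names or column indices; must differ.
#' @return Mutual information in bits.
#' @export
mutual_information <- function(data, x, y) {
  comp <- if (inherits(data, "dd_compiled")) data else dd_compile(data)
  x <- dd_var_index(comp, x); y <- dd_var_index(comp, y)
  if (x == y) rlang::abort("`x` and `y` must differ; use entropy() for one variable.")
  mi_idx(comp, x, y)
}

#' Empirical conditional mutual information
#'
#' `I(X;Y|Z) = sum_z p(z) I(X;Y | Z = z)`, in bits, clamped below at zero.
#'
#' @inheritParams mutual_information
#' @param z Conditioning variable; `x`, `y`, `z` must be pairwise distinct.
#' @return Conditional mutual information in bits.
#' @export
conditional_mutual_information <- function(data, x, y, z) {
  comp <- if (inherits(data, "dd_compiled")) data else dd_compile(data)
  x <- dd_var_index(comp, x); y <- dd_var_index(comp, y); z <- dd_var_index(comp, z)
  if (anyDuplicated(c(x, y, z))) {
    rlang::abort("`x`, `y` and `z` must be pairwise distinct.")
  }
  cmi_idx(comp, x, y, z)
}

ci_idx <- function(comp, x, y, z, significance) {
  cmi <- cmi_idx(comp, x, y, z)
  g2 <- 2 * comp$n * log(2) * cmi
  df <- max(1L, (comp$arities[x] - 1L) * (comp$arities[y] - 1L) * comp$arities[z])
  crit <- stats::qchisq(1 - significance, df)
  structure(g2 <= crit, statistic = g2, df = df,
            p.value = stats::pchisq(g2, df, lower.tail = FALSE))
}

#' G-squared conditional-independence test
#'
#' Tests whether `X` and `Y` are conditionally independent given `Z` using
#' the likelihood-ratio statistic `G^2 = 2 N ln(2) I(X;Y|Z)` (with `I` in
#' bits) against a chi-square null with
#' `df = (r_x - 1)(r_y - 1) r_z`, floored at 1 so degenerate single-state
#' variables never error.
#'
#' @inheritParams conditional_mutual_information
#' @param significance Test level in (0, 1); default 0.05.
#' @return Logical: `TRUE` means "conditionally independent" (the test does
#'   not reject). Attributes `statistic`, `df` and `p.value` carry the
#'   details.
#' @export
ci_test <- function(data, x, y, z, significance = 0.05) {
  if (!(significance > 0 && significance < 1)) {
    rlang::abort("`significance` must lie strictly between 0 and 1.")
  }
  comp <- if (inherits(data, "dd_compiled")) data else dd_compile(data)
  x <- dd_var_index(comp, x); y <- dd_var_index(comp, y); z <- dd_var_index(comp, z)
  if (anyDuplicated(c(x, y, z))) {
    rlang::abort("`x`, `y` and `z` must be pairwise distinct.")
  }
  ci_idx(comp, x, y, z, significance)
}
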