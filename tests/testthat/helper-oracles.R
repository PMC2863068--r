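# Independent brute-force oracles, deliberately naive: they materialize full
# joint probability tables (or enumerate exhaustively) and never share code
# with the package internals they check.

# Joint probability table of a data frame of factors: one row per observed
# state combination with its empirical probability.
oracle_joint <- function(data) {
  tab <- as.data.frame(table(data), stringsAsFactors = FALSE)
  tab$prob <- tab$Freq / sum(tab$Freq)
  tab
}

oracle_entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

# I(X;Y) by explicit double sum over the joint table.
oracle_mi <- function(data, x, y) {
  jt <- oracle_joint(data[c(x, y)])
  px <- tapply(jt$prob, jt[[x]], sum)
  py <- tapply(jt$prob, jt[[y]], sum)
  s <- 0
  for (r in seq_len(nrow(jt))) {
    pxy <- jt$prob[r]
    if (pxy > 0) {
      s <- s + pxy * log2(pxy / (px[[jt[[x]][r]]] * py[[jt[[y]][r]]]))
    }
  }
  s
}

# I(X;Y|Z) = sum_z p(z) I(X;Y | Z = z), each stratum by oracle_mi.
oracle_cmi <- function(data, x, y, z) {
  pz <- table(data[[z]]) / nrow(data)
  s <- 0
  for (lev in names(pz)) {
    if (pz[[lev]] == 0) next
    stratum <- data[data[[z]] == lev, , drop = FALSE]
    s <- s + pz[[lev]] * oracle_mi(stratum, x, y)
  }
  s
}

# Cycle detection by exhaustive DFS from every node.
oracle_has_cycle <- function(edges, nodes) {
  adj <- lapply(setNames(nodes, nodes), function(v) edges$to[edges$from == v])
  visit <- function(v, stack) {
    for (w in adj[[v]]) {
      if (w %in% stack) return(TRUE)
      if (visit(w, c(stack, w))) return(TRUE)
    }
    FALSE
  }
  any(vapply(nodes, function(v) visit(v, v), logical(1)))
}

# Predicted-vs-true comparison by brute force over all node pairs.
oracle_compare <- function(pred, truth_edges, nodes) {
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  true_sk <- key(truth_edges$from, truth_edges$to)
  true_dir <- paste(truth_edges$from, truth_edges$to)
  me <- we <- 0
  pred_sk <- character()
  for (i in seq_len(nrow(pred))) pred_sk <- c(pred_sk, key(pred$from[i], pred$to[i]))
  for (k in true_sk) if (!k %in% pred_sk) me <- me + 1
  for (k in unique(pred_sk)) if (!k %in% true_sk) we <- we + 1
  tn <- pred[pred$trustworthy, , drop = FALSE]
  cetn <- 0
  for (i in seq_len(nrow(tn))) {
    if (paste(tn$from[i], tn$to[i]) %in% true_dir) cetn <- cetn + 1
  }
  list(me = me, we = we, netn = nrow(tn), cetn = cetn)
}
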