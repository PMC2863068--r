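chain4_net <- function() {
  bn(c("A", "B", "C", "D"),
     list(A = yn2, B = yn2, C = yn2, D = yn2),
     list(A = character(), B = "A", C = "B", D = "C"),
     list(A = cbind(0.5, 0.5),
          B = matrix(c(0.90, 0.10, 0.10, 0.90), 2, 2, byrow = TRUE),
          C = matrix(c(0.88, 0.12, 0.12, 0.88), 2, 2, byrow = TRUE),
          D = matrix(c(0.86, 0.14, 0.14, 0.86), 2, 2, byrow = TRUE)))
}

test_that("rank_edges orders pairs by MI and applies the threshold", {
  withr::with_seed(51, {
    x <- sample(0:1, 4000, TRUE)
    d <- as_discrete_data(data.frame(x = x, y = x, z = sample(0:1, 4000, TRUE)))
  })
  r <- rank_edges(d, alpha = 1e-4)
  expect_equal(c(r$x[1], r$y[1]), c("x", "y")) # perfectly correlated pair first
  expect_equal(nrow(rank_edges(d, alpha = Inf)), 0)
  # every excluded pair really is below the threshold
  all_pairs <- rank_edges(d, alpha = 0)
  excluded <- dplyr::anti_join(all_pairs, r, by = c("x", "y"))
  expect_true(all(excluded$mi < 1e-4))
  expect_true(all(diff(r$mi) <= 0))
})

test_that("classify_case distinguishes triangle, cycle and plain candidates", {
  tri <- data.frame(from = c("i", "k"), to = c("k", "j"))
  expect_equal(classify_case(tri, c("i", "j")), "triangle")
  sep <- data.frame(from = c("h", "j"), to = c("i", "k"))
  expect_equal(classify_case(sep, c("i", "j")), "plain")
  path <- data.frame(from = c("i", "a", "b"), to = c("a", "b", "j"))
  expect_equal(classify_case(path, c("i", "j")), "cycle")
  expect_error(classify_case(tri, c("i", "k")), "already connected")
})

test_that("a spurious triangle edge is removed by the CI test", {
  # chain A -> B -> C: the A-C candidate closes a triangle and is the one
  # conditionally independent pair (given B), so it is declined
  d <- forward_sample(chain_net(), 50000, seed = 61)
  fit <- mici_learn(d)
  e <- tidy(fit)
  expect_setequal(paste(pmin(e$from, e$to), pmax(e$from, e$to)),
                  c("A B", "B C"))
  expect_false(any(e$directed)) # chain: equivalence class, no orientation
  tr <- fit$trace[fit$trace$case == "triangle", ]
  expect_equal(tr$action, "skipped")
  expect_match(tr$details, "independent given B")
})

test_that("triangle resolution can delete an existing spurious edge", {
  # state holding skeleton {B-C, A-C} on chain A -> B -> C data; candidate
  # (B, A) forms the triangle; A and C are the conditionally independent
  # pair given B, so A-C is deleted and the candidate connects
  d <- forward_sample(chain_net(), 50000, seed = 67)
  comp <- micinet:::dd_compile(d)
  mi <- matrix(1, 3, 3)
  st <- micinet:::new_learn_state(comp, 1e-4, 0.05, 1L, mi)
  micinet:::st_connect(st, 2L, 3L) # B-C
  micinet:::st_connect(st, 1L, 3L) # A-C (spurious)
  res <- micinet:::resolve_triangle(st, 2L, 1L) # candidate B-A
  expect_equal(res$action, "deleted_other")
  expect_true(st$adj[1, 2])   # candidate connected
  expect_false(st$adj[1, 3])  # spurious edge removed
  expect_true(st$adj[2, 3])
})

test_that("a fully dependent triangle declines the closing edge", {
  # all three pairs stay dependent given the third node: the current edge
  # is not used and the earlier skeleton survives
  net <- bn(c("A", "B", "C"),
            list(A = yn2, B = yn2, C = yn2),
            list(A = character(), B = "A", C = c("A", "B")),
            list(A = cbind(0.5, 0.5),
                 B = matrix(c(0.8, 0.2, 0.2, 0.8), 2, 2, byrow = TRUE),
                 C = matrix(c(0.9, 0.1, 0.6, 0.4, 0.4, 0.6, 0.1, 0.9),
                            4, 2, byrow = TRUE)))
  d <- forward_sample(net, 50000, seed = 71)
  fit <- mici_learn(d)
  expect_equal(nrow(tidy(fit)), 2)
  tr <- fit$trace[fit$trace$case == "triangle", ]
  expect_equal(nrow(tr), 1)
  expect_equal(tr$action, "skipped")
})

test_that("a cycle-closing edge with no immorality is declined", {
  d <- forward_sample(chain4_net(), 50000, seed = 73)
  fit <- mici_learn(d)
  e <- tidy(fit)
  expect_setequal(paste(pmin(e$from, e$to), pmax(e$from, e$to)),
                  c("A B", "B C", "C D"))
  tr <- fit$trace[fit$trace$case == "cycle", ]
  expect_gte(nrow(tr), 1)
  expect_true(all(tr$action == "skipped"))
})

test_that("an isolated v-structure is recovered with trustworthy orientations", {
  d <- forward_sample(collider_net(), 50000, seed = 79)
  fit <- mici_learn(d)
  e <- tidy(fit)
  expect_equal(nrow(e), 2)
  expect_true(all(e$directed))
  expect_true(all(e$trustworthy))
  expect_true(all(e$to == "C"))
})

test_that("constant data yields an empty graph", {
  d <- as_discrete_data(data.frame(a = factor(rep("x", 50), c("x", "y")),
                                   b = factor(rep("x", 50), c("x", "y")),
                                   c = factor(rep("x", 50), c("x", "y"))))
  fit <- mici_learn(d)
  expect_equal(nrow(tidy(fit)), 0)
  expect_true(all(fit$trace$case == "below_threshold"))
})

test_that("the pass visits each candidate pair exactly once", {
  d <- forward_sample(asia_network(), 10000, seed = 83)
  fit <- mici_learn(d)
  n <- ncol(d)
  expect_equal(nrow(fit$trace), n * (n - 1) / 2)
  expect_equal(anyDuplicated(paste(pmin(fit$trace$x, fit$trace$y),
                                   pmax(fit$trace$x, fit$trace$y))), 0)
  cand <- rank_edges(d, alpha = fit$config$alpha)
  expect_equal(sum(fit$trace$case != "below_threshold"), nrow(cand))
})

test_that("outputs are acyclic, trustworthy edges are directed, runs are deterministic", {
  for (case in 1:8) {
    net <- random_network(6, max_parents = 2, seed = 200 + case, strength = 0.85)
    d <- forward_sample(net, 3000, seed = 300 + case)
    fit <- mici_learn(d, seed = case)
    e <- tidy(fit)
    dir_edges <- e[e$directed, c("from", "to")]
    expect_true(topological_check(dir_edges, fit$nodes))
    expect_false(oracle_has_cycle(dir_edges, fit$nodes))
    expect_true(all(e$directed[e$trustworthy]))
  }
  d <- forward_sample(asia_network(), 20000, seed = 89)
  f1 <- mici_learn(d, seed = 42)
  f2 <- mici_learn(d, seed = 42)
  expect_identical(tidy(f1), tidy(f2))
  expect_identical(f1$trace, f2$trace)
})

test_that("learner rejects degenerate inputs and configs", {
  d <- as_discrete_data(data.frame(a = c(0, 1)))
  expect_error(mici_learn(d), "two variables")
  d <- forward_sample(pair_net(), 100, seed = 1)
  expect_error(mici_learn(d, alpha = -1), "non-negative")
  expect_error(mici_learn(d, ci_alpha = 0), "between 0 and 1")
})

test_that("tidy, glance and autoplot work on a fit", {
  d <- forward_sample(collider_net(), 5000, seed = 97)
  fit <- mici_learn(d)
  g <- glance(fit)
  expect_equal(g$n_vars, 3)
  expect_equal(g$n_obs, 5000)
  expect_equal(g$n_edges, nrow(tidy(fit)))
  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
})
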