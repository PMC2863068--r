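test_that("entropy handles fair, degenerate and skewed counts", {
  expect_equal(entropy(c(5, 5)), 1.0)
  expect_equal(entropy(c(7, 0)), 0.0)
  expect_equal(entropy(c(3, 1)), 0.8112781, tolerance = 1e-6)
  expect_error(entropy(c(0, 0)), "positive")
  expect_error(entropy(c(-1, 2)), "non-negative")
})

test_that("mutual information matches hand cases and the joint-table oracle", {
  # constant y carries nothing
  d <- as_discrete_data(data.frame(x = c(0, 1, 0, 1), y = rep(1, 4)))
  expect_equal(mutual_information(d, "x", "y"), 0)
  # y identical to x with a fair marginal: I = H = 1 bit
  d <- as_discrete_data(data.frame(x = rep(0:1, 5), y = rep(0:1, 5)))
  expect_equal(mutual_information(d, "x", "y"), 1.0)
  # 2x2 joint {(0,0):2,(0,1):1,(1,0):1,(1,1):2} against the double-sum oracle
  d <- as_discrete_data(data.frame(x = c(0, 0, 0, 1, 1, 1),
                                   y = c(0, 0, 1, 0, 1, 1)))
  expect_equal(mutual_information(d, "x", "y"), oracle_mi(d, "x", "y"),
               tolerance = 1e-12)
  expect_error(mutual_information(d, "x", "x"), "must differ")
})

test_that("information measures agree with the brute-force oracle on random ternary tables", {
  withr::with_seed(21, {
    for (case in 1:12) {
      d <- as_discrete_data(data.frame(
        a = sample(0:2, 40, TRUE), b = sample(0:2, 40, TRUE),
        c = sample(0:2, 40, TRUE), e = sample(0:1, 40, TRUE)))
      expect_equal(mutual_information(d, "a", "b"), oracle_mi(d, "a", "b"),
                   tolerance = 1e-10)
      expect_equal(conditional_mutual_information(d, "a", "b", "c"),
                   oracle_cmi(d, "a", "b", "c"), tolerance = 1e-10)
      expect_equal(conditional_mutual_information(d, "e", "c", "a"),
                   oracle_cmi(d, "e", "c", "a"), tolerance = 1e-10)
      # symmetry and non-negativity
      expect_identical(mutual_information(d, "a", "b"),
                       mutual_information(d, "b", "a"))
      expect_gte(mutual_information(d, "a", "c"), 0)
    }
  })
})

test_that("conditional MI vanishes when y duplicates z and is 1 bit for XOR", {
  d <- as_discrete_data(data.frame(x = c(0, 1, 0, 1), y = c(0, 0, 1, 1),
                                   z = c(0, 0, 1, 1)))
  expect_equal(conditional_mutual_information(d, "x", "y", "z"), 0)
  # x, y independent fair coins, z = xor: I(X;Y|Z) = 1 bit exactly
  d <- as_discrete_data(data.frame(x = c(0, 0, 1, 1), y = c(0, 1, 0, 1),
                                   z = c(0, 1, 1, 0)))
  expect_equal(conditional_mutual_information(d, "x", "y", "z"), 1.0)
  expect_error(conditional_mutual_information(d, "x", "y", "y"), "distinct")
})

test_that("the G-squared CI test separates dependence from independence", {
  # y a deterministic copy of x, z noise: overwhelmingly dependent
  withr::with_seed(31, {
    x <- sample(0:1, 50000, TRUE)
    d <- as_discrete_data(data.frame(x = x, y = x, z = sample(0:1, 50000, TRUE)))
  })
  expect_false(as.logical(ci_test(d, "x", "y", "z")))
  # all samples identical: G2 = 0, trivially independent
  d <- as_discrete_data(data.frame(x = rep(1, 4), y = rep(1, 4), z = rep(1, 4)))
  res <- ci_test(d, "x", "y", "z")
  expect_true(as.logical(res))
  expect_equal(attr(res, "statistic"), 0)
  expect_equal(attr(res, "df"), 1) # df floored at 1 for degenerate arities
  expect_error(ci_test(d, "x", "y", "z", significance = 1.2), "between 0 and 1")
})

test_that("the CI test is approximately size-correct under the null", {
  # x independent of y within each z stratum by construction; acceptance
  # frequency should approach 1 - significance. Run at N = 4,000 rather than
  # the benchmark's 50,000 to keep the suite fast; the G2 null calibration
  # does not depend on N at these sizes.
  accept <- logical(200)
  withr::with_seed(41, {
    for (r in 1:200) {
      z <- sample(0:1, 4000, TRUE)
      x <- ifelse(z == 1, sample(0:1, 4000, TRUE, prob = c(0.7, 0.3)),
                  sample(0:1, 4000, TRUE, prob = c(0.3, 0.7)))
      y <- ifelse(z == 1, sample(0:1, 4000, TRUE, prob = c(0.8, 0.2)),
                  sample(0:1, 4000, TRUE, prob = c(0.4, 0.6)))
      d <- as_discrete_data(data.frame(x = x, y = y, z = z))
      accept[r] <- as.logical(ci_test(d, "x", "y", "z", significance = 0.05))
    }
  })
  expect_gte(mean(accept), 0.90)
  expect_lte(mean(accept), 0.99)
})

test_that("conditional MI collapses along a sampled chain", {
  d <- forward_sample(chain_net(), 50000, seed = 3)
  cmi <- conditional_mutual_information(d, "A", "C", "B")
  expect_lt(cmi, mutual_information(d, "A", "C"))
  expect_lt(cmi, 1e-3) # approaches 0 as N grows
})
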