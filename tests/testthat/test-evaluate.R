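test_that("comparison metrics match hand-checked cases", {
  truth <- data.frame(from = c("A", "B", "C"), to = c("B", "C", "D"))
  nodes <- c("A", "B", "C", "D")

  # perfect fully trustworthy prediction
  pred <- tibble::tibble(from = truth$from, to = truth$to,
                         directed = TRUE, trustworthy = TRUE)
  res <- compare_networks(pred, truth, nodes = nodes)
  expect_equal(res[, c("me", "we", "netn", "cetn")],
               tibble::tibble(me = 0L, we = 0L, netn = 3L, cetn = 3L),
               ignore_attr = TRUE)
  expect_equal(res$accuracy, 1)

  # empty prediction: everything missed, accuracy undefined
  empty <- tibble::tibble(from = character(), to = character(),
                          directed = logical(), trustworthy = logical())
  res <- compare_networks(empty, truth, nodes = nodes)
  expect_equal(res$me, 3)
  expect_equal(res$we, 0)
  expect_equal(res$netn, 0)
  expect_true(is.na(res$accuracy))

  # one extra edge and one flipped trustworthy edge on a 4-node toy
  pred <- tibble::tibble(from = c("A", "C", "C", "A"), to = c("B", "B", "D", "D"),
                         directed = TRUE, trustworthy = c(TRUE, TRUE, TRUE, FALSE))
  res <- compare_networks(pred, truth, nodes = nodes)
  expect_equal(res$we, 1)          # A-D not in truth
  expect_equal(res$me, 0)
  expect_equal(res$netn, 3)
  expect_equal(res$cetn, res$netn - 1) # C->B flips B->C
})

test_that("WOE is counted for directed predictions and NA for mixed ones", {
  truth <- data.frame(from = c("A", "B"), to = c("B", "C"))
  pred <- tibble::tibble(from = c("B", "B"), to = c("A", "C"),
                         directed = TRUE, trustworthy = FALSE)
  expect_equal(compare_networks(pred, truth, nodes = c("A", "B", "C"))$woe, 1)
  pred_mixed <- tibble::tibble(from = c("A", "B"), to = c("B", "C"),
                               directed = c(TRUE, FALSE), trustworthy = FALSE)
  expect_true(is.na(compare_networks(pred_mixed, truth, nodes = c("A", "B", "C"))$woe))
})

test_that("comparison agrees with brute-force enumeration on random graphs", {
  nodes <- LETTERS[1:6]
  withr::with_seed(43, {
    for (case in 1:20) {
      rand_edges <- function() {
        k <- sample(0:7, 1)
        out <- data.frame(from = sample(nodes, k, TRUE),
                          to = sample(nodes, k, TRUE))
        out <- out[out$from != out$to, ]
        # one edge per unordered pair, as in any graph skeleton
        out[!duplicated(paste(pmin(out$from, out$to), pmax(out$from, out$to))), ]
      }
      truth <- rand_edges()
      pred <- rand_edges()
      pred <- tibble::tibble(from = pred$from, to = pred$to, directed = TRUE,
                             trustworthy = sample(c(TRUE, FALSE), nrow(pred), TRUE))
      got <- compare_networks(pred, truth, nodes = nodes)
      want <- oracle_compare(pred, truth, nodes)
      expect_equal(got$me, want$me)
      expect_equal(got$we, want$we)
      expect_equal(got$netn, want$netn)
      expect_equal(got$cetn, want$cetn)
    }
  })
  expect_error(compare_networks(
    tibble::tibble(from = "X", to = "Y", directed = TRUE, trustworthy = FALSE),
    data.frame(from = "A", to = "B"), nodes = NULL), NA)
})

test_that("metrics are invariant to the column shuffle before learning", {
  net <- collider_net()
  d <- forward_sample(net, 20000, seed = 47)
  fit_plain <- mici_learn(d, seed = 1)
  fit_shuf <- mici_learn(shuffle_columns(d, seed = 53), seed = 1)
  expect_equal(compare_networks(fit_plain, net),
               compare_networks(fit_shuf, net))
})

test_that("run_benchmark averages replicates and keeps the per-replicate table", {
  net <- collider_net()
  res <- run_benchmark(net, n_datasets = 2, n_samples = 5000, seed = 59,
                       methods = "mici")
  expect_equal(nrow(res), 1)
  reps <- attr(res, "replicates")
  expect_equal(nrow(reps), 2)
  expect_equal(res$we, mean(reps$we))
  # single replicate: no averaging artifacts
  res1 <- run_benchmark(net, n_datasets = 1, n_samples = 5000, seed = 59,
                        methods = "mici")
  expect_identical(res1$me, as.numeric(attr(res1, "replicates")$me))
  # TSV export is rounded to two decimals
  tmp <- withr::local_tempfile(fileext = ".tsv")
  run_benchmark(net, n_datasets = 1, n_samples = 2000, seed = 61,
                methods = "mici", file = tmp)
  tab <- readr::read_tsv(tmp, show_col_types = FALSE)
  expect_true(all(round(tab$we, 2) == tab$we))
})

test_that("both methods run through the benchmark driver", {
  net <- pair_net(0.05)
  res <- run_benchmark(net, n_datasets = 2, n_samples = 4000, seed = 67,
                       methods = c("mici", "hc"))
  expect_setequal(res$method, c("mici", "hc"))
  expect_true(all(res$we >= 0))
  hc_row <- res[res$method == "hc", ]
  expect_false(is.na(hc_row$woe)) # fully directed baseline reports WOE
})
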