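test_that("array initialisation is deterministic and validated", {
  p <- sim_params(n0 = 10, unit_len = 652, seed = 5)
  a1 <- init_array(p)
  a2 <- init_array(p)
  expect_identical(a1$copies, a2$copies)
  expect_equal(length(a1$copies), 10L)
  expect_equal(unique(nchar(a1$copies)), 652L)
  expect_equal(length(unique(a1$copies)), 1L)
  expect_error(init_array(p, ancestor = "ACGT"), class = "alphadom_parameter")
  expect_error(init_array(sim_params(n0 = 2, copy_bounds = c(5, 100))),
               class = "alphadom_parameter")
  expect_error(sim_params(mu = -1), class = "alphadom_parameter")
  expect_error(sim_params(xo_identity_min = 0), class = "alphadom_parameter")
})

test_that("null dynamics leave the array untouched", {
  p <- sim_params(n0 = 8, unit_len = 100, mu = 0, conv_rate = 0,
                  xo_rate = 0, generations = 10, seed = 6)
  arr <- init_array(p)
  res <- evolve(arr, p)
  expect_identical(res$array$copies, arr$copies)
  expect_equal(length(res$log$events), 0L)
  # zero generations returns the initial array
  expect_identical(evolve(arr, p, generations = 0)$array$copies, arr$copies)
})

test_that("the identity gate closes crossovers on diverged arrays", {
  p <- sim_params(n0 = 10, unit_len = 200, mu = 0, conv_rate = 0,
                  xo_rate = 3, xo_identity_min = 1.0, generations = 15,
                  seed = 7)
  arr <- init_array(p)
  # diverge every copy so no pair is identical anywhere
  arr$copies <- vapply(seq_along(arr$copies), function(i)
    alphadom:::mutate_fixed(arr$copies[i], 10), character(1))
  res <- evolve(arr, p)
  types <- vapply(res$log$events, function(e) e$type, character(1))
  expect_true(all(types %in% c("crossover_rejected")))
  expect_gt(sum(types == "crossover_rejected"), 0)
  expect_equal(length(res$array$copies), 10L)
})

test_that("mutation counts follow the configured Poisson intensity", {
  # 10 copies x 652 bp at mu = 1e-3 for one generation: mean 6.52 per step
  p <- sim_params(n0 = 10, unit_len = 652, mu = 1e-3, conv_rate = 0,
                  xo_rate = 0, generations = 1, seed = 8)
  arr <- init_array(p)
  counts <- vapply(1:200, function(r) {
    pr <- p; pr$seed <- 1000L + r
    length(evolve(arr, pr)$log$events)
  }, numeric(1))
  mean_expected <- 6.52
  se <- sqrt(mean_expected / 200)
  expect_lt(abs(mean(counts) - mean_expected), 2.58 * se * 1.5)
})

test_that("conversion is copy-number neutral and crossover changes it by d", {
  p <- sim_params(n0 = 20, unit_len = 150, mu = 1e-4, conv_rate = 1,
                  conv_tract_mean = 40, xo_rate = 1, xo_identity_min = 0.9,
                  xo_offset_max = 4, generations = 40, seed = 9)
  res <- evolve(init_array(p), p)
  n <- 20L
  for (e in res$log$events) {
    if (e$type == "crossover") {
      expect_equal(abs(e$copy_number_change), e$offset)
      n <- n + e$copy_number_change
    }
  }
  expect_equal(length(res$array$copies), n)
})

test_that("event-log replay reproduces evolved arrays exactly", {
  for (seed in c(11, 12, 13)) {
    p <- sim_params(n0 = 12, unit_len = 180, mu = 5e-4, conv_rate = 0.8,
                    conv_tract_mean = 50, xo_rate = 0.8,
                    xo_identity_min = 0.9, generations = 50, seed = seed)
    res <- evolve(init_array(p), p)
    expect_identical(replay_log(res$log)$copies, res$array$copies)
  }
})

test_that("lineage splitting is deterministic and a no-op at g_split = 0", {
  p <- sim_params(n0 = 10, unit_len = 150, generations = 20, seed = 14)
  arr <- evolve(init_array(p), p)$array
  sp0 <- split_lineages(arr, p, g_split = 0)
  expect_identical(sp0$a$copies, sp0$b$copies)
  sp1 <- split_lineages(arr, p, g_split = 30)
  sp2 <- split_lineages(arr, p, g_split = 30)
  expect_identical(sp1$a$copies, sp2$a$copies)
  expect_identical(sp1$b$copies, sp2$b$copies)
  expect_false(identical(sp1$a$copies, sp1$b$copies))
})

test_that("clone sampling emulates anonymous, possibly duplicated PCR clones", {
  p <- sim_params(n0 = 12, unit_len = 300, mu = 1e-3, conv_rate = 0,
                  xo_rate = 0, generations = 5, seed = 15)
  arr <- evolve(init_array(p), p)$array
  cl <- sample_clones(arr, n = 12, dup_prob = 0, seed = 16)
  expect_true(all(cl$sequence %in% arr$copies))
  expect_false(any(grepl("[0-9]+_[0-9]+$", cl$id)))   # no positional ids
  cl_dup <- sample_clones(arr, n = 8, dup_prob = 1, seed = 17)
  expect_equal(length(unique(cl_dup$sequence)), 1L)
  cl_win <- sample_clones(arr, n = 5, window = c(51L, 150L), seed = 18)
  expect_equal(unique(nchar(cl_win$sequence)), 100L)
  expect_error(sample_clones(arr, 5, window = c(1L, 400L)),
               class = "alphadom_parameter")
})

test_that("crossover-dominated dynamics homogenise the array", {
  idents <- vapply(1:5, function(r) {
    base <- sim_params(n0 = 15, unit_len = 250, mu = 5e-4, conv_rate = 0,
                       conv_tract_mean = 60, xo_identity_min = 0.9,
                       xo_offset_max = 3, generations = 120,
                       seed = 3000 + r)
    p_on <- base; p_on$xo_rate <- 1.5
    p_off <- base; p_off$xo_rate <- 0
    arr <- init_array(base)
    on <- evolve(arr, p_on)$array
    off <- evolve(arr, p_off)$array
    c(alphadom:::mean_pairwise_identity(on$copies, 60),
      alphadom:::mean_pairwise_identity(off$copies, 60))
  }, numeric(2))
  expect_gt(mean(idents[1, ]), mean(idents[2, ]))
})
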