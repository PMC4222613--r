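test_that("fraction tokens parse exactly; malformed tokens are rejected", {
  f <- parse_fraction("1/3")
  expect_identical(c(f$num, f$den), c(1, 3))
  expect_equal(f$value, 1 / 3)
  expect_identical(parse_fraction("1")$value, 1)
  expect_identical(parse_fraction("2/6")$num / parse_fraction("2/6")$den, 1 / 3)
  expect_equal(parse_fraction("0.25")$value, 0.25, tolerance = 1e-12)
  expect_true(is.na(parse_fraction("0.25")$num))
  expect_error(parse_fraction("1/0"), "zero denominator")
  expect_error(parse_fraction("a/b"), "malformed")
  expect_error(parse_fraction("1//2"), "malformed")
})

test_that("basic format assigns 1/k per neighbour occurrence, waiting for repeats", {
  net <- parse_network(c(
    "NODE 0 1", "NODE 1 0 2", "NODE 2 1 3", "NODE 3 2 9",
    "NODE 4 5", "NODE 5 4 6", "NODE 6 5 7", "NODE 7 6 9",
    "NODE 8 9", "NODE 9 9 9 3"), "basic")$network
  e9 <- net$edges[net$edges$from == 9, ]
  expect_equal(sum(e9$p[e9$to == 3]), 1 / 3)
  expect_equal(sum(e9$p[e9$to == 9]), 2 / 3)   # waiting probability
  expect_true(all(e9$tau == 1))
  expect_true(all(e9$p_den == 3))
})

test_that("the square parses to uniform 1/2 probabilities with unit times", {
  net <- square_net()
  expect_equal(net$n_nodes, 4L)
  expect_true(all(net$edges$p == 0.5))
  expect_true(all(net$edges$tau == 1))
  for (l in 0:3) expect_identical(sum(net$edges$p[net$edges$from == l]), 1)
})

test_that("advanced format accepts triplets and validates per-line sums", {
  net <- parse_network(
    c("NODE 0 1 1/2 1.5 1 1/2 0.5", "NODE 1 0 1 0"), "advanced")$network
  expect_equal(nrow(net$edges), 3)
  expect_equal(net$edges$tau, c(1.5, 0.5, 0))
  expect_equal(net$edges$p[3], 1)  # single-exit node, zero time, accepted
  expect_error(parse_network(c("NODE 0 1 1/2 1 1 1/3 1", "NODE 1 0 1 1"),
                             "advanced"),
               "node 0.*sum")
  expect_error(parse_network(c("NODE 0 1 0.4999 1 1 0.5 1", "NODE 1 0 1 1"),
                             "advanced"),
               "node 0.*sum")
  # within 1e-9 decimals are accepted
  expect_silent(parse_network(
    c("NODE 0 1 0.4999999999 1 1 0.5000000001 1", "NODE 1 0 1 1"), "advanced"))
})

test_that("node numbering must increase from zero without gaps or repeats", {
  expect_error(parse_network(c("NODE 1 0", "NODE 0 1"), "basic"), "increase")
  expect_error(parse_network(c("NODE 0 2", "NODE 2 0"), "basic"), "increase")
  expect_error(parse_network(c("NODE 0 1", "NODE 0 1"), "basic"), "duplicate")
  expect_error(parse_network(c("WALK 100"), "basic"), "no NODE")
  expect_error(parse_network(c("NODE 0 1", "NODE 1 0", "NOISE 3"), "basic"),
               "unknown keyword")
})

test_that("run keywords populate walkers, simulations, queries and info", {
  pr <- parse_network(c("NODE 0 1", "NODE 1 0", "WALK 1000", "SIMU 10",
                        "MFPT 0 1", "MFPT 1 0 0", "INFO  hello world "),
                      "basic")
  expect_identical(pr$run$walkers, 1000L)
  expect_identical(pr$run$simulations, 10L)
  expect_length(pr$run$queries, 2)
  expect_identical(pr$run$queries[[2]]$finals, c(0L, 0L))
  expect_identical(pr$run$info, "hello world")
})

test_that("write/parse round-trips preserve networks exactly, fractions included", {
  sq_lines <- c("NODE 0 1 3", "NODE 1 0 2", "NODE 2 1 3", "NODE 3 0 2")
  expect_identical(write_network(square_net(), format = "basic"), sq_lines)
  withr::with_seed(31, {
    for (i in 1:20) {
      net <- random_small_net()
      back <- parse_network(write_network(net, format = "advanced"),
                            "advanced")$network
      expect_equal(back$edges, net$edges)
    }
    big <- generate_network("random_tree", n = 200,
                            prob_mode = "random_rational", time_mode = "random")
    back <- parse_network(write_network(big, format = "advanced"),
                          "advanced")$network
    expect_equal(back$edges, big$edges)
  })
  # fraction tokens survive as fractions, not decimals
  lines <- write_network(parse_network(c("NODE 0 0 0 1", "NODE 1 0"),
                                       "basic")$network, format = "basic")
  expect_identical(lines[1], "NODE 0 0 0 1")
})

test_that("run spec round-trips through write_network", {
  pr <- parse_network(c("NODE 0 1", "NODE 1 0", "WALK 50", "SIMU 2",
                        "MFPT 0 1", "INFO note"), "basic")
  lines <- write_network(pr$network, run = pr$run, format = "basic")
  pr2 <- parse_network(lines, "basic")
  expect_identical(pr2$run$walkers, 50L)
  expect_identical(pr2$run$queries, pr$run$queries)
  expect_identical(pr2$run$info, "note")
})

test_that("results writer emits values, errors and the inaccessibility sentinel", {
  res <- dplyr::bind_rows(
    mfpt_result(0, 1, 12.5, std = 0.4, method = "montecarlo"),
    mfpt_result(0, c(1, 2), Inf, method = "hill"))
  lines <- write_results(res, info = "test comment")
  expect_true(any(grepl("INFO test comment", lines, fixed = TRUE)))
  expect_true(any(grepl("12.5 [std 0.4]", lines, fixed = TRUE)))
  expect_true(any(grepl("Infinity (not accessible)", lines, fixed = TRUE)))
  # empty result set: header and info only
  empty <- write_results(res[0, ], info = "x")
  expect_length(empty, 2)
})

test_that("probability sums outside tolerance are rejected at construction", {
  expect_error(stoch_net(2, data.frame(from = 0, to = 1, p = 0.9, tau = 1)),
               "sum")
  expect_error(stoch_net(2, data.frame(from = c(0, 0), to = c(0, 1),
                                       p = c(0.5, 0.500001), tau = 1)),
               "sum")
  expect_error(stoch_net(2, data.frame(from = 0, to = 1, p = 1, tau = -1)),
               "local times")
  expect_error(stoch_net(2, data.frame(from = 0, to = 5, p = 1, tau = 1)),
               "outside")
})
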