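test_that("CAPRI classification reproduces the reference pose labels", {
  # the five favourable-trajectory states: I9, I30, A20, M22, M21
  tab <- tibble::tibble(
    id = c(9, 30, 20, 22, 21),
    irmsd = c(4.41, 4.01, 2.95, 1.88, 1.41),
    lrmsd = c(15.43, 14.81, 10.60, 5.53, 3.14),
    fnat = c(0.22, 0.25, 0.42, 0.61, 0.67))
  expect_identical(capri_classify(tab$fnat, tab$lrmsd, tab$irmsd),
                   c("incorrect", "incorrect", "acceptable", "medium", "medium"))
  # clause boundaries
  expect_identical(capri_classify(0.55, 0.9, 3), "high")
  expect_identical(capri_classify(0.55, 3, 0.8), "high")
  expect_identical(capri_classify(0.09, 1, 1), "incorrect")
  expect_identical(capri_classify(0.35, 4.9, 3), "medium")
  expect_identical(capri_classify(0.35, 6, 3), "acceptable")
})

test_that("transition probabilities follow the energy rule with cutoff and pruning", {
  # two neighbours at equal energy split evenly
  st <- tibble::tibble(id = 0:2, energy = c(-5, -5, -5), lrmsd = c(1, 1, 1))
  adj <- tibble::tibble(from = c(0, 0), to = c(1, 2))
  net <- assign_transition_probabilities(st, adj)
  e0 <- net$edges[net$edges$from == 0, ]
  expect_equal(e0$p, c(0.5, 0.5))
  expect_true(all(net$edges$tau == 1))
  # downhill moves get raw score one; a 20 kT uphill move is pruned
  st2 <- tibble::tibble(id = 0:2, energy = c(0, -1, 20), lrmsd = 1)
  net2 <- assign_transition_probabilities(st2, tibble::tibble(from = c(0, 0),
                                                              to = c(1, 2)))
  e0 <- net2$edges[net2$edges$from == 0, ]
  expect_equal(e0$to, 1L)          # exp(-20) ~ 2e-9 < 1e-6 pruned
  expect_equal(e0$p, 1)            # single survivor renormalized to one
  # ligand-RMSD cutoff zeroes transitions INTO far states by default
  st3 <- tibble::tibble(id = 0:2, energy = c(0, -1, -5), lrmsd = c(1, 8, 1))
  adj3 <- tibble::tibble(from = c(0, 0, 1), to = c(1, 2, 2))
  net3 <- assign_transition_probabilities(st3, adj3)
  expect_false(any(net3$edges$to == 1))
  expect_true(any(net3$edges$from == 1))   # far state may still exit
  # ... and OUT of far states with the alternate direction
  net4 <- assign_transition_probabilities(st3, adj3, cutoff_direction = "out")
  expect_false(any(net4$edges$from == 1))
  expect_true(any(net4$edges$to == 1))
  # dead ends are recorded, not errors
  st5 <- tibble::tibble(id = 0:1, energy = c(0, 0), lrmsd = c(1, 8))
  net5 <- assign_transition_probabilities(st5, tibble::tibble(from = 0, to = 1))
  expect_equal(attr(net5, "dead_ends"), 0)  # the far state itself may still exit
  # surviving rows are stochastic
  for (l in unique(net3$edges$from)) {
    expect_equal(sum(net3$edges$p[net3$edges$from == l]), 1, tolerance = 1e-12)
  }
})

test_that("MFPT-weighted graphs keep exactly the finite entries", {
  m <- matrix(as.numeric(1:9), 3, 3, byrow = TRUE)
  diag(m) <- NA
  g <- mfpt_weighted_graph(m)
  expect_equal(nrow(g), 6)
  m[1, 2] <- NA
  expect_equal(nrow(mfpt_weighted_graph(m)), 5)
  m[2, 1] <- Inf
  expect_equal(nrow(mfpt_weighted_graph(m)), 4)
  m[3, 1] <- -2
  expect_error(mfpt_weighted_graph(m), "positive")
})

test_that("favourable paths are shortest in summed MFPT with lexicographic ties", {
  # triangle: two-hop route beats the direct edge
  m <- matrix(NA_real_, 3, 3)
  m[1, 2] <- 1; m[2, 3] <- 1; m[1, 3] <- 3
  g <- mfpt_weighted_graph(m)
  sp <- shortest_path(g, 0, 2)
  expect_identical(sp$path, c(0L, 1L, 2L))
  expect_identical(sp$total, 2)
  # equal-cost paths resolve to the lexicographically smallest sequence
  m2 <- matrix(NA_real_, 4, 4)
  m2[1, 2] <- 1; m2[2, 4] <- 1; m2[1, 3] <- 1; m2[3, 4] <- 1
  sp2 <- shortest_path(mfpt_weighted_graph(m2), 0, 3)
  expect_identical(sp2$path, c(0L, 1L, 3L))
  # unreachable target
  m3 <- matrix(NA_real_, 3, 3); m3[1, 2] <- 1
  sp3 <- shortest_path(mfpt_weighted_graph(m3), 0, 2)
  expect_false(sp3$accessible)
  expect_identical(sp3$total, Inf)
})

test_that("shortest paths agree with brute-force enumeration on random graphs", {
  withr::with_seed(61, {
    for (i in 1:12) {
      n <- sample(4:8, 1)
      m <- matrix(NA_real_, n, n)
      fill <- which(matrix(stats::runif(n * n), n, n) < 0.5 & row(m) != col(m))
      m[fill] <- round(stats::runif(length(fill), 0.1, 10), 2)
      g <- mfpt_weighted_graph(m)
      sp <- shortest_path(g, 0, n - 1)
      bf <- brute_shortest(g, 0, n - 1)
      if (!sp$accessible) {
        expect_identical(bf$total, Inf)
      } else {
        expect_equal(sp$total, bf$total, tolerance = 1e-12)
        expect_identical(sp$path, as.integer(bf$path))
        # total equals the sum of its edge weights exactly
        wsum <- sum(vapply(seq_len(length(sp$path) - 1), function(k)
          min(g$weight[g$from == sp$path[k] & g$to == sp$path[k + 1]]), 0))
        expect_identical(sp$total, wsum)
      }
    }
  })
})

test_that("MFPT matrices round-trip through the text format", {
  m <- matrix(NA_real_, 3, 3)
  m[1, 2] <- 123.456; m[2, 3] <- 1e6; m[3, 1] <- 0.001
  path <- withr::local_tempfile(fileext = ".mfpt")
  write_mfpt_matrix(m, path)
  back <- read_mfpt_matrix(path)
  expect_equal(back, m)
})
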