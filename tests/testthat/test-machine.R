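test_that("equilibrium occupation is degree over total degree", {
  tree <- generate_network("random_tree", n = 200, seed = 2)
  eq <- equilibrium_occupation(tree)
  expect_equal(sum(eq$p_eq), 1, tolerance = 1e-12)
  expect_equal(sum(eq$degree), 2 * (200 - 1))
  leaf <- eq$node[eq$degree == 1][1]
  expect_equal(eq$p_eq[eq$node == leaf], 1 / 398)
  cyc <- generate_network("cycle", n = 7)
  expect_equal(equilibrium_occupation(cyc)$p_eq, rep(1 / 7, 7))
  star <- stoch_net(5, data.frame(from = c(rep(0, 4), 1:4),
                                  to = c(1:4, rep(0, 4)),
                                  p = c(rep(0.25, 4), rep(1, 4)), tau = 1))
  eqs <- equilibrium_occupation(star)
  expect_equal(eqs$p_eq, c(4 / 8, rep(1 / 8, 4)))
})

test_that("the unit probability pins the machine time scale", {
  expect_equal(round(unit_probability(40, 1 / 398), 3), 0.091)
  expect_equal(unit_probability(5, 1 / 5), 0.5)     # tau * p_eq = 1
  expect_gt(unit_probability(1e9, 0.5), 0.999)      # tau -> Inf limit
  expect_lt(unit_probability(1e-9, 0.5), 1e-8)
})

test_that("gate transition probabilities close the unit at the selected gate", {
  p <- unit_probability(40, 1 / 398)
  v <- gate_rates(p, 40, beta_A_l = 10, p_fwd_gate_eq = 1 / 398,
                  p_bwd_gate_eq = 1 / 398)
  expect_equal(p + v$v_plus, 1, tolerance = 1e-12)
  # detailed-balance case: zero force, equal occupations
  v0 <- gate_rates(0.2, 10, 0, 0.05, 0.05)
  expect_equal(v0$v_plus, v0$v_minus)
  # the Boltzmann factor suppresses the backward rate
  v10 <- gate_rates(0.2, 10, 10, 0.05, 0.05)
  expect_equal(v10$v_minus / v10$v_plus, exp(-10), tolerance = 1e-12)
})

test_that("machine networks close every row to one, the selected gate exactly", {
  withr::with_seed(8, {
    net <- gated_tree(n = 30, tau1 = 10, tau2 = 10, beta_A1 = 8, beta_A2 = 0)
  })
  gs <- attr(net, "gate_system")
  sums <- vapply(0:(net$n_nodes - 1), function(l)
    sum(net$edges$p[net$edges$from == l]), 0)
  expect_equal(sums, rep(1, net$n_nodes), tolerance = 1e-12)
  sel <- gs$gates[[gs$selected_gate]]
  expect_false(any(net$edges$from == sel & net$edges$to == sel))  # no waiting
  # interior node of degree k: k internal edges of p/k plus waiting
  deg <- mfptnet:::support_degrees(gs$net)
  interior <- setdiff(which(deg >= 3) - 1L, gs$gates)[1]
  ei <- net$edges[net$edges$from == interior, ]
  kint <- deg[interior + 1]
  expect_equal(sum(ei$from == ei$to), 1)
  expect_equal(ei$p[ei$from != ei$to], rep(gs$p / kint, kint))
  # all machine local times are one step
  expect_true(all(net$edges$tau == 1))
})

test_that("external times too small for the gate choice are rejected", {
  base <- generate_network("random_tree", n = 12, seed = 3)
  deg <- mfptnet:::support_degrees(base)
  leaves <- which(deg == 1) - 1
  gs <- gate_system(base, leaves[1], leaves[2], leaves[3], leaves[4],
                    tau1 = 0.5, tau2 = 500, beta_A1 = 0, beta_A2 = 0,
                    selected_gate = "2pp")
  expect_error(build_machine_network(gs), "external time too small")
})

test_that("detailed balance: zero forces give equilibrium occupation, zero net flux", {
  withr::with_seed(19, {
    net <- gated_tree(n = 16, tau1 = 6, tau2 = 6, beta_A1 = 0, beta_A2 = 0)
  })
  gs <- attr(net, "gate_system")
  pst <- stationary_solve(to_rates(net))
  expect_equal(pst$p_st, gs$eq$p_eq, tolerance = 1e-9)
  # net one-way flux difference across each gate vanishes
  for (l in 1:2) {
    gp <- gs$gates[[paste0(l, "p")]]; gpp <- gs$gates[[paste0(l, "pp")]]
    vl <- gs$v[[paste0("v", l)]]
    Jnet <- vl$v_plus * pst$p_st[pst$node == gpp] -
      vl$v_minus * pst$p_st[pst$node == gp]
    expect_lt(abs(Jnet), 1e-9)
  }
})

test_that("one-way fluxes match the stationary probability current", {
  withr::with_seed(37, {
    net <- gated_tree(n = 12, tau1 = 5, tau2 = 5, beta_A1 = 6, beta_A2 = 0)
  })
  gs <- attr(net, "gate_system")
  pst <- stationary_solve(to_rates(net))
  for (l in 1:2) {
    gp <- gs$gates[[paste0(l, "p")]]; gpp <- gs$gates[[paste0(l, "pp")]]
    vl <- gs$v[[paste0("v", l)]]
    jp <- one_way_flux(net, gpp, gp, method = "hill")$flux
    jm <- one_way_flux(net, gp, gpp, method = "hill")$flux
    Jdirect <- vl$v_plus * pst$p_st[pst$node == gpp] -
      vl$v_minus * pst$p_st[pst$node == gp]
    expect_equal(jp - jm, Jdirect, tolerance = 1e-8)
  }
})

test_that("the MFPT decomposition identity holds on random gated trees", {
  withr::with_seed(43, {
    for (i in 1:6) {
      net <- gated_tree(n = sample(10:18, 1), tau1 = 5, tau2 = 5,
                        beta_A1 = sample(0:8, 1), beta_A2 = 0,
                        placement = sample(c("coupled", "random"), 1))
      gs <- attr(net, "gate_system")
      gp <- gs$gates[["2p"]]; gpp <- gs$gates[["2pp"]]
      ow <- one_way_flux(net, gpp, gp, method = "hill")
      de <- decompose_mfpt(net, gpp, gp, method = "hill")
      expect_equal(de$total, ow$mfpt, tolerance = 1e-6)
      expect_gt(de$internal_mfpt, 0)
      expect_gt(de$gate_term, 0)
    }
  })
})

test_that("degree of coupling and efficiency follow from the one-way fluxes", {
  # the four printed one-way MFPTs of the worked free-energy-transduction
  # example determine epsilon = 0.992 (Hill) and ~0.978 (Monte Carlo)
  hill <- coupling_and_efficiency(1 / 5050.17, 1 / 5086078.41,
                                  1 / 423.29, 1 / 461.62,
                                  beta_A1 = 10, beta_A2 = 0)
  expect_equal(round(hill$epsilon, 3), 0.992)
  expect_true(is.na(hill$eta))  # zero output force: undefined, not zero
  mc <- coupling_and_efficiency(1 / 5048.95, 1 / 5081053.61,
                                1 / 425.39, 1 / 463.55,
                                beta_A1 = 10, beta_A2 = 0)
  expect_equal(round(mc$epsilon, 3), 0.978)
  # uncoupled case and the J1 = 0 guard
  expect_equal(coupling_and_efficiency(2, 1, 5, 5, 1, -1)$epsilon, 0)
  expect_error(coupling_and_efficiency(1, 1, 2, 1, 1, 0), "J1 is zero")
  # both forces non-zero: eta defined
  both <- coupling_and_efficiency(2, 1, 0.5, 1, beta_A1 = 4, beta_A2 = -2)
  expect_equal(both$eta, -0.25)  # -J2*A2 / (J1*A1) with J1 = 1, J2 = -0.5
})

test_that("a driven coupled machine transduces: positive coupling below one", {
  withr::with_seed(51, {
    net <- gated_tree(n = 40, tau1 = 15, tau2 = 15, beta_A1 = 10, beta_A2 = 0)
  })
  gs <- attr(net, "gate_system")
  mf <- machine_fluxes(gs, method = "hill")
  expect_gt(mf$epsilon, 0)
  expect_lte(mf$epsilon, 1 + 1e-9)
  expect_true(is.na(mf$eta))
  td <- tidy(mf); gl <- glance(mf)
  expect_identical(td$flux, c("J+1", "J-1", "J+2", "J-2"))
  expect_true(all(td$value > 0))
  expect_equal(gl$epsilon, mf$epsilon)
})
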