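#' Equilibrium occupation of a conformational network
#'
#' For an undirected conformational network whose internal transition rates
#' are `p/k_l` out of each node (equal splitting over the `k_l` neighbours),
#' detailed balance fixes the equilibrium occupation at
#' `p_l_eq = k_l / sum(k)`. For a tree `sum(k) = 2(N-1)`.
#'
#' @param net A [stoch_net()] whose undirected support is the conformational
#'   network (self-loops ignored).
#' @return Tibble `(node, degree, p_eq)` summing to one.
#' @export
equilibrium_occupation <- function(net) {
  k <- support_degrees(net)
  tibble::tibble(node = 0:(net$n_nodes - 1L), degree = k, p_eq = k / sum(k))
}

#' Unit probability fixing the machine time scale
#'
#' The internal transition probability `p` shared by all conformational
#' moves is pinned by requiring that, at the gate with the largest external
#' transition probability, internal and external probabilities fill the
#' whole unit: `p + v = 1`. For a forward exit this gives
#' `p = 1 / (1 + (tau_l * p_gate_eq)^-1)`.
#'
#' @param tau_l External transition time at the selected gate (> 0).
#' @param p_gate_eq Equilibrium occupation of the selected gate, in (0, 1].
#' @param boltzmann Optional factor `exp(-beta_A)` when the selected exit is
#'   a backward one (default 1, the forward case).
#' @return `p` in (0, 1).
#' @examples
#' unit_probability(40, 1/398)  # ~0.091
#' @export
unit_probability <- function(tau_l, p_gate_eq, boltzmann = 1) {
  stopifnot(tau_l > 0, p_gate_eq > 0, p_gate_eq <= 1)
  1 / (1 + boltzmann / (tau_l * p_gate_eq))
}

#' External gate transition probabilities
#'
#' Forward (exit from the double-primed gate) and backward (exit from the
#' primed gate) external transition probabilities:
#' `v_plus = p / (tau_l * p_eq(l''))` and
#' `v_minus = p * exp(-beta_A_l) / (tau_l * p_eq(l'))`. The Boltzmann factor
#' breaks detailed balance; with `beta_A = 0` and equal gate occupations the
#' two rates coincide.
#'
#' @param p Unit probability from [unit_probability()].
#' @param tau_l External transition time.
#' @param beta_A_l Dimensionless force.
#' @param p_fwd_gate_eq Equilibrium occupation of the forward-exit gate
#'   (`l''`).
#' @param p_bwd_gate_eq Equilibrium occupation of the backward-exit gate
#'   (`l'`).
#' @return List with `v_plus` and `v_minus`.
#' @export
gate_rates <- function(p, tau_l, beta_A_l, p_fwd_gate_eq, p_bwd_gate_eq) {
  stopifnot(p > 0, tau_l > 0, p_fwd_gate_eq > 0, p_bwd_gate_eq > 0)
  list(v_plus = p / (tau_l * p_fwd_gate_eq),
       v_minus = p * exp(-beta_A_l) / (tau_l * p_bwd_gate_eq))
}

#' Define a chemo-chemical machine (gated conformational network)
#'
#' Couples two reversible reactions through a conformational network: each
#' reaction `l = 1, 2` passes through a pair of gate nodes (primed =
#' backward exit, double-primed = forward exit) with external transition
#' time `tau_l` and dimensionless force `beta_A_l`. The internal unit
#' probability `p` is fixed by [unit_probability()] at the gate with the
#' highest external transition probability (overridable through
#' `selected_gate`), so that gate carries no waiting probability.
#'
#' @param net Conformational network ([stoch_net()]); only its undirected
#'   support is used.
#' @param gate_1p,gate_1pp,gate_2p,gate_2pp The four distinct gate node ids
#'   (1', 1'', 2', 2'').
#' @param tau1,tau2 External transition times (> 0).
#' @param beta_A1,beta_A2 Dimensionless forces.
#' @param selected_gate Optional: one of `"1p"`, `"1pp"`, `"2p"`, `"2pp"`
#'   to force the Eq.-15 gate choice.
#' @return A `gate_system` object.
#' @export
gate_system <- function(net, gate_1p, gate_1pp, gate_2p, gate_2pp,
                        tau1, tau2, beta_A1 = 0, beta_A2 = 0,
                        selected_gate = NULL) {
  gates <- c(`1p` = as.integer(gate_1p), `1pp` = as.integer(gate_1pp),
             `2p` = as.integer(gate_2p), `2pp` = as.integer(gate_2pp))
  stopifnot(length(unique(gates)) == 4, tau1 > 0, tau2 > 0)
  eq <- equilibrium_occupation(net)
  p_eq <- eq$p_eq[match(gates, eq$node)]
  names(p_eq) <- names(gates)
  # exit transitions: 1'' forward (factor 1), 1' backward (exp(-bA1)), etc.
  score <- c(`1pp` = 1 / (tau1 * p_eq[["1pp"]]),
             `1p` = exp(-beta_A1) / (tau1 * p_eq[["1p"]]),
             `2pp` = 1 / (tau2 * p_eq[["2pp"]]),
             `2p` = exp(-beta_A2) / (tau2 * p_eq[["2p"]]))
  if (is.null(selected_gate)) {
    best <- max(score)
    cand <- names(score)[score >= best * (1 - 1e-12)]
    selected_gate <- cand[order(p_eq[cand])][1]
  }
  stopifnot(selected_gate %in% names(gates))
  tau_sel <- if (selected_gate %in% c("1p", "1pp")) tau1 else tau2
  bfac <- c(`1pp` = 1, `1p` = exp(-beta_A1), `2pp` = 1, `2p` = exp(-beta_A2))
  p <- unit_probability(tau_sel, p_eq[[selected_gate]],
                        boltzmann = bfac[[selected_gate]])
  v1 <- gate_rates(p, tau1, beta_A1, p_eq[["1pp"]], p_eq[["1p"]])
  v2 <- gate_rates(p, tau2, beta_A2, p_eq[["2pp"]], p_eq[["2p"]])
  structure(list(net = net, gates = gates, tau = c(tau1, tau2),
                 beta_A = c(beta_A1, beta_A2), p = p,
                 selected_gate = selected_gate, eq = eq,
                 v = list(v1 = v1, v2 = v2)), class = "gate_system")
}

#' @export
print.gate_system <- function(x, ...) {
  cat(sprintf("<gate_system> %d conformational states; gates 1'=%d 1''=%d 2'=%d 2''=%d\n",
              x$net$n_nodes, x$gates[["1p"]], x$gates[["1pp"]],
              x$gates[["2p"]], x$gates[["2pp"]]))
  cat(sprintf("  tau = (%g, %g), beta_A = (%g, %g), p = %.6g (gate %s)\n",
              x$tau[1], x$tau[2], x$beta_A[1], x$beta_A[2], x$p, x$selected_gate))
  cat(sprintf("  v+1 = %.6g, v-1 = %.6g, v+2 = %.6g, v-2 = %.6g\n",
              x$v$v1$v_plus, x$v$v1$v_minus, x$v$v2$v_plus, x$v$v2$v_minus))
  invisible(x)
}

#' Assemble the full machine network
#'
#' Internal edges get probability `p / k_l` each; the gate nodes get the
#' external edges (`1'' -> 1'` with `v_plus_1`, `1' -> 1''` with
#' `v_minus_1`, likewise for reaction 2); every node's deficit from one
#' becomes a waiting self-loop. All local times are 1: machine time is
#' counted in walker steps. At the selected gate the waiting probability is
#' exactly zero by construction.
#'
#' @param gs A [gate_system()].
#' @return A [stoch_net()] whose edge table carries a `kind` column
#'   (`"internal"`, `"external"`, `"wait"`) and attributes `gates` and
#'   `gate_system`.
#' @export
build_machine_network <- function(gs) {
  n <- gs$net$n_nodes
  sup <- undirected_support(gs$net)
  k <- support_degrees(gs$net)
  from <- c(sup$a, sup$b); to <- c(sup$b, sup$a)
  p <- gs$p / k[from + 1L]
  kind <- rep("internal", length(from))
  ext <- tibble::tibble(
    from = c(gs$gates[["1pp"]], gs$gates[["1p"]], gs$gates[["2pp"]], gs$gates[["2p"]]),
    to   = c(gs$gates[["1p"]], gs$gates[["1pp"]], gs$gates[["2p"]], gs$gates[["2pp"]]),
    p    = c(gs$v$v1$v_plus, gs$v$v1$v_minus, gs$v$v2$v_plus, gs$v$v2$v_minus))
  from <- c(from, ext$from); to <- c(to, ext$to)
  p <- c(p, ext$p); kind <- c(kind, rep("external", 4))
  # waiting closure
  outsum <- vapply(0:(n - 1L), function(l) sum(p[from == l]), 0)
  if (any(outsum > 1 + 1e-12)) {
    bad <- which(outsum > 1 + 1e-12)[1] - 1L
    stop(sprintf("node %d: probabilities sum to %.6g > 1; external time too small for this gate choice",
                 bad, outsum[bad + 1L]))
  }
  wait <- 1 - outsum
  wl <- which(wait > 1e-12) - 1L
  from <- c(from, wl); to <- c(to, wl)
  p <- c(p, wait[wl + 1L]); kind <- c(kind, rep("wait", length(wl)))
  edges <- tibble::tibble(from = from, to = to, p = p, tau = 1, kind = kind)
  # exact closure: renormalize tiny float residue per node
  for (l in unique(edges$from)) {
    idx <- which(edges$from == l)
    edges$p[idx] <- edges$p[idx] / sum(edges$p[idx])
  }
  net <- stoch_net(n, edges[, c("from", "to", "p", "tau")])
  net$edges$kind <- edges$kind
  attr(net, "gates") <- gs$gates
  attr(net, "gate_system") <- gs
  net
}

# locate the external edge from_gate -> to_gate in a machine network
find_external_edge <- function(net, from_gate, to_gate) {
  e <- net$edges
  idx <- which(e$from == from_gate & e$to == to_gate)
  if ("kind" %in% names(e) && length(idx) > 1) {
    idx <- idx[e$kind[idx] == "external"]
  }
  if (length(idx) != 1) {
    stop(sprintf("expected exactly one transition %d -> %d (found %d)",
                 from_gate, to_gate, length(idx)))
  }
  idx
}

# augmented network: append absorbing node * (id n_nodes) and redirect the
# from_gate -> to_gate transition into it
augment_with_star <- function(net, from_gate, to_gate) {
  idx <- find_external_edge(net, from_gate, to_gate)
  e <- net$edges
  star <- net$n_nodes
  e$to[idx] <- star
  e$p_num[idx] <- NA_real_; e$p_den[idx] <- NA_real_
  out <- stoch_net(net$n_nodes + 1L, e[, c("from", "to", "p", "tau")])
  if ("kind" %in% names(net$edges)) out$edges$kind <- net$edges$kind
  attr(out, "star") <- star
  attr(out, "redirected_p") <- net$edges$p[idx]
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' One-way stationary flux across a gate
#'
#' Computes a one-way reaction flux by the first-passage construction: a
#' new absorbing node `*` is appended, the transition `from_gate ->
#' to_gate` is redirected into `*`, and the flux is the reciprocal MFPT
#' from the opposite gate of the pair to `*`.
#'
#' @param net Machine network from [build_machine_network()].
#' @param from_gate,to_gate The redirected transition (e.g. `1'' -> 1'` for
#'   the forward flux of reaction 1).
#' @param start Node the passage starts from (the opposite gate; defaults
#'   to `to_gate`, which is the opposite gate for an external pair).
#' @param method `"hill"` or `"montecarlo"`.
#' @param ... Passed to [mfpt_hill()] or [mfpt_mc()].
#' @return List with `flux` and `mfpt`.
#' @export
one_way_flux <- function(net, from_gate, to_gate, start = to_gate,
                         method = c("hill", "montecarlo"), ...) {
  method <- match.arg(method)
  aug <- augment_with_star(net, from_gate, to_gate)
  star <- attr(aug, "star")
  tau <- if (method == "hill") as.numeric(mfpt_hill(aug, start, star, ...)) else
    mfpt_mc(aug, start, star, ...)$value
  if (!is.finite(tau) || tau <= 0) stop("one-way MFPT not finite; check the gate wiring")
  list(flux = 1 / tau, mfpt = tau)
}

#' Split a one-way MFPT into conformational and gate contributions
#'
#' Uses the decomposition `tau(start -> *) = tau(start -> from_gate) +
#' 1 / (v * p_st(from_gate))`: the redirected external edge is replaced by
#' a self-loop at `from_gate`, the internal MFPT and the stationary
#' occupation of `from_gate` are computed on that closed network, and the
#' gate term is the reciprocal of the stationary one-way rate through the
#' external transition.
#'
#' @inheritParams one_way_flux
#' @return List with `internal_mfpt`, `gate_term`, `total`.
#' @export
decompose_mfpt <- function(net, from_gate, to_gate, start = to_gate,
                           method = c("hill", "montecarlo"), ...) {
  method <- match.arg(method)
  idx <- find_external_edge(net, from_gate, to_gate)
  v <- net$edges$p[idx]
  e <- net$edges
  e$to[idx] <- from_gate  # close the network: external exit becomes waiting
  closed <- stoch_net(net$n_nodes, e[, c("from", "to", "p", "tau")])
  if ("kind" %in% names(net$edges)) closed$edges$kind <- net$edges$kind
  internal <- if (method == "hill") as.numeric(mfpt_hill(closed, start, from_gate, ...)) else
    mfpt_mc(closed, start, from_gate, ...)$value
  pst <- stationary_solve(to_rates(closed))
  p_gate <- pst$p_st[pst$node == from_gate]
  gate_term <- 1 / (v * p_gate)
  list(internal_mfpt = internal, gate_term = gate_term,
       total = internal + gate_term)
}

#' Degree of coupling and efficiency from one-way fluxes
#'
#' Net fluxes are `J_l = J_plus_l - J_minus_l`; the degree of coupling is
#' `epsilon = J_2 / J_1` and the efficiency `eta = -J_2 A_2 / (J_1 A_1)`.
#' With a zero output force (`beta_A2 = 0`) the efficiency is reported as
#' undefined (`NA`), not zero.
#'
#' @param j_plus_1,j_minus_1,j_plus_2,j_minus_2 One-way fluxes (>= 0).
#' @param beta_A1,beta_A2 Dimensionless forces.
#' @return List with `J1`, `J2`, `epsilon`, `eta` (`NA` when undefined).
#' @export
coupling_and_efficiency <- function(j_plus_1, j_minus_1, j_plus_2, j_minus_2,
                                    beta_A1, beta_A2) {
  J1 <- j_plus_1 - j_minus_1
  J2 <- j_plus_2 - j_minus_2
  if (J1 == 0) stop("input reaction flux J1 is zero; degree of coupling undefined")
  eta <- if (beta_A1 != 0 && beta_A2 != 0) -J2 * beta_A2 / (J1 * beta_A1) else NA_real_
  list(J1 = J1, J2 = J2, epsilon = J2 / J1, eta = eta)
}

#' Full flux / coupling analysis of a machine
#'
#' Computes the four one-way MFPTs and fluxes, the net fluxes, the degree
#' of coupling and (when defined) the efficiency.
#'
#' @param gs A [gate_system()].
#' @param method `"hill"` or `"montecarlo"`.
#' @param ... Passed to the MFPT route.
#' @return A `machine_flux` object: tibble of one-way results plus scalars.
#' @export
machine_fluxes <- function(gs, method = c("hill", "montecarlo"), ...) {
  method <- match.arg(method)
  net <- build_machine_network(gs)
  g <- gs$gates
  spec <- tibble::tibble(
    flux = c("J+1", "J-1", "J+2", "J-2"),
    from = c(g[["1pp"]], g[["1p"]], g[["2pp"]], g[["2p"]]),
    to   = c(g[["1p"]], g[["1pp"]], g[["2p"]], g[["2pp"]]))
  res <- purrr::pmap(spec, function(flux, from, to) {
    ow <- one_way_flux(net, from, to, start = to, method = method, ...)
    tibble::tibble(flux = flux, mfpt = ow$mfpt, value = ow$flux)
  }) |> dplyr::bind_rows()
  ce <- coupling_and_efficiency(res$value[1], res$value[2],
                                res$value[3], res$value[4],
                                gs$beta_A[1], gs$beta_A[2])
  structure(list(one_way = res, J1 = ce$J1, J2 = ce$J2,
                 epsilon = ce$epsilon, eta = ce$eta,
                 method = method, gate_system = gs), class = "machine_flux")
}

#' @export
print.machine_flux <- function(x, ...) {
  cat(sprintf("<machine_flux> method = %s\n", x$method))
  print(x$one_way)
  cat(sprintf("J1 = %.6g, J2 = %.6g, epsilon = %.4g, eta = %s\n",
              x$J1, x$J2, x$epsilon,
              if (is.na(x$eta)) "undefined (zero output force)" else
                format(x$eta, digits = 4)))
  invisible(x)
}
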