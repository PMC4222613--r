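# --- undirected-support constructions (edge tibbles a < b) ------------------

support_cycle <- function(n) {
  stopifnot(n >= 3)
  tibble::tibble(a = 0:(n - 1L), b = c(1:(n - 1L), 0L)) |>
    (\(d) tibble::tibble(a = pmin(d$a, d$b), b = pmax(d$a, d$b)))()
}

support_hypercube <- function(d) {
  stopifnot(d >= 1)
  n <- 2L^d
  rows <- list()
  for (v in 0:(n - 1L)) {
    for (bit in 0:(d - 1L)) {
      u <- bitwXor(v, bitwShiftL(1L, bit))
      if (u > v) rows[[length(rows) + 1]] <- c(v, u)
    }
  }
  m <- do.call(rbind, rows)
  tibble::tibble(a = m[, 1], b = m[, 2])
}

support_sierpinski <- function(order) {
  stopifnot(order >= 0)
  # integer coordinates (x, y) in the triangular-lattice basis
  pts <- rbind(c(0, 0), c(1, 0), c(0, 1))
  edges <- rbind(c(1, 2), c(1, 3), c(2, 3))
  for (g in seq_len(order)) {
    shift <- 2L^(g - 1L)
    key <- function(m) paste(m[, 1], m[, 2])
    p1 <- pts
    p2 <- cbind(pts[, 1] + shift, pts[, 2])
    p3 <- cbind(pts[, 1], pts[, 2] + shift)
    allp <- rbind(p1, p2, p3)
    uk <- unique(key(allp))
    idx_of <- function(m) match(key(m), uk)
    ne <- rbind(
      cbind(idx_of(p1)[edges[, 1]], idx_of(p1)[edges[, 2]]),
      cbind(idx_of(p2)[edges[, 1]], idx_of(p2)[edges[, 2]]),
      cbind(idx_of(p3)[edges[, 1]], idx_of(p3)[edges[, 2]]))
    pts <- do.call(rbind, lapply(strsplit(uk, " "), as.integer))
    edges <- ne
  }
  a <- pmin(edges[, 1], edges[, 2]) - 1L
  b <- pmax(edges[, 1], edges[, 2]) - 1L
  tibble::tibble(a = a, b = b)
}

support_bethe <- function(coordination, shells) {
  stopifnot(coordination >= 2, shells >= 1)
  a <- integer(0); b <- integer(0)
  nxt <- 1L
  frontier <- 0L
  for (s in seq_len(shells)) {
    newf <- integer(0)
    for (v in frontier) {
      kids <- if (s == 1) coordination else coordination - 1L
      if (kids > 0) {
        ids <- nxt:(nxt + kids - 1L)
        a <- c(a, rep(v, kids)); b <- c(b, ids)
        nxt <- nxt + kids
        newf <- c(newf, ids)
      }
    }
    frontier <- newf
  }
  tibble::tibble(a = a, b = b)
}

support_random_tree <- function(n) {
  stopifnot(n >= 2)
  parent <- c(NA, vapply(2:n, function(i) sample.int(i - 1L, 1), 0L))
  tibble::tibble(a = parent[-1] - 1L, b = 1:(n - 1L))
}

support_fractal_scale_free_tree <- function(n, repulsion = 0.7) {
  stopifnot(n >= 2)
  deg <- integer(n); parent <- integer(n)
  deg[1:2] <- 1L
  a <- 0L; b <- 1L
  adj <- list(`1` = 2L, `2` = 1L)
  for (i in 3:n) {
    # preferential choice, then hop to a (typically low-degree) neighbour
    tgt <- sample.int(i - 1L, 1, prob = deg[1:(i - 1L)])
    if (stats::runif(1) < repulsion) {
      nbs <- adj[[as.character(tgt)]]
      tgt <- nbs[sample.int(length(nbs), 1)]
    }
    a <- c(a, tgt - 1L); b <- c(b, i - 1L)
    deg[tgt] <- deg[tgt] + 1L; deg[i] <- 1L
    adj[[as.character(tgt)]] <- c(adj[[as.character(tgt)]], i)
    adj[[as.character(i)]] <- tgt
  }
  tibble::tibble(a = a, b = b)
}

# --- dressing a support with probabilities and times ------------------------

# Build a stoch_net from an undirected support: both directions per pair.
# prob_mode uniform: 1/k rationals; random_rational: integer weights 1..4.
# time_mode unit: tau = 1; random: tau drawn from {0.1, 0.2, ..., 5.0},
# asymmetric per direction. self_loop_prob adds waiting weight to a node.
dress_support <- function(sup, n_nodes, prob_mode = c("uniform", "random_rational"),
                          time_mode = c("unit", "random"), self_loop_prob = 0) {
  prob_mode <- match.arg(prob_mode)
  time_mode <- match.arg(time_mode)
  from <- c(sup$a, sup$b); to <- c(sup$b, sup$a)
  loops <- which(stats::runif(n_nodes) < self_loop_prob) - 1L
  from <- c(from, loops); to <- c(to, loops)
  wgt <- if (prob_mode == "uniform") rep(1, length(from)) else
    sample(1:4, length(from), replace = TRUE)
  rows <- lapply(0:(n_nodes - 1L), function(l) {
    idx <- which(from == l)
    if (length(idx) == 0) return(NULL)
    tot <- sum(wgt[idx])
    tau <- if (time_mode == "unit") rep(1, length(idx)) else
      sample(1:50, length(idx), replace = TRUE) / 10
    tibble::tibble(from = l, to = to[idx],
                   p = wgt[idx] / tot, tau = tau,
                   p_num = wgt[idx], p_den = tot,
                   tau_num = if (time_mode == "unit") 1 else NA_real_,
                   tau_den = if (time_mode == "unit") 1 else NA_real_)
  })
  stoch_net(n_nodes, dplyr::bind_rows(rows))
}

#' Generate a benchmark network
#'
#' Deterministic (for a fixed seed) constructions of the benchmark
#' topologies used to exercise both MFPT routes: hypercubes, Sierpinski
#' gaskets, Bethe lattices, random trees, fractal scale-free trees (hub-
#' repulsion preferential attachment), cycles and the 4-node square, plus
#' gated trees (see [build_machine_network()]) and a small irregular
#' 9-node network in the style of a hand-drawn example
#' ([figure1_style()]).
#'
#' @param family One of `"square"`, `"cycle"`, `"hypercube"`,
#'   `"sierpinski"`, `"bethe"`, `"random_tree"`,
#'   `"fractal_scale_free_tree"`, `"gated_tree"`, `"figure1_style"`.
#' @param n Number of nodes (cycle and tree families).
#' @param d Hypercube dimension.
#' @param order Sierpinski gasket order (0 = a triangle).
#' @param coordination,shells Bethe-lattice parameters.
#' @param prob_mode `"uniform"` (probability `1/k`, kept as exact
#'   rationals) or `"random_rational"` (random small-integer weights).
#' @param time_mode `"unit"` (all local times 1) or `"random"`
#'   (asymmetric times on the grid `0.1 .. 5.0`).
#' @param self_loop_prob Probability that a node receives a waiting
#'   self-loop.
#' @param seed Integer seed; every randomized family takes one explicitly.
#' @param ... Passed to [gate_system()] for `family = "gated_tree"`.
#' @return A [stoch_net()].
#' @examples
#' generate_network("hypercube", d = 2)  # the 4-node square, u = 1/2
#' @export
generate_network <- function(family = c("square", "cycle", "hypercube",
                                        "sierpinski", "bethe", "random_tree",
                                        "fractal_scale_free_tree", "gated_tree",
                                        "figure1_style"),
                             n = NULL, d = NULL, order = NULL,
                             coordination = 3, shells = 2,
                             prob_mode = "uniform", time_mode = "unit",
                             self_loop_prob = 0, seed = NULL, ...) {
  family <- match.arg(family)
  if (!is.null(seed)) set.seed(seed)
  if (family == "figure1_style") return(figure1_style(seed = NULL))
  if (family == "gated_tree") return(gated_tree(n = if (is.null(n)) 20 else n, ...))
  sup <- switch(family,
    square = support_cycle(4),
    cycle = { stopifnot(!is.null(n)); support_cycle(n) },
    hypercube = { stopifnot(!is.null(d)); support_hypercube(d) },
    sierpinski = { stopifnot(!is.null(order)); support_sierpinski(order) },
    bethe = support_bethe(coordination, shells),
    random_tree = { stopifnot(!is.null(n)); support_random_tree(n) },
    fractal_scale_free_tree = { stopifnot(!is.null(n)); support_fractal_scale_free_tree(n) })
  n_nodes <- max(sup$a, sup$b) + 1L
  dress_support(sup, n_nodes, prob_mode, time_mode, self_loop_prob)
}

#' A small irregular network with one cycle, waiting and asymmetric times
#'
#' Builds a 9-node, 9-edge network emulating the structure of a small
#' worked example: a random spanning tree plus one chord (a single cycle),
#' at least one waiting self-loop, exact-rational asymmetric probabilities
#' and asymmetric decimal local times. Rows always sum to one.
#'
#' @param seed Optional integer seed.
#' @return A [stoch_net()] with 9 nodes and 9 undirected support edges.
#' @export
figure1_style <- function(seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- 9L
  sup <- support_random_tree(n)
  # add one chord not already present -> exactly one cycle
  repeat {
    cand <- sort(sample.int(n, 2) - 1L)
    if (!any(sup$a == cand[1] & sup$b == cand[2])) break
  }
  sup <- rbind(sup, tibble::tibble(a = cand[1], b = cand[2]))
  net <- dress_support(sup, n, prob_mode = "random_rational",
                       time_mode = "random", self_loop_prob = 0.3)
  # guarantee at least one waiting self-loop
  if (!any(net$edges$from == net$edges$to)) {
    l <- sample.int(n, 1) - 1L
    idx <- which(net$edges$from == l)
    extra <- 1
    tot <- sum(net$edges$p_num[idx]) + extra
    net$edges$p_den[idx] <- tot
    net$edges$p[idx] <- net$edges$p_num[idx] / tot
    net$edges <- dplyr::bind_rows(net$edges, tibble::tibble(
      from = l, to = l, p = extra / tot, tau = 1,
      p_num = extra, p_den = tot, tau_num = 1, tau_den = 1))
    net <- stoch_net(n, net$edges)
  }
  net
}

#' A random gated tree (machine network fixture)
#'
#' Random tree with four distinct gate nodes, dressed into a full machine
#' network via [gate_system()] and [build_machine_network()]. With
#' `placement = "coupled"` (default) the primed gates are leaves near one
#' end of the tree diameter and the double-primed gates leaves near the
#' other, so the cycles of the two reactions share the backbone path and
#' the driving reaction can drag the driven one — the arrangement that
#' yields a degree of coupling near one. `placement = "random"` scatters
#' the gates, which typically decouples the reactions.
#'
#' @param n Tree size.
#' @param tau1,tau2 External transition times.
#' @param beta_A1,beta_A2 Dimensionless chemical forces.
#' @param placement `"coupled"` or `"random"`.
#' @param fractal Use the fractal scale-free construction (default) rather
#'   than a uniform random tree.
#' @return A machine [stoch_net()] with a `gates` attribute.
#' @export
gated_tree <- function(n = 20, tau1 = 10, tau2 = 10, beta_A1 = 5, beta_A2 = 0,
                       placement = c("coupled", "random"), fractal = TRUE) {
  placement <- match.arg(placement)
  sup <- if (fractal) support_fractal_scale_free_tree(n) else support_random_tree(n)
  base <- dress_support(sup, n, prob_mode = "uniform", time_mode = "unit")
  deg <- support_degrees(base)
  leaves <- which(deg == 1L) - 1L
  if (length(leaves) < 4) leaves <- 0:(n - 1L)
  if (placement == "random") {
    gates <- sample(leaves, 4)
  } else {
    g <- igraph::graph_from_data_frame(
      data.frame(from = sup$a + 1L, to = sup$b + 1L), directed = FALSE,
      vertices = data.frame(name = seq_len(n)))
    far <- igraph::get_diameter(g)
    endA <- as.integer(far[1]) - 1L; endB <- as.integer(far[length(far)]) - 1L
    dA <- as.numeric(igraph::distances(g, v = endA + 1L))[leaves + 1L]
    dB <- as.numeric(igraph::distances(g, v = endB + 1L))[leaves + 1L]
    nearA <- leaves[order(dA)]
    nearB <- setdiff(leaves[order(dB)], nearA[1:2])
    # orientations chosen so both external hops drive the same circulation:
    # 1' and 2'' sit near one diameter end, 1'' and 2' near the other
    gates <- c(nearA[1], nearB[1], nearB[2], nearA[2])  # 1', 1'', 2', 2''
  }
  gs <- gate_system(base, gate_1p = gates[1], gate_1pp = gates[2],
                    gate_2p = gates[3], gate_2pp = gates[4],
                    tau1 = tau1, tau2 = tau2,
                    beta_A1 = beta_A1, beta_A2 = beta_A2)
  build_machine_network(gs)
}
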