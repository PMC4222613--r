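#' Mean step (residence) time of a node
#'
#' The mean time a walker spends per step at `node`: the probability-weighted
#' mean of local times over all outgoing edges, self-loops included.
#'
#' @param net A [stoch_net()].
#' @param node Node id (0-based).
#' @return Mean step time (double).
#' @export
mean_step_time <- function(net, node) {
  idx <- net$edges$from == node
  sum(net$edges$p[idx] * net$edges$tau[idx])
}

#' Convert per-step probabilities and local times to rates
#'
#' Maps each node's outgoing probabilities `u` and local times `tau` to
#' transition probabilities per unit time `w = u / s`, where `s` is the
#' node's mean step time. Self-loops contribute to `s` (they are waiting)
#' but generate no rate edge. A node whose mean step time is zero has no
#' well-defined rate picture and is rejected — Monte Carlo can still walk
#' such networks, the Hill route cannot.
#'
#' @param net A [stoch_net()].
#' @return A `rate_net`: list with `n_nodes` and an edge tibble
#'   `(from, to, w)`.
#' @export
to_rates <- function(net) {
  e <- net$edges
  s <- vapply(0:(net$n_nodes - 1L), function(l) mean_step_time(net, l), 0)
  has_out <- tabulate(e$from + 1L, nbins = net$n_nodes) > 0
  bad <- which(has_out & s <= 0)
  if (length(bad) > 0) {
    stop(sprintf("node %d has zero mean step time; at least one local time must be non-zero for the rate picture",
                 bad[1] - 1L))
  }
  keep <- e$from != e$to & e$p > 0
  re <- tibble::tibble(from = e$from[keep], to = e$to[keep],
                       w = e$p[keep] / s[e$from[keep] + 1L])
  structure(list(n_nodes = net$n_nodes, edges = re), class = "rate_net")
}

#' @export
print.rate_net <- function(x, ...) {
  cat(sprintf("<rate_net> %d nodes, %d rate edges\n", x$n_nodes, nrow(x$edges)))
  print(x$edges, n = 10)
  invisible(x)
}

# dense rate matrix W[to, from] (1-based), parallel edges summed
rate_matrix <- function(rates) {
  W <- matrix(0, rates$n_nodes, rates$n_nodes)
  e <- rates$edges
  for (i in seq_len(nrow(e))) {
    W[e$to[i] + 1L, e$from[i] + 1L] <- W[e$to[i] + 1L, e$from[i] + 1L] + e$w[i]
  }
  W
}

#' Stationary distribution of a rate network
#'
#' Solves the stationary master equation `sum_l' (w_{ll'} p_l' - w_{l'l} p_l)
#' = 0` with `sum p = 1` by a dense direct solve. The network must have a
#' single closed communicating class; otherwise the stationary distribution
#' is not unique and an error is raised.
#'
#' @param rates A `rate_net` from [to_rates()].
#' @return Tibble `(node, p_st)`, summing to one, residual `<= 1e-10`.
#' @export
stationary_solve <- function(rates) {
  n <- rates$n_nodes
  W <- rate_matrix(rates)
  g <- igraph::graph_from_adjacency_matrix(t(W) > 0, mode = "directed")
  comp <- igraph::components(g, mode = "strong")
  closed <- 0L
  for (cid in seq_len(comp$no)) {
    members <- which(comp$membership == cid)
    outside <- sum(W[-members, members, drop = FALSE])
    if (outside == 0) closed <- closed + 1L
  }
  if (closed != 1L) {
    stop(sprintf("network has %d closed communicating classes; stationary distribution not unique",
                 closed))
  }
  A <- W - diag(colSums(W))
  A[n, ] <- 1
  b <- c(rep(0, n - 1), 1)
  p <- solve(A, b)
  resid <- max(abs((W - diag(colSums(W))) %*% p))
  if (resid > 1e-10 * max(1, max(abs(W)))) {
    stop(sprintf("stationary residual %.3g exceeds tolerance", resid))
  }
  tibble::tibble(node = 0:(n - 1L), p_st = as.numeric(p))
}

# Absorption analysis for a query. Returns list(accessible, certain, sure_set)
# accessible: directed path initial -> some final exists.
# certain: absorption in finals is almost sure from initial.
absorption_info <- function(net, initial, finals) {
  g <- as_igraph(net)
  n <- net$n_nodes
  can_reach_final <- rep(FALSE, n)
  for (f in finals) {
    r <- igraph::subcomponent(g, f + 1L, mode = "in")
    can_reach_final[as.integer(r)] <- TRUE
  }
  accessible <- can_reach_final[initial + 1L]
  # nodes (non-final) from which escape to a "dead" node is possible
  dead <- which(!can_reach_final) - 1L
  nonfinal <- setdiff(0:(n - 1L), finals)
  # restricted walk: once in finals the walk stops, so only paths through
  # non-final nodes count for escaping
  e <- net$edges[net$edges$p > 0, , drop = FALSE]
  e <- e[e$from %in% nonfinal, , drop = FALSE]
  can_escape <- rep(FALSE, n)
  can_escape[dead + 1L] <- TRUE
  repeat {
    new <- can_escape[e$to + 1L] & !can_escape[e$from + 1L] & !(e$to %in% finals)
    if (!any(new)) break
    can_escape[e$from[new] + 1L] <- TRUE
  }
  list(accessible = accessible,
       certain = accessible && !can_escape[initial + 1L],
       can_reach_final = can_reach_final,
       can_escape = can_escape)
}

#' MFPT by first-step analysis (linear-algebra reference)
#'
#' Solves the first-step system `t_l = s_l + sum_{l' not final} u_{l'l} t_l'`
#' with `t = 0` on the final set, where `s_l` is the node's mean step time.
#' This is the exact reference both the Hill and Monte Carlo routes are
#' checked against. When `initial` is itself final, the return time (at
#' least one step) is computed. Returns `Inf` when the finals are not
#' almost-surely reached (no path, or positive probability of escaping into
#' a region that cannot reach them); the `accessible` attribute
#' distinguishes "no path at all" from "path exists but absorption is not
#' certain".
#'
#' @param net A [stoch_net()].
#' @param initial Starting node id.
#' @param finals Integer vector of final node ids (non-empty).
#' @return MFPT (double; `Inf` if not almost-surely absorbed) with
#'   attribute `accessible`.
#' @export
mfpt_linear <- function(net, initial, finals) {
  stopifnot(length(finals) >= 1)
  info <- absorption_info(net, initial, finals)
  if (!info$certain) {
    return(structure(Inf, accessible = info$accessible))
  }
  n <- net$n_nodes
  solve_set <- setdiff(which(info$can_reach_final & !info$can_escape) - 1L, finals)
  s <- vapply(0:(n - 1L), function(l) mean_step_time(net, l), 0)
  m <- length(solve_set)
  t_all <- rep(0, n)
  if (m > 0) {
    pos <- match(solve_set, solve_set)
    M <- matrix(0, m, m)
    e <- net$edges
    for (i in seq_len(nrow(e))) {
      fi <- match(e$from[i], solve_set)
      ti <- match(e$to[i], solve_set)
      if (!is.na(fi) && !is.na(ti)) M[fi, ti] <- M[fi, ti] + e$p[i]
    }
    rhs <- s[solve_set + 1L]
    tt <- tryCatch(solve(diag(m) - M, rhs), error = function(err)
      stop("first-step system is singular: ", conditionMessage(err)))
    t_all[solve_set + 1L] <- tt
  }
  if (initial %in% finals) {
    # return time: one forced step from the initial, then absorption
    e <- net$edges[net$edges$from == initial & net$edges$p > 0, , drop = FALSE]
    stray <- !(e$to %in% finals) &
      (!info$can_reach_final[e$to + 1L] | info$can_escape[e$to + 1L])
    if (any(stray)) return(structure(Inf, accessible = info$accessible))
    val <- s[initial + 1L] + sum(e$p * t_all[e$to + 1L] * !(e$to %in% finals))
  } else {
    val <- t_all[initial + 1L]
  }
  structure(val, accessible = TRUE)
}
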