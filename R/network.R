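#' Stochastic network of discrete states
#'
#' A `stoch_net` holds a directed multigraph of `n_nodes` states, numbered
#' `0 .. n_nodes - 1` as in the plain-text input formats. Each edge carries a
#' per-step transition probability `p` and a local time `tau` (the time cost
#' of traversing that edge). Self-loops model waiting in a state; parallel
#' edges and asymmetric probabilities/times are allowed, and a node with no
#' outgoing edges is absorbing.
#'
#' Probabilities parsed from common-fraction tokens keep their exact
#' numerator/denominator (`p_num`/`p_den`); decimal probabilities have `NA`
#' there. For every node with at least one outgoing edge the probabilities
#' must sum to one: exactly when all are fractions, within `1e-9` otherwise.
#'
#' @param n_nodes Number of states (positive integer).
#' @param edges Data frame with columns `from`, `to` (integer ids in
#'   `0 .. n_nodes-1`), `p` (probability), `tau` (local time, `>= 0`), and
#'   optionally `p_num`, `p_den`, `tau_num`, `tau_den` for exact fractions.
#' @param validate Check invariants (default `TRUE`).
#' @return A `stoch_net` object.
#' @examples
#' sq <- stoch_net(4, data.frame(
#'   from = rep(0:3, each = 2),
#'   to   = c(1, 3, 0, 2, 1, 3, 0, 2),
#'   p = 0.5, tau = 1))
#' sq
#' @export
stoch_net <- function(n_nodes, edges, validate = TRUE) {
  n_nodes <- as.integer(n_nodes)
  edges <- tibble::as_tibble(edges)
  for (col in c("p_num", "p_den", "tau_num", "tau_den")) {
    if (!col %in% names(edges)) edges[[col]] <- NA_real_
  }
  if (!"tau" %in% names(edges)) edges$tau <- 1
  edges <- edges[, c("from", "to", "p", "tau",
                     "p_num", "p_den", "tau_num", "tau_den")]
  edges$from <- as.integer(edges$from)
  edges$to <- as.integer(edges$to)
  # canonical storage: group edges by source node (stable, so the file
  # order of a node's edges -- and hence Monte Carlo cumulative ranges --
  # is preserved)
  edges <- edges[order(edges$from), , drop = FALSE]
  # canonicalize fractions so round-trips compare bit-identically
  for (pref in c("p", "tau")) {
    nc <- paste0(pref, "_num"); dc <- paste0(pref, "_den")
    whole <- which(is.na(edges[[nc]]) & edges[[pref]] == round(edges[[pref]]))
    edges[[nc]][whole] <- edges[[pref]][whole]
    edges[[dc]][whole] <- 1
    ok <- which(!is.na(edges[[nc]]) & !is.na(edges[[dc]]))
    for (i in ok) {
      g <- gcd2(edges[[nc]][i], edges[[dc]][i])
      if (g > 1) {
        edges[[nc]][i] <- edges[[nc]][i] / g
        edges[[dc]][i] <- edges[[dc]][i] / g
      }
    }
  }
  net <- structure(list(n_nodes = n_nodes, edges = edges),
                   class = "stoch_net")
  if (validate) validate_stoch_net(net)
  net
}

#' @export
print.stoch_net <- function(x, ...) {
  cat(sprintf("<stoch_net> %d nodes, %d edges (%d self-loops)\n",
              x$n_nodes, nrow(x$edges), sum(x$edges$from == x$edges$to)))
  print(x$edges, n = 10)
  invisible(x)
}

#' @export
as_tibble.stoch_net <- function(x, ...) x$edges

# greatest common divisor, vector-safe scalars
gcd2 <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0) { t <- a %% b; a <- b; b <- t }
  a
}

# exact sum of fractions given as num/den doubles; returns c(num, den)
frac_sum <- function(num, den) {
  acc <- c(0, 1)
  for (i in seq_along(num)) {
    n <- acc[1] * den[i] + num[i] * acc[2]
    d <- acc[2] * den[i]
    g <- gcd2(n, d)
    if (g > 0) { n <- n / g; d <- d / g }
    acc <- c(n, d)
  }
  acc
}

#' Validate a stochastic network
#'
#' Checks node-id range, non-negative local times, and per-node probability
#' sums (exact for fraction-typed probabilities, within `tol` for decimals).
#' Nodes without outgoing edges (absorbing) are skipped by the sum check.
#'
#' @param net A [stoch_net()].
#' @param tol Tolerance for decimal probability sums.
#' @return `net`, invisibly; errors name the offending node.
#' @export
validate_stoch_net <- function(net, tol = 1e-9) {
  e <- net$edges
  if (net$n_nodes < 1) stop("network must have at least one node")
  if (nrow(e) > 0) {
    bad <- e$from < 0L | e$from >= net$n_nodes | e$to < 0L | e$to >= net$n_nodes
    if (any(bad)) {
      stop(sprintf("edge references node outside 0..%d (first bad edge %d -> %d)",
                   net$n_nodes - 1L, e$from[which(bad)[1]], e$to[which(bad)[1]]))
    }
    if (any(e$tau < 0)) stop("local times must be >= 0")
    if (any(e$p < 0 | e$p > 1)) stop("edge probabilities must lie in [0, 1]")
    for (node in unique(e$from)) {
      idx <- which(e$from == node)
      if (all(!is.na(e$p_num[idx]))) {
        s <- frac_sum(e$p_num[idx], e$p_den[idx])
        if (!(s[1] == s[2])) {
          stop(sprintf("node %d: probabilities sum to %g/%g, not exactly 1",
                       node, s[1], s[2]))
        }
      } else if (abs(sum(e$p[idx]) - 1) > tol) {
        stop(sprintf("node %d: probabilities sum to %.12g, not 1 within %g",
                     node, sum(e$p[idx]), tol))
      }
    }
  }
  invisible(net)
}

# nodes with at least one outgoing positive-probability edge
out_nodes <- function(net) unique(net$edges$from[net$edges$p > 0])

# igraph view of the positive-probability directed structure (self-loops kept)
as_igraph <- function(net, drop_loops = FALSE) {
  e <- net$edges[net$edges$p > 0, , drop = FALSE]
  if (drop_loops) e <- e[e$from != e$to, , drop = FALSE]
  igraph::graph_from_data_frame(
    data.frame(from = e$from + 1L, to = e$to + 1L),
    directed = TRUE,
    vertices = data.frame(name = seq_len(net$n_nodes)))
}

# undirected simple support (unique unordered pairs, no self-loops)
undirected_support <- function(net) {
  e <- net$edges[net$edges$from != net$edges$to & net$edges$p > 0, , drop = FALSE]
  if (nrow(e) == 0) return(tibble::tibble(a = integer(), b = integer()))
  a <- pmin(e$from, e$to); b <- pmax(e$from, e$to)
  u <- unique(tibble::tibble(a = a, b = b))
  u[order(u$a, u$b), ]
}

# undirected-support degree of every node (0-based result vector index = id+1)
support_degrees <- function(net) {
  u <- undirected_support(net)
  tabulate(c(u$a, u$b) + 1L, nbins = net$n_nodes)
}
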