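#' Build the modified graph for the Hill method
#'
#' Implements the network modification at the heart of the Hill method:
#' every edge entering the final set is redirected to the initial node (the
#' walker instantly restarts), the final nodes and their outgoing edges are
#' removed, and the redirected edges are recorded so the one-way stationary
#' flux can later be assembled from the *original* into-final rates. Edges
#' between two final nodes vanish (walkers are absorbed at first contact).
#'
#' @param rates A `rate_net` from [to_rates()].
#' @param initial Initial node id (must not be final).
#' @param finals Final node ids; at most `n_nodes - 2` of them.
#' @return A `modified_graph`: surviving `nodes`, `edges` tibble
#'   `(from, to, w)` in original ids, and `redirected` tibble
#'   `(src, orig_target, w)`.
#' @export
build_modified_graph <- function(rates, initial, finals) {
  finals <- unique(as.integer(finals))
  initial <- as.integer(initial)
  if (initial %in% finals) {
    stop("the final state must be different from the initial state for the Hill method")
  }
  if (length(finals) > rates$n_nodes - 2L) {
    stop(sprintf("the number of final states cannot exceed N-2 = %d", rates$n_nodes - 2L))
  }
  e <- rates$edges
  keep <- !(e$from %in% finals)
  e <- e[keep, , drop = FALSE]
  into_final <- e$to %in% finals
  redirected <- tibble::tibble(src = e$from[into_final],
                               orig_target = e$to[into_final],
                               w = e$w[into_final])
  e$to[into_final] <- initial
  structure(list(
    nodes = setdiff(0:(rates$n_nodes - 1L), finals),
    edges = e,
    redirected = redirected,
    initial = initial,
    finals = finals,
    n_orig = rates$n_nodes), class = "modified_graph")
}

# undirected support pairs with summed directional rates, lexicographic order
support_pairs <- function(edges) {
  e <- edges[edges$from != edges$to & edges$w > 0, , drop = FALSE]
  if (nrow(e) == 0) {
    return(tibble::tibble(a = integer(), b = integer(), w_ab = double(), w_ba = double()))
  }
  a <- pmin(e$from, e$to); b <- pmax(e$from, e$to)
  fwd <- e$from == a
  key <- paste(a, b)
  sp <- tibble::tibble(a = a, b = b, key = key)
  u <- sp[!duplicated(key), c("a", "b", "key")]
  u$w_ab <- vapply(u$key, function(k) sum(e$w[key == k & fwd]), 0)
  u$w_ba <- vapply(u$key, function(k) sum(e$w[key == k & !fwd]), 0)
  u <- u[order(u$a, u$b), c("a", "b", "w_ab", "w_ba")]
  u
}

# union-find check: does this pair subset form a spanning tree over `nodes`?
is_spanning_tree <- function(pa, pb, nodes) {
  parent <- seq_along(nodes)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  for (i in seq_along(pa)) {
    ra <- find(match(pa[i], nodes)); rb <- find(match(pb[i], nodes))
    if (ra == rb) return(FALSE)
    parent[ra] <- rb
  }
  length(pa) == length(nodes) - 1L
}

#' Enumerate the maximal (spanning) trees of a modified graph
#'
#' Yields every spanning tree of the undirected support as a set of edge
#' indices, generated as lexicographically ordered subsets of the edge list.
#' Self-loops never participate. When the number of candidate subsets
#' exceeds `budget` the enumeration refuses with a combinatorial-blow-up
#' error: for such knotted networks the Monte Carlo route is the practical
#' choice.
#'
#' @param graph A `modified_graph` (or `rate_net`).
#' @param budget Maximum number of candidate edge subsets (default `1e7`).
#' @return List of integer vectors (indices into the support edge list,
#'   which is attached as attribute `support`).
#' @export
enumerate_maximal_trees <- function(graph, budget = 1e7) {
  nodes <- if (inherits(graph, "modified_graph")) graph$nodes else
    0:(graph$n_nodes - 1L)
  sp <- support_pairs(graph$edges)
  m <- length(nodes)
  k <- m - 1L
  E <- nrow(sp)
  if (k > E) return(structure(list(), support = sp))
  if (k < 0) return(structure(list(), support = sp))
  if (choose(E, k) > budget) {
    stop(sprintf(
      "combinatorial blow-up: %g candidate edge subsets exceed the enumeration budget (%g); use the Monte Carlo method",
      choose(E, k), budget))
  }
  if (k == 0) {
    return(structure(list(integer(0)), support = sp))
  }
  subsets <- utils::combn(E, k, simplify = FALSE)
  trees <- Filter(function(s) is_spanning_tree(sp$a[s], sp$b[s], nodes), subsets)
  structure(trees, support = sp)
}

# Product-with-zeros bookkeeping: value = prod of nonzero factors, z = #zeros
pz_mul <- function(p, z, f) if (f == 0) c(p, z + 1) else c(p * f, z)
pz_div <- function(p, z, f) if (f == 0) c(p, z - 1) else c(p / f, z)
pz_value <- function(pz) if (pz[2] > 0) 0 else pz[1]

# For one spanning tree, the directed-tree weight W_l for every node l:
# product over tree edges of the rate oriented toward l. Computed by rooting
# at the first node and re-rooting along the tree (O(m) per tree).
tree_weights_all_roots <- function(tree_idx, sp, nodes) {
  m <- length(nodes)
  if (m == 1) return(stats::setNames(1, nodes))
  adj <- vector("list", m)
  for (ei in tree_idx) {
    ia <- match(sp$a[ei], nodes); ib <- match(sp$b[ei], nodes)
    # rate toward a is w_ba (edge b->a), toward b is w_ab
    adj[[ia]] <- rbind(adj[[ia]], c(ib, sp$w_ba[ei], sp$w_ab[ei]))
    adj[[ib]] <- rbind(adj[[ib]], c(ia, sp$w_ab[ei], sp$w_ba[ei]))
  }
  # BFS from root 1; for each node, record parent and the toward/away rates
  parent <- rep(NA_integer_, m)
  w_to_parent <- rep(NA_real_, m)   # rate child -> parent (toward root)
  w_from_parent <- rep(NA_real_, m) # rate parent -> child
  order_bfs <- integer(m)
  parent[1] <- 0L
  queue <- 1L; qi <- 1L; filled <- 1L
  order_bfs[1] <- 1L
  while (qi <= filled) {
    u <- queue[qi]; qi <- qi + 1L
    nb <- adj[[u]]
    if (!is.null(nb)) for (r in seq_len(nrow(nb))) {
      v <- nb[r, 1]
      if (is.na(parent[v])) {
        parent[v] <- u
        # nb row at u: (v, toward u from v?, ...) -- row stored at u lists
        # neighbour v with col2 = rate v->u? No: at node ia we stored
        # c(ib, w_ba, w_ab): rate toward a (i.e. toward ia) is w_ba = b->a.
        # So col2 = rate from neighbour v into u; col3 = rate u into v.
        w_to_parent[v] <- nb[r, 2]
        w_from_parent[v] <- nb[r, 3]
        filled <- filled + 1L
        queue <- c(queue, v)
        order_bfs[filled] <- v
      }
    }
  }
  # weight with root = node 1: product over non-root nodes of w_to_parent
  pz <- c(1, 0)
  for (v in order_bfs[-1]) pz <- pz_mul(pz[1], pz[2], w_to_parent[v])
  W <- rep(0, m)
  Wpz <- vector("list", m)
  Wpz[[1]] <- pz
  # re-root down the BFS order: moving root from parent u to child v flips
  # the edge {u,v}: divide by w(v->u), multiply by w(u->v)
  for (v in order_bfs[-1]) {
    u <- parent[v]
    pz_u <- Wpz[[u]]
    pz_v <- pz_div(pz_u[1], pz_u[2], w_to_parent[v])
    pz_v <- pz_mul(pz_v[1], pz_v[2], w_from_parent[v])
    Wpz[[v]] <- pz_v
  }
  for (i in seq_len(m)) W[i] <- pz_value(Wpz[[i]])
  stats::setNames(W, nodes)
}

#' Stationary occupation probabilities by maximal-tree summation
#'
#' Sums, for every node `l`, the weights `W_l(T)` of all spanning trees `T`
#' directed toward `l` (each weight the product of rates along the tree,
#' oriented toward `l`), and normalizes: `p_l = W_l / sum_n W_n`.
#'
#' @param graph A `modified_graph` or `rate_net`.
#' @param budget Enumeration budget, see [enumerate_maximal_trees()].
#' @return Tibble `(node, p_st)` over the graph's nodes.
#' @export
hill_stationary <- function(graph, budget = 1e7) {
  nodes <- if (inherits(graph, "modified_graph")) graph$nodes else
    0:(graph$n_nodes - 1L)
  trees <- enumerate_maximal_trees(graph, budget = budget)
  sp <- attr(trees, "support")
  if (length(trees) == 0) stop("graph has no spanning tree (disconnected support)")
  W <- rep(0, length(nodes))
  for (tr in trees) {
    W <- W + tree_weights_all_roots(tr, sp, nodes)
  }
  tot <- sum(W)
  if (tot == 0) stop("all directed-tree weights vanish; no positive-rate spanning structure")
  tibble::tibble(node = nodes, p_st = as.numeric(W / tot))
}

#' MFPT by the combinatorial Hill method
#'
#' Converts the network to rates, builds the modified graph in which
#' transitions into the final set restart at the initial node, computes the
#' stationary occupation probabilities there by maximal-tree enumeration,
#' assembles the one-way stationary flux `J = sum w_into_final * p_st(src)`
#' over the redirected edges, and returns `1/J`. Returns `Inf` (with
#' attribute `accessible`) when the finals are not almost-surely reached.
#'
#' @inheritParams mfpt_linear
#' @param budget Enumeration budget, see [enumerate_maximal_trees()].
#' @return MFPT (double) with attribute `accessible`.
#' @export
mfpt_hill <- function(net, initial, finals, budget = 1e7) {
  finals <- unique(as.integer(finals))
  info <- absorption_info(net, initial, finals)
  if (!info$certain) {
    return(structure(Inf, accessible = info$accessible))
  }
  rates <- to_rates(net)
  mg <- build_modified_graph(rates, initial, finals)
  # restrict to the weakly connected component holding the initial node;
  # other components never carry stationary mass of the restarted walk
  g <- igraph::graph_from_data_frame(
    data.frame(from = match(mg$edges$from, mg$nodes),
               to = match(mg$edges$to, mg$nodes)),
    directed = FALSE,
    vertices = data.frame(name = seq_along(mg$nodes)))
  comp <- igraph::components(g)
  keep_local <- comp$membership == comp$membership[match(mg$initial, mg$nodes)]
  keep_nodes <- mg$nodes[keep_local]
  if (!all(keep_local)) {
    mg$edges <- mg$edges[mg$edges$from %in% keep_nodes, , drop = FALSE]
    mg$redirected <- mg$redirected[mg$redirected$src %in% keep_nodes, , drop = FALSE]
    mg$nodes <- keep_nodes
  }
  pst <- hill_stationary(mg, budget = budget)
  J <- sum(mg$redirected$w * pst$p_st[match(mg$redirected$src, pst$node)])
  if (J <= 0) return(structure(Inf, accessible = info$accessible))
  structure(1 / J, accessible = TRUE)
}
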