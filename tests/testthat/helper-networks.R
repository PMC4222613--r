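# Fixture builders used across the suite. Everything is generated in code;
# seeds are fixed by the calling tests.

# the 4-node square with u = 1/2, tau = 1 (basic-format reference network)
square_net <- function() {
  parse_network(c("NODE 0 1 3", "NODE 1 0 2", "NODE 2 1 3", "NODE 3 0 2"),
                "basic")$network
}

# random connected network with N <= 8 nodes: random tree plus optional
# chords, random small-integer rational probabilities, random decimal local
# times, optional waiting self-loops
random_small_net <- function(n = sample(3:8, 1), chords = sample(0:2, 1),
                             self_loops = TRUE) {
  net <- generate_network("random_tree", n = n, prob_mode = "random_rational",
                          time_mode = "random",
                          self_loop_prob = if (self_loops) 0.4 else 0)
  sup <- tidy(net)
  for (i in seq_len(chords)) {
    cand <- sort(sample.int(n, 2) - 1L)
    present <- any((sup$from == cand[1] & sup$to == cand[2]))
    if (!present && cand[1] != cand[2]) {
      # splice a new two-way connection, reweighting each endpoint
      e <- net$edges
      for (side in 1:2) {
        l <- cand[side]; m <- cand[3 - side]
        idx <- which(e$from == l)
        wts <- c(e$p_num[idx], 1)
        tot <- sum(wts)
        e$p_num[idx] <- e$p_num[idx]; e$p_den[idx] <- tot
        e$p[idx] <- e$p_num[idx] / tot
        e <- dplyr::bind_rows(e, tibble::tibble(
          from = l, to = m, p = 1 / tot, tau = sample(1:50, 1) / 10,
          p_num = 1, p_den = tot, tau_num = NA_real_, tau_den = NA_real_))
      }
      net <- stoch_net(net$n_nodes, e)
      sup <- tidy(net)
    }
  }
  net
}

# brute-force shortest path by exhaustive simple-path enumeration
brute_shortest <- function(graph, source, target) {
  n <- attr(graph, "n_nodes")
  best <- list(total = Inf, path = integer(0))
  rec <- function(path, total) {
    last <- path[length(path)]
    if (last == target) {
      if (total < best$total ||
          (total == best$total && paste(path, collapse = ",") <
           paste(best$path, collapse = ","))) {
        best <<- list(total = total, path = path)
      }
      return()
    }
    nxt <- graph[graph$from == last & !(graph$to %in% path), , drop = FALSE]
    for (i in seq_len(nrow(nxt))) rec(c(path, nxt$to[i]), total + nxt$weight[i])
  }
  rec(source, 0)
  best
}

# matrix-tree count of spanning trees of the undirected simple support
matrix_tree_count <- function(net_or_rates) {
  edges <- if (inherits(net_or_rates, "stoch_net")) {
    u <- mfptnet:::undirected_support(net_or_rates)
    n <- net_or_rates$n_nodes
    u
  } else {
    e <- net_or_rates$edges
    e <- e[e$from != e$to, ]
    u <- unique(tibble::tibble(a = pmin(e$from, e$to), b = pmax(e$from, e$to)))
    n <- net_or_rates$n_nodes
    u
  }
  n <- if (inherits(net_or_rates, "stoch_net")) net_or_rates$n_nodes else
    net_or_rates$n_nodes
  A <- matrix(0, n, n)
  for (i in seq_len(nrow(edges))) {
    A[edges$a[i] + 1, edges$b[i] + 1] <- 1
    A[edges$b[i] + 1, edges$a[i] + 1] <- 1
  }
  L <- diag(rowSums(A)) - A
  round(det(L[-1, -1, drop = FALSE]))
}
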