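#' Is any final state reachable from the initial state?
#'
#' True iff a directed path of positive-probability edges connects
#' `initial` to some member of `finals`. When `initial` is itself final the
#' walk must still take at least one step, so reachability means returning:
#' a self-loop or any path back counts.
#'
#' @inheritParams mfpt_linear
#' @return Logical.
#' @export
reachable <- function(net, initial, finals) {
  finals <- unique(as.integer(finals))
  e <- net$edges[net$edges$p > 0, , drop = FALSE]
  if (nrow(e) == 0) return(FALSE)
  # first step away from the initial node, then ordinary reachability
  first <- unique(e$to[e$from == initial])
  if (length(first) == 0) return(FALSE)
  if (any(first %in% finals)) return(TRUE)
  g <- as_igraph(net)
  for (s in first) {
    r <- as.integer(igraph::subcomponent(g, s + 1L, mode = "out")) - 1L
    if (any(r %in% finals)) return(TRUE)
  }
  FALSE
}

# flattened edge arrays for the C++ stepper, in file order per node
flatten_edges <- function(net) {
  e <- net$edges
  ord <- order(e$from)  # stable: preserves file order within each node
  e <- e[ord, , drop = FALSE]
  start <- integer(net$n_nodes + 1L)
  cnt <- tabulate(e$from + 1L, nbins = net$n_nodes)
  start[1] <- 0L
  for (i in seq_len(net$n_nodes)) start[i + 1L] <- start[i] + cnt[i]
  cump <- numeric(nrow(e))
  for (l in unique(e$from)) {
    idx <- which(e$from == l)
    cump[idx] <- cumsum(e$p[idx]) / sum(e$p[idx])
  }
  list(start = start, to = e$to, cump = cump, tau = e$tau)
}

#' Simulate one random walker (reference implementation)
#'
#' Pure-R per-walker walk used as the behavioural contract for the batch
#' C++ stepper: start at `initial` with time zero; each step draws one
#' uniform number, picks the edge whose cumulative-probability interval
#' contains it (a draw on a boundary selects the latter interval), adds the
#' edge's local time (self-loops add waiting time), moves, and stops on
#' first arrival in `finals` — taking at least one step when the walk
#' starts on a final node.
#'
#' @inheritParams mfpt_linear
#' @param max_steps Guard against astronomically slow walks.
#' @return The walker's first-passage time.
#' @export
single_walk <- function(net, initial, finals, max_steps = 1e9) {
  fl <- flatten_edges(net)
  pos <- initial; t <- 0; steps <- 0
  repeat {
    lo <- fl$start[pos + 1L] + 1L; hi <- fl$start[pos + 2L]
    if (hi < lo) stop(sprintf("walker reached absorbing non-final node %d", pos))
    u <- stats::runif(1)
    e <- lo
    while (e < hi && u >= fl$cump[e]) e <- e + 1L
    t <- t + fl$tau[e]
    pos <- fl$to[e]
    steps <- steps + 1
    if (steps > max_steps) stop("walker exceeded max_steps")
    if (pos %in% finals) return(t)
  }
}

#' MFPT by Monte Carlo random-walk simulation
#'
#' Runs `simulations` independent simulations of `walkers` walkers each.
#' The reported value is the mean of per-simulation means; with more than
#' one simulation the standard deviation of those means is reported as the
#' error estimate. Unreachable finals short-circuit to the
#' not-accessible sentinel without simulating.
#'
#' @inheritParams mfpt_linear
#' @param walkers Walkers per simulation (WALK).
#' @param simulations Number of simulations (SIMU).
#' @param seed Integer seed for R's Mersenne-Twister RNG; `NULL` continues
#'   the current RNG stream.
#' @param max_steps Per-walker step guard; exceeding it is an error, not a
#'   truncation.
#' @return One-row tibble from [mfpt_result()] with a `sims` list-column of
#'   per-simulation means and `se`, the walker-level standard error of the
#'   grand mean.
#' @export
mfpt_mc <- function(net, initial, finals, walkers = 10000, simulations = 1,
                    seed = NULL, max_steps = 1e9) {
  stopifnot(walkers >= 1, simulations >= 1, length(finals) >= 1)
  finals <- unique(as.integer(finals))
  if (!reachable(net, initial, finals)) {
    return(mfpt_result(initial, finals, Inf, method = "montecarlo"))
  }
  if (!is.null(seed)) set.seed(seed)
  fl <- flatten_edges(net)
  is_final <- rep(FALSE, net$n_nodes)
  is_final[finals + 1L] <- TRUE
  batches <- lapply(seq_len(simulations), function(s) {
    mc_walk_batch(net$n_nodes, as.integer(fl$start), as.integer(fl$to),
                  fl$cump, fl$tau, as.integer(initial), is_final,
                  as.numeric(walkers), as.numeric(max_steps))
  })
  sims <- vapply(batches, `[[`, 0, "mean")
  ntot <- walkers * simulations
  tot <- sum(vapply(batches, `[[`, 0, "sum"))
  totsq <- sum(vapply(batches, `[[`, 0, "sumsq"))
  var_w <- max(0, (totsq - tot^2 / ntot) / max(1, ntot - 1))
  res <- mfpt_result(initial, finals,
                     value = mean(sims),
                     std = if (simulations > 1) stats::sd(sims) else NA_real_,
                     method = "montecarlo", sims = sims)
  res$se <- sqrt(var_w / ntot)  # walker-level standard error of the mean
  res
}

#' Compute an MFPT by either method
#'
#' Thin dispatcher over [mfpt_hill()] and [mfpt_mc()], returning a uniform
#' one-row result tibble.
#'
#' @inheritParams mfpt_mc
#' @param method `"hill"` or `"montecarlo"`.
#' @param ... Passed on to the method.
#' @return One-row tibble from [mfpt_result()].
#' @export
mfpt <- function(net, initial, finals, method = c("hill", "montecarlo"), ...) {
  method <- match.arg(method)
  if (method == "hill") {
    v <- mfpt_hill(net, initial, finals, ...)
    r <- mfpt_result(initial, finals, as.numeric(v), method = "hill")
    r$accessible <- attr(v, "accessible") & is.finite(v)
    r
  } else {
    mfpt_mc(net, initial, finals, ...)
  }
}
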