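#' Classify a docked pose by the CAPRI criteria
#'
#' Applies the standard threshold rules on the fraction of native contacts
#' (`fnat`), ligand RMSD (`lrmsd`, Angstrom) and interface RMSD (`irmsd`,
#' Angstrom), evaluated high, then medium, then acceptable, then incorrect:
#' * high: `fnat >= 0.5` and (`lrmsd <= 1` or `irmsd <= 1`)
#' * medium: (`fnat >= 0.5` and `lrmsd > 1` and `irmsd > 1`) or
#'   (`0.3 <= fnat < 0.5` and (`lrmsd <= 5` or `irmsd <= 2`))
#' * acceptable: (`fnat >= 0.3` and `lrmsd > 5` and `irmsd > 2`) or
#'   (`0.1 <= fnat < 0.3` and (`lrmsd <= 10` or `irmsd <= 4`))
#' * incorrect: `fnat < 0.1` or (`lrmsd > 10` and `irmsd > 4`)
#'
#' @param fnat,lrmsd,irmsd Numeric vectors (recycled to a common length).
#' @return Character vector in
#'   `c("high", "medium", "acceptable", "incorrect")`.
#' @examples
#' capri_classify(0.67, 3.14, 1.41)  # "medium"
#' @export
capri_classify <- function(fnat, lrmsd, irmsd) {
  n <- max(length(fnat), length(lrmsd), length(irmsd))
  fnat <- rep_len(fnat, n); lrmsd <- rep_len(lrmsd, n); irmsd <- rep_len(irmsd, n)
  out <- character(n)
  high <- fnat >= 0.5 & (lrmsd <= 1 | irmsd <= 1)
  medium <- (fnat >= 0.5 & lrmsd > 1 & irmsd > 1) |
    (fnat >= 0.3 & fnat < 0.5 & (lrmsd <= 5 | irmsd <= 2))
  acceptable <- (fnat >= 0.3 & lrmsd > 5 & irmsd > 2) |
    (fnat >= 0.1 & fnat < 0.3 & (lrmsd <= 10 | irmsd <= 4))
  out[] <- "incorrect"
  out[acceptable] <- "acceptable"
  out[medium & !high] <- "medium"
  out[high] <- "high"
  out
}

#' Build a funnel transition network from state energies
#'
#' Converts a symmetric conformational adjacency plus per-state metadata
#' into a stochastic network: for a move from state `l` to neighbour `m`
#' the raw exit score is 1 when the move is downhill in energy
#' (`E_l > E_m`) and `exp(-(E_m - E_l))` otherwise; moves involving a state
#' whose ligand RMSD exceeds `lrmsd_cutoff` get score zero (by default the
#' rule applies to moves *into* such states; `cutoff_direction = "out"`
#' zeroes the exits instead). Scores are normalized per node, transitions
#' below `prune` are removed, and the node is re-normalized. All local
#' times are 1 (global time scale). States left without exits become
#' absorbing dead ends, recorded in the `dead_ends` attribute.
#'
#' @param states Data frame with columns `id`, `energy`, `lrmsd` (extra
#'   columns such as `irmsd`, `fnat` are carried along untouched).
#' @param adjacency Data frame of undirected neighbour pairs
#'   (columns `from`, `to`, state ids).
#' @param lrmsd_cutoff Ligand-RMSD exclusion threshold (Angstrom,
#'   default 6).
#' @param prune Minimum post-normalization transition probability
#'   (default 1e-6).
#' @param cutoff_direction `"into"` (default) or `"out"`.
#' @return A [stoch_net()] with attribute `dead_ends`.
#' @export
assign_transition_probabilities <- function(states, adjacency,
                                            lrmsd_cutoff = 6, prune = 1e-6,
                                            cutoff_direction = c("into", "out")) {
  cutoff_direction <- match.arg(cutoff_direction)
  states <- tibble::as_tibble(states)
  stopifnot(all(c("id", "energy", "lrmsd") %in% names(states)))
  ids <- sort(unique(states$id))
  stopifnot(identical(as.integer(ids), seq_along(ids) - 1L))
  energy <- states$energy[match(ids, states$id)]
  lrmsd <- states$lrmsd[match(ids, states$id)]
  adj <- tibble::tibble(from = c(adjacency$from, adjacency$to),
                        to = c(adjacency$to, adjacency$from))
  adj <- unique(adj[adj$from != adj$to, ])
  rows <- list()
  dead <- integer(0)
  for (l in ids) {
    nb <- adj$to[adj$from == l]
    if (length(nb) == 0) { dead <- c(dead, l); next }
    dE <- energy[nb + 1L] - energy[l + 1L]
    raw <- ifelse(energy[l + 1L] > energy[nb + 1L], 1, exp(-dE))
    if (cutoff_direction == "into") {
      raw[lrmsd[nb + 1L] > lrmsd_cutoff] <- 0
    } else if (lrmsd[l + 1L] > lrmsd_cutoff) {
      raw[] <- 0
    }
    if (sum(raw) == 0) { dead <- c(dead, l); next }
    p <- raw / sum(raw)
    keep <- p >= prune
    if (!any(keep)) { dead <- c(dead, l); next }
    p <- p[keep] / sum(p[keep])
    rows[[length(rows) + 1]] <- tibble::tibble(from = l, to = nb[keep],
                                               p = p, tau = 1)
  }
  net <- stoch_net(length(ids), dplyr::bind_rows(rows))
  attr(net, "dead_ends") <- dead
  attr(net, "states") <- states
  net
}

#' Build an MFPT-weighted directed graph
#'
#' Edge `(i, j)` with weight `MFPT(i -> j)` exists iff a finite MFPT was
#' provided; missing (`NA`) or infinite entries yield no edge.
#'
#' @param mfpt_matrix Square numeric matrix indexed by state id (row =
#'   initial, column = final); `NA`/`Inf` marks a pair that was not
#'   computed or not accessible.
#' @return Tibble `(from, to, weight)` of class `mfpt_graph`, with
#'   `n_nodes` attribute.
#' @export
mfpt_weighted_graph <- function(mfpt_matrix) {
  m <- as.matrix(mfpt_matrix)
  stopifnot(nrow(m) == ncol(m))
  if (any(m < 0, na.rm = TRUE)) stop("MFPT weights must be positive")
  idx <- which(is.finite(m) & row(m) != col(m), arr.ind = TRUE)
  g <- tibble::tibble(from = idx[, 1] - 1L, to = idx[, 2] - 1L,
                      weight = m[idx])
  if (any(g$weight <= 0)) stop("MFPT weights must be positive")
  g <- g[order(g$from, g$to), ]
  structure(g, n_nodes = nrow(m), class = c("mfpt_graph", class(g)))
}

#' Favourable (shortest) path on an MFPT-weighted graph
#'
#' Dijkstra shortest path in units of summed mean first-passage times.
#' Among equally short paths the lexicographically smallest node sequence
#' is returned, so results are deterministic.
#'
#' @param graph An [mfpt_weighted_graph()] result (or any tibble with
#'   `from`, `to`, `weight` and an `n_nodes` attribute).
#' @param source,target State ids.
#' @return List with `path` (integer vector of ids), `total` (sum of edge
#'   weights) and `accessible`; an unreachable target gives
#'   `accessible = FALSE`, `total = Inf`, empty path.
#' @export
shortest_path <- function(graph, source, target) {
  n <- attr(graph, "n_nodes")
  ig <- igraph::graph_from_data_frame(
    data.frame(from = graph$from + 1L, to = graph$to + 1L),
    directed = TRUE, vertices = data.frame(name = seq_len(n)))
  sp <- suppressWarnings(igraph::all_shortest_paths(
    ig, from = source + 1L, to = target + 1L, mode = "out",
    weights = graph$weight))
  paths <- sp$vpaths %||% sp$res
  if (length(paths) == 0) {
    return(list(path = integer(0), total = Inf, accessible = FALSE))
  }
  seqs <- lapply(paths, function(p) as.integer(p) - 1L)
  ord <- do.call(order, as.data.frame(t(vapply(
    seqs, function(s) c(s, rep(-1L, max(lengths(seqs)) - length(s))),
    integer(max(lengths(seqs)))))))
  path <- seqs[[ord[1]]]
  total <- 0
  for (i in seq_len(length(path) - 1)) {
    w <- graph$weight[graph$from == path[i] & graph$to == path[i + 1]]
    total <- total + min(w)
  }
  list(path = path, total = total, accessible = TRUE)
}

#' Read / write an MFPT matrix as a whitespace-delimited table
#'
#' Square table of times; `missing_token` marks pairs that were not
#' computed or not accessible.
#'
#' @param path File path.
#' @param missing_token Token used for missing entries (default `"NA"`).
#' @return `read_mfpt_matrix`: a numeric matrix.
#' @export
read_mfpt_matrix <- function(path, missing_token = "NA") {
  m <- as.matrix(utils::read.table(path, na.strings = missing_token,
                                   header = FALSE))
  dimnames(m) <- NULL
  m
}

#' @rdname read_mfpt_matrix
#' @param m Numeric matrix to write.
#' @export
write_mfpt_matrix <- function(m, path, missing_token = "NA") {
  txt <- apply(m, 1, function(r) {
    paste(ifelse(is.finite(r), format(r, digits = 17), missing_token),
          collapse = " ")
  })
  writeLines(txt, path)
  invisible(path)
}
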