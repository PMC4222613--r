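#' Parse a probability or time token, keeping common fractions exact
#'
#' Tokens may be integers (`"1"`), decimals (`"0.25"`), or common fractions
#' (`"1/3"`). Fractions and integers are kept exact through their
#' numerator/denominator; decimals are retained at full double precision.
#'
#' @param token A single character token.
#' @return A list with `value` (double), `num`, `den` (doubles, `NA` for
#'   decimals).
#' @examples
#' parse_fraction("1/3")$value  # 0.3333...
#' parse_fraction("0.25")$value # 0.25
#' @export
parse_fraction <- function(token) {
  stopifnot(is.character(token), length(token) == 1)
  if (grepl("^[+-]?[0-9]+/[0-9]+$", token)) {
    parts <- strsplit(token, "/", fixed = TRUE)[[1]]
    num <- as.numeric(parts[1]); den <- as.numeric(parts[2])
    if (den == 0) stop(sprintf("malformed fraction token '%s': zero denominator", token))
    g <- gcd2(num, den)
    if (g > 0) { num <- num / g; den <- den / g }
    list(value = num / den, num = num, den = den)
  } else if (grepl("^[+-]?[0-9]+$", token)) {
    v <- as.numeric(token)
    list(value = v, num = v, den = 1)
  } else if (grepl("^[+-]?([0-9]+\\.[0-9]*|\\.[0-9]+)([eE][+-]?[0-9]+)?$", token) ||
             grepl("^[+-]?[0-9]+[eE][+-]?[0-9]+$", token)) {
    list(value = as.numeric(token), num = NA_real_, den = NA_real_)
  } else {
    stop(sprintf("malformed numeric token '%s'", token))
  }
}

empty_run_spec <- function() {
  list(walkers = NA_integer_, simulations = NA_integer_,
       queries = list(), info = character(0), input_format = NA_character_)
}

#' Parse a network description in the basic or advanced text format
#'
#' The basic format lists, per line, `NODE <id> <neighbour> ...`; each
#' neighbour occurrence becomes an edge of probability `1/k` (`k` tokens on
#' the line) and local time 1, so a repeated self id yields a waiting
#' probability of `multiplicity/k`. The advanced format lists triplets
#' `NODE <id> <neighbour> <probability> <time> ...`, with probabilities and
#' times given as decimals or common fractions; each line's probabilities
#' must sum to one. Node ids must appear in strictly increasing order,
#' starting at 0, without gaps. Keyword lines `WALK <n>`, `SIMU <n>`,
#' `MFPT <initial> <final> ...` (repeatable; several finals allowed) and
#' `INFO <free text>` populate the run spec. Blank lines and `#` comments
#' are ignored.
#'
#' @param text Character vector of lines, or a single string with newlines.
#' @param format `"basic"` or `"advanced"`.
#' @return A list with elements `network` ([stoch_net()]) and `run`
#'   (walkers, simulations, queries, info).
#' @seealso [read_network()], [write_network()]
#' @export
parse_network <- function(text, format = c("basic", "advanced")) {
  format <- match.arg(format)
  if (length(text) == 1 && grepl("\n", text)) {
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  }
  run <- empty_run_spec()
  run$input_format <- format
  rows <- list()
  seen_ids <- integer(0)
  for (li in seq_along(text)) {
    line <- sub("#.*$", "", text[li])
    tok <- strsplit(trimws(line), "[[:space:]]+")[[1]]
    tok <- tok[nzchar(tok)]
    if (length(tok) == 0) next
    kw <- toupper(tok[1])
    if (kw == "NODE") {
      if (length(tok) < 2) stop(sprintf("line %d: NODE without id", li))
      id <- suppressWarnings(as.integer(tok[2]))
      if (is.na(id)) stop(sprintf("line %d: bad node id '%s'", li, tok[2]))
      if (id %in% seen_ids) stop(sprintf("line %d: duplicate NODE line for id %d", li, id))
      if (id != length(seen_ids)) {
        stop(sprintf("line %d: node ids must increase from 0 without gaps (got %d, expected %d)",
                     li, id, length(seen_ids)))
      }
      seen_ids <- c(seen_ids, id)
      body <- tok[-(1:2)]
      if (format == "basic") {
        if (length(body) > 0) {
          k <- length(body)
          nb <- suppressWarnings(as.integer(body))
          if (any(is.na(nb))) stop(sprintf("line %d: bad neighbour token", li))
          rows[[length(rows) + 1]] <- tibble::tibble(
            from = id, to = nb, p = 1 / k, tau = 1,
            p_num = 1, p_den = k, tau_num = 1, tau_den = 1)
        }
      } else {
        if (length(body) %% 3 != 0) {
          stop(sprintf("line %d: advanced NODE body must be (neighbour prob time) triplets", li))
        }
        if (length(body) > 0) {
          m <- matrix(body, ncol = 3, byrow = TRUE)
          nb <- suppressWarnings(as.integer(m[, 1]))
          if (any(is.na(nb))) stop(sprintf("line %d: bad neighbour token", li))
          pr <- lapply(m[, 2], function(t) {
            tryCatch(parse_fraction(t), error = function(e)
              stop(sprintf("line %d: %s", li, conditionMessage(e)), call. = FALSE))
          })
          tm <- lapply(m[, 3], function(t) {
            tryCatch(parse_fraction(t), error = function(e)
              stop(sprintf("line %d: %s", li, conditionMessage(e)), call. = FALSE))
          })
          pv <- vapply(pr, `[[`, 0, "value")
          pn <- vapply(pr, `[[`, 0, "num"); pd <- vapply(pr, `[[`, 0, "den")
          if (all(!is.na(pn))) {
            s <- frac_sum(pn, pd)
            if (s[1] != s[2]) {
              stop(sprintf("node %d: probabilities sum to %g/%g, not exactly 1", id, s[1], s[2]))
            }
          } else if (abs(sum(pv) - 1) > 1e-9) {
            stop(sprintf("node %d: probabilities sum to %.12g, not 1", id, sum(pv)))
          }
          rows[[length(rows) + 1]] <- tibble::tibble(
            from = id, to = nb, p = pv, tau = vapply(tm, `[[`, 0, "value"),
            p_num = pn, p_den = pd,
            tau_num = vapply(tm, `[[`, 0, "num"),
            tau_den = vapply(tm, `[[`, 0, "den"))
        }
      }
    } else if (kw == "WALK") {
      run$walkers <- as.integer(tok[2])
    } else if (kw == "SIMU") {
      run$simulations <- as.integer(tok[2])
    } else if (kw == "MFPT") {
      ids <- suppressWarnings(as.integer(tok[-1]))
      if (length(ids) < 2 || any(is.na(ids))) {
        stop(sprintf("line %d: MFPT needs an initial and at least one final id", li))
      }
      run$queries[[length(run$queries) + 1]] <-
        list(initial = ids[1], finals = ids[-1])
    } else if (kw == "INFO") {
      run$info <- c(run$info, trimws(sub("^[[:space:]]*INFO[[:space:]]?", "", line,
                                         ignore.case = TRUE)))
    } else {
      stop(sprintf("line %d: unknown keyword '%s'", li, tok[1]))
    }
  }
  if (length(seen_ids) == 0) stop("input contains no NODE lines")
  edges <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(from = integer(), to = integer(), p = double(), tau = double(),
                   p_num = double(), p_den = double(),
                   tau_num = double(), tau_den = double())
  net <- stoch_net(length(seen_ids), edges)
  list(network = net, run = run)
}

#' Read a network file
#'
#' @param path Path to a text file in the basic or advanced format.
#' @inheritParams parse_network
#' @return As [parse_network()].
#' @export
read_network <- function(path, format = c("basic", "advanced")) {
  parse_network(readLines(path, warn = FALSE), format)
}

fmt_token <- function(value, num, den) {
  if (!is.na(num)) {
    if (den == 1) sprintf("%.0f", num) else sprintf("%.0f/%.0f", num, den)
  } else {
    format(value, digits = 17)
  }
}

#' Write a network in the basic or advanced text format
#'
#' Writing then re-parsing reproduces the network exactly: common fractions
#' are emitted as `a/b` tokens and decimals at full double precision. The
#' basic format can only represent uniform `1/k` probabilities with unit
#' times; other networks must use the advanced format.
#'
#' @param net A [stoch_net()].
#' @param run Optional run spec (as returned by [parse_network()]); its
#'   WALK/SIMU/MFPT/INFO lines are appended.
#' @param format `"basic"` or `"advanced"`.
#' @param path Optional output file; when `NULL` the lines are returned.
#' @return Character vector of lines (invisibly when `path` is given).
#' @export
write_network <- function(net, run = NULL, format = c("basic", "advanced"),
                          path = NULL) {
  format <- match.arg(format)
  e <- net$edges
  lines <- character(0)
  for (id in 0:(net$n_nodes - 1L)) {
    idx <- which(e$from == id)
    if (format == "basic") {
      if (length(idx) > 0) {
        k <- length(idx)
        ok <- all(!is.na(e$p_num[idx]) & e$p_num[idx] == 1 & e$p_den[idx] == k &
                    e$tau[idx] == 1)
        if (!ok) stop(sprintf(
          "node %d not representable in basic format (needs uniform 1/%d probabilities, unit times); use format = 'advanced'",
          id, k))
        lines <- c(lines, paste(c("NODE", id, e$to[idx]), collapse = " "))
      } else {
        lines <- c(lines, paste("NODE", id))
      }
    } else {
      trip <- character(0)
      for (j in idx) {
        trip <- c(trip, as.character(e$to[j]),
                  fmt_token(e$p[j], e$p_num[j], e$p_den[j]),
                  fmt_token(e$tau[j], e$tau_num[j], e$tau_den[j]))
      }
      lines <- c(lines, paste(c("NODE", id, trip), collapse = " "))
    }
  }
  if (!is.null(run)) {
    if (!is.na(run$walkers)) lines <- c(lines, paste("WALK", run$walkers))
    if (!is.na(run$simulations)) lines <- c(lines, paste("SIMU", run$simulations))
    for (q in run$queries) {
      lines <- c(lines, paste(c("MFPT", q$initial, q$finals), collapse = " "))
    }
    for (inf in run$info) lines <- c(lines, paste("INFO", inf))
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Assemble an MFPT result row
#'
#' @param initial,finals Query nodes.
#' @param value MFPT (time; `Inf` when the finals are not accessible).
#' @param std Standard deviation of per-simulation means (`NA` for single
#'   simulations or the Hill method).
#' @param method `"hill"` or `"montecarlo"`.
#' @param sims Optional numeric vector of per-simulation means.
#' @return One-row tibble with a `finals` list-column and an `accessible`
#'   flag.
#' @export
mfpt_result <- function(initial, finals, value, std = NA_real_,
                        method = NA_character_, sims = NULL) {
  tibble::tibble(
    initial = as.integer(initial),
    finals = list(as.integer(finals)),
    value = as.numeric(value),
    std = as.numeric(std),
    accessible = is.finite(value),
    method = method,
    sims = list(sims))
}

NOT_ACCESSIBLE_TEXT <- "Infinity (not accessible)"

#' Write MFPT results as plain text
#'
#' One record per query: initial node, final set, the MFPT (or the literal
#' sentinel `Infinity (not accessible)` for unreachable finals) and, when
#' present, the standard deviation over simulations. `INFO` comments are
#' copied verbatim.
#'
#' @param results Tibble of rows from [mfpt_result()] (possibly empty).
#' @param info Character vector of comment lines to copy into the output.
#' @param path Optional output file.
#' @return Character vector of lines (invisibly when `path` is given).
#' @export
write_results <- function(results, info = character(0), path = NULL) {
  lines <- "# initial -> finals : MFPT [std]"
  for (inf in info) lines <- c(lines, paste("INFO", inf))
  if (nrow(results) > 0) {
    for (i in seq_len(nrow(results))) {
      fin <- paste(results$finals[[i]], collapse = ",")
      val <- if (!results$accessible[i]) NOT_ACCESSIBLE_TEXT else
        format(results$value[i], digits = 10)
      ln <- sprintf("MFPT %d -> %s : %s", results$initial[i], fin, val)
      if (!is.na(results$std[i])) {
        ln <- paste0(ln, sprintf(" [std %s]", format(results$std[i], digits = 10)))
      }
      lines <- c(lines, ln)
    }
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
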