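#' Build a weighted movement network
#'
#' Receivers are nodes; each movement adds one unit of weight to the edge
#' from its origin to its destination (directed) or between the pair
#' (undirected). All receivers in `nodes` are kept as vertices even when
#' isolated, so node counts — and hence the triad-census denominator — stay
#' constant across windows.
#'
#' @param movements Movement table.
#' @param nodes Character vector of receiver ids forming the vertex set.
#'   Defaults to the receivers appearing in `movements`.
#' @param window Optional `c(start, end)` (POSIXct or coercible); only
#'   movements whose departure falls in `[start, end)` are used.
#' @param directed Build a directed network (default `TRUE`).
#' @param subject Optional transmitter id; restricts to that fish.
#' @return An `igraph` graph with integer `weight` edge attribute and
#'   graph attributes `window_start`, `window_end`, `subject`.
#' @export
build_network <- function(movements, nodes = NULL, window = NULL,
                          directed = TRUE, subject = NULL) {
  m <- movements
  if (!is.null(subject)) m <- m[m$transmitter_id %in% subject, , drop = FALSE]
  if (!is.null(window)) {
    w0 <- as.POSIXct(window[1], tz = "UTC")
    w1 <- as.POSIXct(window[2], tz = "UTC")
    m <- m[m$departure >= w0 & m$departure < w1, , drop = FALSE]
  }
  if (is.null(nodes)) {
    nodes <- sort(unique(c(movements$from_receiver, movements$to_receiver)))
  }
  if (any(m$from_receiver == m$to_receiver)) stop("self-movements present")
  g <- igraph::make_empty_graph(n = 0, directed = directed)
  g <- igraph::add_vertices(g, length(nodes), name = nodes)
  if (nrow(m) > 0) {
    key <- if (directed) {
      paste(m$from_receiver, m$to_receiver, sep = "\r")
    } else {
      paste(pmin(m$from_receiver, m$to_receiver),
            pmax(m$from_receiver, m$to_receiver), sep = "\r")
    }
    tab <- table(key)
    ends_chr <- strsplit(names(tab), "\r", fixed = TRUE)
    el <- do.call(rbind, ends_chr)
    g <- igraph::add_edges(g, t(cbind(match(el[, 1], nodes),
                                      match(el[, 2], nodes))),
                           weight = as.integer(tab))
  }
  g <- igraph::set_graph_attr(g, "subject",
                              if (is.null(subject)) "aggregate" else subject)
  if (!is.null(window)) {
    g <- igraph::set_graph_attr(g, "window_start", as.character(window[1]))
    g <- igraph::set_graph_attr(g, "window_end", as.character(window[2]))
  }
  g
}

#' Node strength of an undirected movement network
#'
#' The weighted connectivity of each receiver: the summed weights of its
#' incident edges, i.e. its cumulative incomings and outgoings. Totals over
#' all nodes equal twice the total edge weight.
#'
#' @param network Undirected `igraph` movement network with `weight` edges.
#' @return Named numeric vector of strengths.
#' @export
node_strength <- function(network) {
  if (igraph::is_directed(network)) {
    stop("node strength is defined on undirected movement networks")
  }
  if (igraph::ecount(network) == 0) {
    return(stats::setNames(rep(0, igraph::vcount(network)),
                           igraph::V(network)$name))
  }
  igraph::strength(network, weights = igraph::E(network)$weight)
}

#' Degree of an undirected movement network
#'
#' The unweighted connectivity of each receiver: its number of distinct
#' neighbours.
#'
#' @param network Undirected `igraph` movement network.
#' @return Named numeric vector of degrees.
#' @export
node_degree <- function(network) {
  if (igraph::is_directed(network)) {
    stop("degree is computed on undirected movement networks")
  }
  igraph::degree(network)
}

#' Weekly node-strength and degree series per fish
#'
#' For each subject and each consecutive 7-day window from `start`, builds
#' the subject's undirected movement network and sums node strength and
#' degree across all receivers (each undirected edge therefore contributes
#' twice, once per endpoint). Weeks without movements yield zero rows and
#' are kept: the zeros carry information for the zero-inflated degree
#' model. A trailing partial week is dropped.
#'
#' @param movements Movement table.
#' @param start Start instant of the first week (POSIXct or coercible;
#'   the reference design starts 2015-08-25).
#' @param n_weeks Number of 7-day windows.
#' @param subjects Transmitters to include (default: all in `movements`).
#' @param nodes Receiver vertex set (default: all receivers in
#'   `movements`).
#' @param tz Timezone used when coercing `start`.
#' @return A `data.frame` with `transmitter_id`, `week`, `week_start`,
#'   `strength`, `degree`.
#' @export
weekly_metrics <- function(movements, start, n_weeks,
                           subjects = NULL, nodes = NULL,
                           tz = "Europe/Stockholm") {
  if (n_weeks <= 0) stop("n_weeks must be positive")
  start <- as.POSIXct(start, tz = tz)
  if (is.null(subjects)) subjects <- sort(unique(movements$transmitter_id))
  if (is.null(nodes)) {
    nodes <- sort(unique(c(movements$from_receiver, movements$to_receiver)))
  }
  grid <- expand.grid(week = seq_len(n_weeks), transmitter_id = subjects,
                      stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)[, c(2, 1)]
  res <- mapply(function(subj, wk) {
    w0 <- start + (wk - 1) * 7 * 86400
    g <- build_network(movements, nodes = nodes,
                       window = c(w0, w0 + 7 * 86400),
                       directed = FALSE, subject = subj)
    c(strength = sum(node_strength(g)), degree = sum(node_degree(g)))
  }, grid$transmitter_id, grid$week)
  out <- cbind(grid, t(res))
  out$week_start <- as.Date(start + (out$week - 1) * 7 * 86400, tz = tz)
  rownames(out) <- NULL
  out[, c("transmitter_id", "week", "week_start", "strength", "degree")]
}

#' Aggregated seasonal movement networks
#'
#' Pools all retained fish and builds one directed weighted network per
#' season; the total edge weight of each network equals the number of
#' movements departing in that season.
#'
#' @param movements Movement table (all retained fish).
#' @param windows A [season_windows()] object.
#' @param nodes Receiver vertex set.
#' @param tz Day-boundary timezone.
#' @return Named list of directed `igraph` networks, one per season.
#' @export
aggregate_seasonal <- function(movements, windows = default_season_windows(),
                               nodes = NULL, tz = "Europe/Stockholm") {
  if (is.null(nodes)) {
    nodes <- sort(unique(c(movements$from_receiver, movements$to_receiver)))
  }
  season <- if (nrow(movements) > 0) {
    assign_season(movements$departure, windows, tz = tz)
  } else character(0)
  out <- lapply(seq_len(nrow(windows)), function(i) {
    build_network(movements[season == windows$label[i], , drop = FALSE],
                  nodes = nodes, directed = TRUE)
  })
  names(out) <- windows$label
  out
}
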