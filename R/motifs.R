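#' MAN labels of the 16 directed-triad isomorphism classes
#'
#' Davis--Leinhardt ordering: each label counts the Mutual, Asymmetric and
#' Null dyads of the triad, with D(own)/U(p)/C(yclic)/T(ransitive)
#' qualifiers where the dyad counts are ambiguous. Class 1 (003) is the
#' null triad with no edges; class 16 (300) the complete mutual triad.
#'
#' @return Character vector of length 16.
#' @export
triad_classes <- function() {
  c("003", "012", "102", "021D", "021U", "021C", "111D", "111U",
    "030T", "030C", "201", "120D", "120U", "120C", "210", "300")
}

#' Classify a directed triad into its isomorphism class
#'
#' Classifies the subgraph induced on three labelled nodes by the
#' mutual/asymmetric/null (MAN) dyad decision table, disambiguating the
#' 021, 111, 030 and 120 families by in/out-degree patterns. The result is
#' invariant under relabelling of the three nodes.
#'
#' @param adj A 3x3 binary adjacency matrix (`adj[i, j] = 1` when the
#'   ordered edge i -> j is present); the diagonal must be zero.
#' @return Integer class index in 1..16, named with its MAN code (see
#'   [triad_classes()]).
#' @export
classify_triad <- function(adj) {
  adj <- (as.matrix(adj) != 0) * 1L
  if (!all(dim(adj) == c(3, 3))) stop("adj must be 3x3")
  if (any(diag(adj) != 0)) stop("self-loops are not allowed")
  idx <- .classify_code(adj[1, 2], adj[2, 1], adj[1, 3], adj[3, 1],
                        adj[2, 3], adj[3, 2])
  stats::setNames(idx, triad_classes()[idx])
}

# Dyad decision table on the six ordered edges of a labelled triad.
# e12 = edge 1->2 etc. Returns the class index 1..16.
.classify_code <- function(e12, e21, e13, e31, e23, e32) {
  A <- matrix(c(0, e12, e13, e21, 0, e23, e31, e32, 0),
              nrow = 3, byrow = TRUE)
  pair_i <- c(1, 1, 2); pair_j <- c(2, 3, 3)
  fwd <- A[cbind(pair_i, pair_j)]
  bwd <- A[cbind(pair_j, pair_i)]
  m <- sum(fwd & bwd)          # mutual dyads
  a <- sum(xor(fwd, bwd))      # asymmetric dyads
  n <- 3L - m - a              # null dyads
  outd <- rowSums(A); ind <- colSums(A)
  if (m == 0 && a == 0) return(1L)                       # 003
  if (m == 0 && a == 1) return(2L)                       # 012
  if (m == 1 && a == 0 && n == 2) return(3L)             # 102
  if (m == 0 && a == 2) {
    if (any(outd == 2)) return(4L)                       # 021D out-star
    if (any(ind == 2)) return(5L)                        # 021U in-star
    return(6L)                                           # 021C path
  }
  if (m == 1 && a == 1) {
    # x = the node outside the mutual dyad; direction of its lone
    # asymmetric edge separates 111D (x points in) from 111U (x points out)
    mut <- which(fwd & bwd)
    x <- setdiff(1:3, c(pair_i[mut], pair_j[mut]))
    if (outd[x] == 1) return(7L)                         # 111D
    return(8L)                                           # 111U
  }
  if (m == 0 && a == 3) {
    if (all(outd == 1)) return(10L)                      # 030C cycle
    return(9L)                                           # 030T transitive
  }
  if (m == 2 && a == 0) return(11L)                      # 201
  if (m == 1 && a == 2) {
    mut <- which(fwd & bwd)                              # node outside mutual
    x <- setdiff(1:3, c(pair_i[mut], pair_j[mut]))
    if (outd[x] == 2) return(12L)                        # 120D
    if (ind[x] == 2) return(13L)                         # 120U
    return(14L)                                          # 120C
  }
  if (m == 2 && a == 1) return(15L)                      # 210
  16L                                                    # 300
}

# 64-entry lookup: class of every labelled triad, indexed by the 6-bit
# edge code 1 + e12 + 2*e21 + 4*e13 + 8*e31 + 16*e23 + 32*e32.
.triad_lookup <- local({
  tab <- integer(64)
  for (code in 0:63) {
    b <- as.integer(intToBits(code))[1:6]
    tab[code + 1L] <- .classify_code(b[1], b[2], b[3], b[4], b[5], b[6])
  }
  tab
})

#' Directed triad census
#'
#' Counts the 16 isomorphism classes over every unordered triple of nodes
#' of a directed network. Edge weights are ignored (an ordered pair either
#' is or is not connected). For a fixed 11-receiver array every census sums
#' to `choose(11, 3) = 165`, so an empty network has 165 null (003)
#' triads.
#'
#' @param network Directed `igraph` graph, or a square binary adjacency
#'   matrix.
#' @return Named integer vector of length 16 (MAN codes), with attribute
#'   `"n_nodes"`; the counts sum to `choose(n, 3)`.
#' @export
triad_census16 <- function(network) {
  A <- if (inherits(network, "igraph")) {
    if (!igraph::is_directed(network)) stop("network must be directed")
    as.matrix(igraph::as_adjacency_matrix(network, sparse = FALSE))
  } else {
    as.matrix(network)
  }
  A <- (A != 0) * 1L
  diag(A) <- 0L
  n <- nrow(A)
  counts <- integer(16)
  if (n >= 3) {
    tri <- utils::combn(n, 3)
    i <- tri[1, ]; j <- tri[2, ]; k <- tri[3, ]
    code <- A[cbind(i, j)] + 2L * A[cbind(j, i)] +
      4L * A[cbind(i, k)] + 8L * A[cbind(k, i)] +
      16L * A[cbind(j, k)] + 32L * A[cbind(k, j)]
    counts <- tabulate(.triad_lookup[code + 1L], nbins = 16)
  }
  structure(stats::setNames(as.integer(counts), triad_classes()),
            n_nodes = n)
}

#' Monthly per-fish triad-census series
#'
#' For each retained fish and each calendar month of the study, builds the
#' fish's directed movement network over the full receiver array and runs
#' the triad census, joining the monthly mean sea surface temperature.
#' Months in which a fish did not move yield the null census
#' (165, 0, ..., 0) on an 11-receiver array.
#'
#' @param movements Movement table (movements are assigned to the calendar
#'   month of their departure).
#' @param months Character vector of months, `"YYYY-MM"`.
#' @param sst_monthly Named numeric vector of monthly mean SST, keyed by
#'   `"YYYY-MM"`.
#' @param subjects Transmitters to include (default: all in `movements`).
#' @param nodes Receiver vertex set.
#' @param tz Day-boundary timezone.
#' @return A `data.frame` with `transmitter_id`, `month`, `sst` and the 16
#'   class-count columns named by MAN code.
#' @export
monthly_motif_series <- function(movements, months, sst_monthly,
                                 subjects = NULL, nodes = NULL,
                                 tz = "Europe/Stockholm") {
  if (is.null(subjects)) subjects <- sort(unique(movements$transmitter_id))
  if (is.null(nodes)) {
    nodes <- sort(unique(c(movements$from_receiver, movements$to_receiver)))
  }
  mo <- format(as.Date(movements$departure, tz = tz), "%Y-%m")
  grid <- expand.grid(month = months, transmitter_id = subjects,
                      stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)[, c(2, 1)]
  census <- t(mapply(function(subj, m) {
    sel <- movements$transmitter_id == subj & mo == m
    g <- build_network(movements[sel, , drop = FALSE], nodes = nodes,
                       directed = TRUE)
    triad_census16(g)
  }, grid$transmitter_id, grid$month))
  out <- cbind(grid, census)
  out$sst <- as.numeric(sst_monthly[out$month])
  rownames(out) <- NULL
  out[, c("transmitter_id", "month", "sst", triad_classes())]
}

#' Model a motif class count against temperature
#'
#' Fits a negative binomial mixed model of the monthly count of one triad
#' class against monthly mean SST, with a per-fish random intercept and a
#' log link. Classes that never occur (or never vary) are reported as
#' non-estimable rather than raising an error, since geography makes
#' several of the higher-order classes impossible in a sparse coastal
#' array.
#'
#' @param series Output of [monthly_motif_series()].
#' @param class_index Class to model: integer 1..16 or MAN code.
#' @return A `glmm_fit` object (see [fit_nb_glmm()]); `$converged` is
#'   `FALSE` with `$note` set for degenerate classes.
#' @export
motif_temperature_model <- function(series, class_index) {
  lab <- if (is.character(class_index)) class_index
  else triad_classes()[class_index]
  if (!lab %in% triad_classes()) stop("unknown triad class: ", class_index)
  d <- data.frame(count = series[[lab]], sst = series$sst,
                  transmitter_id = series$transmitter_id,
                  stringsAsFactors = FALSE)
  if (all(d$count == 0) || stats::var(d$count) == 0) {
    return(structure(list(converged = FALSE,
                          note = "class count constant: non-estimable",
                          class = lab, coefficients = NULL),
                     class = "glmm_fit"))
  }
  fit <- fit_nb_glmm(count ~ sst, data = d, subject = "transmitter_id")
  fit$class <- lab
  fit
}
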