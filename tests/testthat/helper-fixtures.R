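# Shared fixture builders and independent oracles.

utc <- function(x) as.POSIXct(x, tz = "UTC")

# detection data frame from vectors (timestamps as "YYYY-mm-dd HH:MM:SS" UTC)
make_det <- function(ts, tag, rec, valid = TRUE) {
  ts <- utc(ts)
  d <- data.frame(timestamp = ts, transmitter_id = as.character(tag),
                  receiver_id = as.character(rec),
                  valid = rep_len(valid, length(ts)),
                  stringsAsFactors = FALSE)
  d <- d[order(d$transmitter_id, d$timestamp), , drop = FALSE]
  rownames(d) <- NULL
  d
}

# minimal fish metadata for a set of transmitters
make_fish <- function(tags, release = "2015-08-15 10:00:00",
                      site = "I") {
  data.frame(transmitter_id = tags,
             release_site = rep_len(site, length(tags)),
             weight = 200, total_length = 30,
             release_datetime = utc(rep_len(release, length(tags))),
             stringsAsFactors = FALSE)
}

# random movement table over a node set
random_movements <- function(n, nodes = LETTERS[1:5], tags = c("f1", "f2"),
                             t0 = utc("2015-09-01 00:00:00")) {
  from <- sample(nodes, n, replace = TRUE)
  to <- vapply(from, function(f) sample(setdiff(nodes, f), 1), character(1))
  dep <- t0 + sort(sample.int(n * 3600, n))
  data.frame(transmitter_id = sample(tags, n, replace = TRUE),
             from_receiver = from, to_receiver = unname(to),
             departure = dep, arrival = dep + 300, transit_s = 300,
             stringsAsFactors = FALSE)
}

# --- independent triad oracle: permutation matching against exemplars ----
# Each exemplar is the canonical edge list of one isomorphism class.
triad_exemplars <- local({
  e <- list(
    `003`  = cbind(integer(0), integer(0)),
    `012`  = rbind(c(1, 2)),
    `102`  = rbind(c(1, 2), c(2, 1)),
    `021D` = rbind(c(2, 1), c(2, 3)),
    `021U` = rbind(c(1, 2), c(3, 2)),
    `021C` = rbind(c(1, 2), c(2, 3)),
    `111D` = rbind(c(1, 2), c(2, 1), c(3, 2)),
    `111U` = rbind(c(1, 2), c(2, 1), c(2, 3)),
    `030T` = rbind(c(1, 2), c(3, 2), c(1, 3)),
    `030C` = rbind(c(1, 2), c(2, 3), c(3, 1)),
    `201`  = rbind(c(1, 2), c(2, 1), c(1, 3), c(3, 1)),
    `120D` = rbind(c(2, 1), c(2, 3), c(1, 3), c(3, 1)),
    `120U` = rbind(c(1, 2), c(3, 2), c(1, 3), c(3, 1)),
    `120C` = rbind(c(1, 2), c(2, 3), c(1, 3), c(3, 1)),
    `210`  = rbind(c(1, 2), c(2, 1), c(2, 3), c(3, 2), c(1, 3)),
    `300`  = rbind(c(1, 2), c(2, 1), c(1, 3), c(3, 1), c(2, 3), c(3, 2)))
  lapply(e, function(el) {
    A <- matrix(0L, 3, 3)
    if (nrow(el) > 0) A[el] <- 1L
    A
  })
})

perm3 <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
               c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))

# brute-force class of a 3x3 adjacency matrix
oracle_classify <- function(A) {
  for (k in seq_along(triad_exemplars)) {
    E <- triad_exemplars[[k]]
    for (r in seq_len(nrow(perm3))) {
      p <- perm3[r, ]
      if (all(A[p, p] == E)) return(k)
    }
  }
  stop("unclassifiable triad")
}

# brute-force census: classify every unordered triple
oracle_census <- function(A) {
  n <- nrow(A)
  counts <- integer(16)
  if (n >= 3) {
    for (tri in utils::combn(n, 3, simplify = FALSE)) {
      k <- oracle_classify(A[tri, tri])
      counts[k] <- counts[k] + 1L
    }
  }
  counts
}

random_digraph <- function(n, p) {
  A <- matrix(stats::rbinom(n * n, 1, p), n)
  diag(A) <- 0L
  A
}

# independent permutation enumerator for the Spearman oracle (iterative,
# distinct from the package's recursive generator)
oracle_perms <- function(n) {
  out <- matrix(1L, 1, 1)
  for (m in 2:n) {
    blocks <- lapply(seq_len(m), function(pos) {
      left <- out[, seq_len(pos - 1), drop = FALSE]
      right <- if (pos <= m - 1) out[, pos:(m - 1), drop = FALSE]
      do.call(cbind, Filter(Negate(is.null), list(left, m, right)))
    })
    out <- do.call(rbind, blocks)
  }
  out
}
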