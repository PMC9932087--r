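#' Draw one vaznull replicate
#'
#' Generates a random weighted matrix preserving the dimensions, the total
#' weight m and the number of links L of the observed matrix, while letting
#' marginal totals vary. Cell selection probabilities are proportional to
#' the outer product of the observed marginal totals. First a binary
#' skeleton of exactly L occupied cells is drawn sequentially without
#' replacement, constrained so every row and column ends up with at least
#' one occupied cell (when the remaining number of draws equals the number
#' of still-empty rows or columns, candidates are restricted to cells that
#' reduce that deficit, which guarantees termination without rejection);
#' the remaining m - L interaction events are then distributed among the
#' occupied cells with the same probabilities.
#'
#' @param net bipartite network matrix.
#' @param seed integer seed.
#' @return a matrix with the same dimnames, total and link count as `net`.
#' @export
vaznull_sample <- function(net, seed) {
  validate_network(net)
  if (missing(seed)) abort_input("a seed is required")
  nr <- nrow(net); nc <- ncol(net)
  L <- sum(net > 0)
  m <- sum(net)
  if (L < nr || L < nc)
    abort_input("infeasible: fewer links than rows or columns; every species cannot be connected")
  p <- outer(rowSums(net), colSums(net))
  with_seed(seed, {
    chosen <- matrix(FALSE, nr, nc)
    for (step in seq_len(L)) {
      remaining <- L - step + 1L
      er <- which(rowSums(chosen) == 0)
      ec <- which(colSums(chosen) == 0)
      cand <- !chosen
      if (remaining == max(length(er), length(ec))) {
        # tight: this draw must cover an empty row and/or column
        if (length(er) >= length(ec) && length(er) > 0)
          cand[-er, ] <- FALSE
        if (length(ec) >= length(er) && length(ec) > 0)
          cand[, -ec] <- FALSE
      }
      idx <- which(cand)
      cell <- if (length(idx) == 1L) idx
              else sample(idx, 1L, prob = p[idx])
      chosen[cell] <- TRUE
    }
    out <- matrix(0, nr, nc, dimnames = dimnames(net))
    out[chosen] <- 1
    extra <- m - L
    if (extra > 0) {
      idx <- which(chosen)
      out[idx] <- out[idx] +
        as.vector(stats::rmultinom(1, extra, prob = p[idx]))
    }
    out
  })
}

#' Monte Carlo significance of a network metric under vaznull
#'
#' p equals the number of null replicates whose metric is greater than or
#' equal to the observed metric, divided by the number of replicates
#' (upper-tail test; ties count against the observed structure). A metric
#' failure on a replicate triggers regeneration of that replicate, at most
#' 10 times, with a message.
#'
#' @param net bipartite network matrix.
#' @param metric function of one network returning a scalar.
#' @param n number of null matrices (default 1000).
#' @param seed integer seed for the ensemble; replicate substreams are
#'   derived by counter so ensembles are reproducible and order-independent.
#' @return list: `observed`, `p`, `n`, `seed`, and the replicate `values`.
#' @export
mc_pvalue <- function(net, metric, n = 1000L, seed) {
  validate_network(net)
  if (missing(seed)) abort_input("a seed is required")
  stopifnot(n >= 1L)
  obs <- metric(net)
  vals <- numeric(n)
  base <- as.integer(seed) %% 1000003L
  for (i in seq_len(n)) {
    val <- NULL
    for (try in 0:10) {
      sub_seed <- (base + i * 131071L + try * 7919L) %% 2147483647L
      val <- tryCatch(metric(vaznull_sample(net, seed = sub_seed)),
                      error = function(e) NULL)
      if (!is.null(val)) break
      message(sprintf("metric failed on replicate %d (attempt %d); regenerating", i, try + 1L))
    }
    if (is.null(val)) abort_input("metric failed repeatedly on null replicates")
    vals[i] <- val
  }
  list(observed = obs, p = sum(vals >= obs) / n, n = n, seed = seed,
       values = vals)
}
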