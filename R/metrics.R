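#' Complementary specialization H2'
#'
#' H2' standardises the two-dimensional Shannon entropy of the interaction
#' frequencies against the entropy bounds attainable under the observed
#' marginal totals: H2' = (H2max - H2) / (H2max - H2min), clipped to
#' \[0, 1\]. A value of 1 means species share no partners (perfectly
#' complementary interactions); 0 means interactions follow the marginal
#' expectations.
#'
#' H2max is the entropy of the maximum-entropy nonnegative table with the
#' observed marginals, i.e. the independence table obtained as the outer
#' product of the marginal frequencies (the fixed point of iterative
#' proportional fitting on the real-valued relaxation). H2min comes from the
#' greedy cell-packing heuristic: repeatedly allocate
#' min(remaining row total, remaining column total) to the cell of the
#' currently largest remaining marginals. On balanced marginals both bounds
#' coincide with the exact integer-matrix optima.
#'
#' @param net bipartite network matrix, at least 2 x 2 with total >= 2.
#' @return H2' in \[0, 1\].
#' @export
h2prime <- function(net) {
  validate_network(net, min_dim = 2L, min_total = 2L)
  m <- sum(net)
  p <- net / m
  h2 <- entropy_nats(p)
  rfrac <- rowSums(net) / m
  cfrac <- colSums(net) / m
  h2max <- entropy_nats(outer(rfrac, cfrac))
  h2min <- entropy_nats(greedy_min_entropy_table(rowSums(net), colSums(net)) / m)
  if (h2max - h2min < 1e-12) return(0)
  min(max((h2max - h2) / (h2max - h2min), 0), 1)
}

entropy_nats <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

# Greedy minimum-entropy integer allocation under fixed marginals: always
# pack as much weight as possible into the cell joining the largest
# remaining row and column totals.
greedy_min_entropy_table <- function(rt, ct) {
  out <- matrix(0, length(rt), length(ct))
  while (sum(rt) > 0) {
    i <- which.max(rt)
    j <- which.max(ct)
    w <- min(rt[i], ct[j])
    out[i, j] <- out[i, j] + w
    rt[i] <- rt[i] - w
    ct[j] <- ct[j] - w
  }
  out
}

# Pairwise weighted-nestedness contribution for ordered pair (u over v) of
# row vectors restricted to shared partners: the fraction (x100) of v's
# positive cells strictly dominated by u's.
wnoda_pair_directed <- function(u, v) {
  pos <- which(v > 0)
  if (!length(pos)) return(NA_real_)
  100 * sum(u[pos] > v[pos]) / length(pos)
}

# Contribution of an unordered same-side pair: the richer node (larger
# marginal) overlaps the poorer; equal marginal totals do not zero the
# contribution — both orderings are evaluated and averaged.
wnoda_pair <- function(a, b) {
  ma <- sum(a); mb <- sum(b)
  if (ma > mb) wnoda_pair_directed(a, b)
  else if (mb > ma) wnoda_pair_directed(b, a)
  else mean(c(wnoda_pair_directed(a, b), wnoda_pair_directed(b, a)), na.rm = TRUE)
}

wnoda_pair_table <- function(net) {
  pairs <- list()
  add <- function(side, i, j, val) {
    pairs[[length(pairs) + 1L]] <<- list(side = side, i = i, j = j, value = val)
  }
  nr <- nrow(net); nc <- ncol(net)
  for (i in seq_len(nr - 1L)) for (j in seq.int(i + 1L, nr))
    add("row", i, j, wnoda_pair(net[i, ], net[j, ]))
  for (i in seq_len(nc - 1L)) for (j in seq.int(i + 1L, nc))
    add("col", i, j, wnoda_pair(net[, i], net[, j]))
  do.call(rbind, lapply(pairs, as.data.frame))
}

#' Weighted nestedness WNODA
#'
#' Mean over all unordered row pairs and column pairs of the pairwise
#' weighted-nestedness contribution: for a pair ordered so the richer node
#' (larger marginal total) comes first, the percentage of the poorer node's
#' positive cells whose weight is strictly exceeded by the richer node's
#' weight with the same partner. Unlike weighted NODF, ties in marginal
#' totals do not zero a pair's contribution; both orderings are averaged.
#' Reported on the 0-100 scale (`scale01 = TRUE` divides by 100).
#'
#' @param net bipartite network matrix, at least 2 x 2.
#' @param scale01 report on \[0, 1\] instead of 0-100.
#' @return nestedness value.
#' @export
wnoda <- function(net, scale01 = FALSE) {
  validate_network(net, min_dim = 2L)
  tab <- wnoda_pair_table(net)
  val <- mean(tab$value, na.rm = TRUE)
  if (scale01) val / 100 else val
}

#' Within- and between-module WNODA (compound topology)
#'
#' Averages the same pairwise contributions as [wnoda()] separately over
#' node pairs sharing a module and pairs in different modules. A network
#' with a compound topology shows high within-module and low between-module
#' nestedness.
#'
#' @param net bipartite network matrix.
#' @param partition a module partition as returned by [dirtlpawb_plus()]
#'   (list with `row_modules`, `col_modules`).
#' @param scale01 report on \[0, 1\] instead of 0-100.
#' @return named numeric vector `c(within = , between = )`; for a
#'   single-module partition `between` is `NA` (undefined) with a warning
#'   and `within` equals [wnoda()].
#' @export
wnoda_compound <- function(net, partition, scale01 = FALSE) {
  validate_network(net, min_dim = 2L)
  rm_ <- partition$row_modules
  cm_ <- partition$col_modules
  if (length(rm_) != nrow(net) || length(cm_) != ncol(net))
    abort_input("partition does not match the network dimensions")
  single <- length(unique(c(rm_, cm_))) < 2L
  if (single)
    warning("single-module partition: between-module nestedness is undefined")
  tab <- wnoda_pair_table(net)
  mi <- ifelse(tab$side == "row", rm_[tab$i], cm_[tab$i])
  mj <- ifelse(tab$side == "row", rm_[tab$j], cm_[tab$j])
  same <- mi == mj
  w <- mean(tab$value[same], na.rm = TRUE)
  b <- if (single) NA_real_ else mean(tab$value[!same], na.rm = TRUE)
  out <- c(within = w, between = b)
  if (scale01) out / 100 else out
}

#' Barber weighted modularity Qw
#'
#' Qw = (1/m) * sum_ij (Y_ij - k_i d_j / m) over same-module (i, j) pairs,
#' with k and d the row and column marginal totals and m the total weight.
#'
#' @param net bipartite network matrix.
#' @param partition list with integer vectors `row_modules`, `col_modules`.
#' @return modularity score.
#' @export
barber_qw <- function(net, partition) {
  validate_network(net)
  rm_ <- partition$row_modules
  cm_ <- partition$col_modules
  if (length(rm_) != nrow(net) || length(cm_) != ncol(net))
    abort_input("partition does not match the network dimensions")
  m <- sum(net)
  B <- net - outer(rowSums(net), colSums(net)) / m
  sum(B[outer(rm_, cm_, "==")]) / m
}

# One weighted label-propagation + agglomeration run from the given initial
# row labels; returns list(row_modules, col_modules, qw).
lpawb_run <- function(B, init_rows) {
  nr <- nrow(B); nc <- ncol(B)
  rowlab <- init_rows
  collab <- rep(NA_integer_, nc)
  next_label <- max(rowlab) + 1L

  # best label for every node on one side given the other side's labels;
  # ties keep the current label if tied-best, else the smallest label id;
  # a node whose best score is negative opens a fresh module.
  assign_side <- function(scores_by_label, labels_avail, current) {
    out <- integer(ncol(scores_by_label))
    for (v in seq_len(ncol(scores_by_label))) {
      sc <- scores_by_label[, v]
      best <- max(sc)
      if (best < 0) {
        out[v] <- next_label
        next_label <<- next_label + 1L
      } else {
        cand <- labels_avail[abs(sc - best) < 1e-12]
        out[v] <- if (!is.na(current[v]) && current[v] %in% cand) current[v]
                  else min(cand)
      }
    }
    out
  }

  score_matrix <- function(M, labels) {
    # rows of result indexed by unique label; M is B or t(B)
    u <- sort(unique(labels))
    agg <- rowsum(M, group = labels, reorder = TRUE)
    list(scores = agg, labels = u)
  }

  qw_of <- function(rl, cl) sum(B[outer(rl, cl, "==")])

  qw_prev <- -Inf
  for (iter in seq_len(100L)) {
    sc <- score_matrix(B, rowlab)           # label x col scores
    collab <- assign_side(sc$scores, sc$labels, collab)
    sc <- score_matrix(t(B), collab)        # label x row scores
    rowlab <- assign_side(sc$scores, sc$labels, rowlab)
    qw_now <- qw_of(rowlab, collab)
    if (qw_now <= qw_prev + 1e-12) break
    qw_prev <- qw_now
  }

  # exhaustive pairwise agglomeration, greedily accepting the best
  # Qw-increasing merge until none remains
  repeat {
    labs <- sort(unique(c(rowlab, collab)))
    k <- length(labs)
    if (k < 2L) break
    best_gain <- 0; best_pair <- NULL
    for (a in seq_len(k - 1L)) for (b in seq.int(a + 1L, k)) {
      ra <- rowlab == labs[a]; rb <- rowlab == labs[b]
      ca <- collab == labs[a]; cb <- collab == labs[b]
      gain <- sum(B[ra, cb, drop = FALSE]) + sum(B[rb, ca, drop = FALSE])
      if (gain > best_gain + 1e-12) {
        best_gain <- gain
        best_pair <- c(labs[a], labs[b])
      }
    }
    if (is.null(best_pair)) break
    rowlab[rowlab == best_pair[2]] <- best_pair[1]
    collab[collab == best_pair[2]] <- best_pair[1]
  }

  list(row_modules = rowlab, col_modules = collab, qw = qw_of(rowlab, collab))
}

# relabel modules contiguously from 1 in order of first appearance
relabel_partition <- function(part) {
  labs <- unique(c(part$row_modules, part$col_modules))
  map <- seq_along(labs)
  names(map) <- labs
  part$row_modules <- unname(map[as.character(part$row_modules)])
  part$col_modules <- unname(map[as.character(part$col_modules)])
  part
}

#' Maximise Barber modularity by DIRTLPAwb+ label propagation
#'
#' Repeated runs of (i) random label initialisation over the rows, (ii)
#' weighted label propagation alternating sides until Qw stops improving,
#' and (iii) exhaustive pairwise module agglomeration accepted while Qw
#' increases; the best partition over `restarts` runs is returned. The first
#' run starts from one module per row; later runs draw the initial label
#' count and assignment at random, which lets the search escape the
#' one-module-per-row basin. Deterministic given `seed`.
#'
#' @param net bipartite network matrix.
#' @param restarts number of independent runs (default 20).
#' @param seed integer seed (required, for reproducibility).
#' @return list of class `module_partition`: integer `row_modules`,
#'   `col_modules` (contiguous from 1), scalar `qw`, plus `restarts`, `seed`.
#' @export
dirtlpawb_plus <- function(net, restarts = 20L, seed) {
  validate_network(net)
  if (missing(seed)) abort_input("a seed is required")
  stopifnot(restarts >= 1L)
  m <- sum(net)
  B <- (net - outer(rowSums(net), colSums(net)) / m) / m
  nr <- nrow(net)
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(restarts)) {
      init <- if (r == 1L) seq_len(nr)
              else sample.int(sample.int(nr, 1L), nr, replace = TRUE)
      run <- lpawb_run(B, init)
      if (is.null(best) || run$qw > best$qw + 1e-12) best <- run
    }
  })
  # never worse than the single-module partition (Qw = 0)
  if (best$qw < 0) {
    best <- list(row_modules = rep(1L, nr),
                 col_modules = rep(1L, ncol(net)), qw = 0)
  }
  best <- relabel_partition(best)
  best$qw <- barber_qw(net, best)
  best$restarts <- restarts
  best$seed <- seed
  class(best) <- "module_partition"
  best
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf("module partition: %d modules, Qw = %.4f (restarts = %d, seed = %s)\n",
              length(unique(c(x$row_modules, x$col_modules))),
              x$qw, x$restarts, format(x$seed)))
  invisible(x)
}
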