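# Independent oracles, kept free of the implementation code paths they check.

# All nonnegative integer matrices with the given row/column totals,
# enumerated cell by cell (feasible for m <= ~10 and shapes <= 3x3).
enumerate_fixed_marginals <- function(rt, ct) {
  nr <- length(rt); nc <- length(ct)
  out <- list()
  cells <- matrix(0L, nr, nc)
  fill <- function(i, j, row_left, col_left) {
    if (i > nr) {
      if (all(col_left == 0L)) out[[length(out) + 1L]] <<- cells
      return(invisible())
    }
    if (j > nc) {
      if (row_left[i] == 0L) fill(i + 1L, 1L, row_left, col_left)
      return(invisible())
    }
    hi <- min(row_left[i], col_left[j])
    for (v in 0:hi) {
      cells[i, j] <<- v
      rl <- row_left; rl[i] <- rl[i] - v
      cl <- col_left; cl[j] <- cl[j] - v
      fill(i, j + 1L, rl, cl)
    }
    cells[i, j] <<- 0L
  }
  fill(1L, 1L, as.integer(rt), as.integer(ct))
  out
}

shannon <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }

# exact H2' from the integer-matrix entropy bounds under the observed
# marginals, by exhaustive enumeration
h2prime_oracle <- function(net) {
  m <- sum(net)
  ents <- vapply(enumerate_fixed_marginals(rowSums(net), colSums(net)),
                 function(tab) shannon(tab / m), 0)
  h2 <- shannon(net / m)
  (max(ents) - h2) / (max(ents) - min(ents))
}

# restricted-growth-string enumeration of set partitions of n elements
set_partitions <- function(n) {
  out <- list()
  rgs <- integer(n)
  rec <- function(i, maxl) {
    if (i > n) { out[[length(out) + 1L]] <<- rgs; return(invisible()) }
    for (l in seq_len(maxl + 1L)) { rgs[i] <<- l; rec(i + 1L, max(maxl, l)) }
  }
  rec(1L, 0L)
  out
}

# Globally optimal Barber Qw by exhaustive search: enumerate row partitions
# and assign every column to its best row-module (or a module of its own,
# contributing 0). Any full partition is dominated by its induced row
# partition with optimal columns, so the maximum over this family is the
# global optimum.
qw_oracle <- function(net) {
  m <- sum(net)
  B <- net - outer(rowSums(net), colSums(net)) / m
  best <- 0
  for (rp in set_partitions(nrow(net))) {
    agg <- rowsum(B, rp)
    val <- sum(pmax(apply(agg, 2, max), 0))
    if (val > best) best <- val
  }
  best / m
}

# direct evaluation of the pairwise weighted-nestedness rule over explicit
# loops (independent of the vectorised implementation)
wnoda_oracle <- function(net) {
  contrib <- function(u, v) {      # u = richer, v = poorer
    pos <- which(v > 0)
    if (!length(pos)) return(NA_real_)
    100 * sum(u[pos] > v[pos]) / length(pos)
  }
  pair <- function(a, b) {
    if (sum(a) > sum(b)) contrib(a, b)
    else if (sum(b) > sum(a)) contrib(b, a)
    else mean(c(contrib(a, b), contrib(b, a)), na.rm = TRUE)
  }
  vals <- c()
  for (i in seq_len(nrow(net) - 1)) for (j in (i + 1):nrow(net))
    vals <- c(vals, pair(net[i, ], net[j, ]))
  for (i in seq_len(ncol(net) - 1)) for (j in (i + 1):ncol(net))
    vals <- c(vals, pair(net[, i], net[, j]))
  mean(vals, na.rm = TRUE)
}

# one-way ANOVA F from first-principles sums of squares
anova_f_oracle <- function(values, groups) {
  groups <- factor(groups)
  k <- nlevels(groups); n <- length(values)
  gm <- mean(values)
  mns <- tapply(values, groups, mean)
  ns <- tabulate(groups)
  ss_b <- sum(ns * (mns - gm)^2)
  ss_w <- sum((values - mns[groups])^2)
  (ss_b / (k - 1)) / (ss_w / (n - k))
}
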