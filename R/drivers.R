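new_prob_model <- function(mat, label) {
  s <- sum(mat)
  if (any(mat < 0)) abort_input("probability cells must be nonnegative")
  if (s <= 0) abort_input(sprintf("model %s is degenerate (all cells zero)", label))
  mat <- mat / s
  structure(mat, label = label, class = c("prob_model", class(mat)))
}

#' @export
print.prob_model <- function(x, ...) {
  cat(sprintf("interaction probability model '%s' (%d x %d, sums to 1)\n",
              attr(x, "label"), nrow(x), ncol(x)))
  print(unclass(x)[seq_len(min(4, nrow(x))), seq_len(min(4, ncol(x))), drop = FALSE])
  invisible(x)
}

#' Abundance (neutral) probability matrix
#'
#' Cell (i, j) is the product of the relative abundances of bat i and plant
#' j, renormalized to sum one: under neutrality species interact in
#' proportion to how often they meet.
#'
#' @param bat_rel_abund,plant_rel_abund named nonnegative vectors summing to
#'   1 (within 1e-9), aligned to the target network's rows/columns.
#' @return a `prob_model` matrix, label "A".
#' @export
prob_abundance <- function(bat_rel_abund, plant_rel_abund) {
  for (v in list(bat_rel_abund, plant_rel_abund)) {
    if (any(v < 0)) abort_input("relative abundances must be nonnegative")
    if (sum(v) <= 0) abort_input("relative abundances are all zero")
    if (abs(sum(v) - 1) > 1e-9)
      abort_input("relative abundances must sum to one")
  }
  m <- outer(bat_rel_abund, plant_rel_abund)
  dimnames(m) <- list(names(bat_rel_abund), names(plant_rel_abund))
  new_prob_model(m, "A")
}

#' Morphological-specialization probability matrix
#'
#' Cell (i, j) = 1 - |BSI_i - FSI_j| (matching degrees of specialization),
#' renormalized to sum one. Indices are re-normalized (min-max) over the
#' species of the target network, so each analyzed matrix spans \[0, 1\].
#'
#' @param traits list as from [species_trait_table()].
#' @param rows,cols row (bat) and column (plant) labels of the target
#'   network.
#' @return a `prob_model` matrix, label "M".
#' @export
prob_morphology <- function(traits, rows, cols) {
  bt <- traits$bats; pt <- traits$plants
  if (!all(rows %in% bt$species))
    abort_input("missing bat trait indices for: ",
                paste(setdiff(rows, bt$species), collapse = ", "))
  if (!all(cols %in% pt$species))
    abort_input("missing plant trait indices for: ",
                paste(setdiff(cols, pt$species), collapse = ", "))
  bsi <- minmax(bt$bsi_raw[match(rows, bt$species)])
  fsi <- minmax(pt$fsi_raw[match(cols, pt$species)])
  m <- outer(bsi, fsi, morph_match_prob)
  dimnames(m) <- list(rows, cols)
  new_prob_model(m, "M")
}

# months (1-12) in which a species has any positive count, pooled over sites
presence_months <- function(occ, species) {
  sub <- occ[occ$species == species & occ$count > 0, , drop = FALSE]
  sort(unique(sub$month))
}

#' Phenological-overlap probability matrix
#'
#' Raw cell (i, j) = number of calendar months in which bat i was captured
#' and plant j flowered anywhere in the site, renormalized to sum one.
#' Species never recorded in any month yield all-zero rows/columns (with a
#' message); the model is degenerate only if every cell is zero.
#'
#' @param bat_occ,plant_occ occurrence data.frames with columns `species`,
#'   `site`, `month`, `count`.
#' @param rows,cols target network labels.
#' @return a `prob_model` matrix, label "P".
#' @export
prob_phenology <- function(bat_occ, plant_occ, rows, cols) {
  bm <- lapply(rows, presence_months, occ = bat_occ)
  pm <- lapply(cols, presence_months, occ = plant_occ)
  none <- c(rows[lengths(bm) == 0], cols[lengths(pm) == 0])
  if (length(none))
    message("species with zero presence in all months: ",
            paste(none, collapse = ", "))
  m <- matrix(0, length(rows), length(cols), dimnames = list(rows, cols))
  for (i in seq_along(rows)) for (j in seq_along(cols))
    m[i, j] <- length(intersect(bm[[i]], pm[[j]]))
  new_prob_model(m, "P")
}

#' Spatial-overlap probability matrix
#'
#' Raw cell (i, j) = total number of individuals of bat i captured in
#' sampling sites where plant j was registered, over all months,
#' renormalized to sum one.
#'
#' @inheritParams prob_phenology
#' @return a `prob_model` matrix, label "S".
#' @export
prob_spatial <- function(bat_occ, plant_occ, rows, cols) {
  bat_by_site <- with(bat_occ,
    tapply(count, list(factor(species, levels = rows), site), sum, default = 0))
  plant_sites <- lapply(cols, function(sp) {
    sub <- plant_occ[plant_occ$species == sp & plant_occ$count > 0, , drop = FALSE]
    unique(sub$site)
  })
  m <- matrix(0, length(rows), length(cols), dimnames = list(rows, cols))
  for (j in seq_along(cols)) {
    sites <- intersect(plant_sites[[j]], colnames(bat_by_site))
    if (length(sites))
      m[, j] <- rowSums(bat_by_site[, sites, drop = FALSE])
  }
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    message("species with zero spatial overlap present in the S matrix")
  new_prob_model(m, "S")
}

#' Element-wise compound of probability models
#'
#' Cellwise product of the factor matrices, renormalized to sum one; the
#' label is the concatenation of the factor labels (e.g. "MPS"). Zeros in
#' any factor propagate ('forbidden links' stay forbidden).
#'
#' @param ... two or more `prob_model` matrices with aligned dimensions.
#' @return a `prob_model` matrix.
#' @export
compound_model <- function(...) {
  models <- list(...)
  if (length(models) == 1L && is.list(models[[1]]) && !is.matrix(models[[1]]))
    models <- models[[1]]
  stopifnot(length(models) >= 2L)
  dims <- vapply(models, function(x) paste(dim(x), collapse = "x"), "")
  if (length(unique(dims)) != 1L) abort_input("model shapes differ")
  out <- Reduce(`*`, lapply(models, unclass))
  label <- paste(vapply(models, attr, "", "label"), collapse = "")
  new_prob_model(out, label)
}

#' Benchmark null probability model
#'
#' Every cell gets the same probability 1/(rows x cols).
#'
#' @param rows,cols labels of the target network.
#' @return a `prob_model` matrix, label "Null".
#' @export
benchmark_null <- function(rows, cols) {
  m <- matrix(1, length(rows), length(cols), dimnames = list(rows, cols))
  new_prob_model(m, "Null")
}

#' Saturated probability model
#'
#' The observed matrix itself as probabilities, p = Y/m: the
#' maximum-likelihood reference for the multinomial kernel.
#'
#' @param net bipartite network matrix.
#' @return a `prob_model` matrix, label "Saturated".
#' @export
saturated_model <- function(net) {
  validate_network(net)
  new_prob_model(net + 0, "Saturated")
}

#' Multinomial log-likelihood of a probability model
#'
#' Kernel sum(Y_ij * ln p_ij), with 0 * ln 0 := 0; returns -Inf when some
#' observed cell has zero model probability. The multinomial coefficient
#' ln(m! / prod Y_ij!) is a model-independent additive constant, excluded by
#' default (`include_coef = TRUE` adds it; AIC rankings are unchanged).
#'
#' @param net bipartite network matrix.
#' @param model `prob_model` matrix of the same shape.
#' @param include_coef add the multinomial coefficient.
#' @return log-likelihood (possibly -Inf).
#' @export
multinomial_loglik <- function(net, model, include_coef = FALSE) {
  validate_network(net)
  if (!all(dim(net) == dim(model))) abort_input("shape mismatch")
  y <- as.vector(net)
  p <- as.vector(unclass(model))
  if (any(y > 0 & p == 0)) return(-Inf)
  pos <- y > 0
  ll <- sum(y[pos] * log(p[pos]))
  if (include_coef)
    ll <- ll + lgamma(sum(y) + 1) - sum(lgamma(y + 1))
  ll
}

#' Fit and rank all interaction-driver models
#'
#' Builds the four single probability matrices — abundance (A), morphology
#' (M), phenological overlap (P), spatial overlap (S) — from the raw field
#' tables, the seven compounds (SP, AS, AP, APS, MS, MP, MPS) and the
#' benchmark Null, computes each model's multinomial log-likelihood against
#' the observed network, and ranks them by AIC = -2 lnL + 2K. K is the
#' number of species used in the probability matrices (rows + columns of
#' the analyzed network), identical for all models of one network, so
#' within a network the AIC ranking equals the likelihood ranking. dAIC is
#' computed against the chosen reference: `"best"` (the minimum-AIC model
#' of the set) or `"saturated"` (the observed matrix itself as probability
#' model, p = Y/m, also with K = rows + columns). Models with -Inf
#' log-likelihood are flagged unfittable and ranked last with dAIC = Inf.
#'
#' Relative abundances are derived from the occurrence tables after any
#' network subsetting (capture totals for bats, summed flowering counts for
#' plants, each normalized over the network's own species), and the
#' morphology indices are re-normalized on the network's species set, so a
#' sub-network is analyzed as its own multinomial experiment.
#'
#' @param net bipartite network matrix (full or guild sub-network).
#' @param traits list from [species_trait_table()].
#' @param bat_occ,plant_occ occurrence data.frames (`species`, `site`,
#'   `month`, `count`).
#' @param reference `"best"` or `"saturated"`.
#' @param include_coef include the multinomial coefficient (rank-invariant).
#' @return data.frame with columns `label`, `loglik`, `K`, `AIC`,
#'   `delta_aic`, `unfittable`, sorted by AIC ascending; the list of
#'   probability matrices is attached as attribute `"models"`.
#' @export
fit_all <- function(net, traits, bat_occ, plant_occ,
                    reference = c("best", "saturated"),
                    include_coef = FALSE) {
  reference <- match.arg(reference)
  validate_network(net)
  rows <- rownames(net); cols <- colnames(net)

  bat_tot <- with(bat_occ[bat_occ$species %in% rows, , drop = FALSE],
                  tapply(count, factor(species, levels = rows), sum, default = 0))
  plant_tot <- with(plant_occ[plant_occ$species %in% cols, , drop = FALSE],
                    tapply(count, factor(species, levels = cols), sum, default = 0))
  A <- prob_abundance(bat_tot / sum(bat_tot), plant_tot / sum(plant_tot))
  M <- prob_morphology(traits, rows, cols)
  P <- suppressMessages(prob_phenology(bat_occ, plant_occ, rows, cols))
  S <- suppressMessages(prob_spatial(bat_occ, plant_occ, rows, cols))

  base <- list(A = A, M = M, P = P, S = S)
  combos <- list("SP" = c("S", "P"), "AS" = c("A", "S"), "AP" = c("A", "P"),
                 "APS" = c("A", "P", "S"), "MS" = c("M", "S"),
                 "MP" = c("M", "P"), "MPS" = c("M", "P", "S"))
  models <- base
  for (lab in names(combos)) {
    mod <- tryCatch(compound_model(base[combos[[lab]]]),
                    error = function(e) NULL)
    if (!is.null(mod)) {
      attr(mod, "label") <- lab
      models[[lab]] <- mod
    } else {
      models[[lab]] <- NA  # degenerate (all-zero product): unfittable
    }
  }
  models$Null <- benchmark_null(rows, cols)

  K <- length(rows) + length(cols)
  fits <- lapply(names(models), function(lab) {
    mod <- models[[lab]]
    ll <- if (is.matrix(mod)) multinomial_loglik(net, mod, include_coef) else -Inf
    data.frame(label = lab, loglik = ll, K = K,
               AIC = if (is.finite(ll)) -2 * ll + 2 * K else Inf,
               unfittable = !is.finite(ll), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, fits)

  sat_ll <- multinomial_loglik(net, saturated_model(net), include_coef)
  sat_aic <- -2 * sat_ll + 2 * K
  if (reference == "saturated") {
    out <- rbind(out, data.frame(label = "Saturated", loglik = sat_ll, K = K,
                                 AIC = sat_aic, unfittable = FALSE,
                                 stringsAsFactors = FALSE))
    ref_aic <- sat_aic
  } else {
    ref_aic <- min(out$AIC)
  }
  out$delta_aic <- out$AIC - ref_aic
  out$delta_aic[!is.finite(out$AIC)] <- Inf
  out <- out[order(out$AIC, out$label), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "reference") <- reference
  attr(out, "models") <- Filter(is.matrix, models)
  out
}
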