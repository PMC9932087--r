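#' Chao1 asymptotic species richness
#'
#' Classic Chao1 = S_obs + F1^2 / (2 F2) when doubletons are present, and
#' the bias-corrected form S_obs + F1 (F1 - 1) / (2 (F2 + 1)) when F2 = 0,
#' with F1 and F2 the numbers of singleton and doubleton species.
#'
#' @param abund integer abundance vector (observed species only, counts
#'   >= 1).
#' @return list: `S_obs`, `F1`, `F2`, `estimate`, `se` (Chao's variance
#'   formula for the matching branch).
#' @export
chao1 <- function(abund) {
  if (!length(abund)) abort_input("abundance vector is empty")
  if (any(abund < 1)) abort_input("observed species must have count >= 1")
  s_obs <- length(abund)
  f1 <- sum(abund == 1)
  f2 <- sum(abund == 2)
  if (f2 > 0) {
    est <- s_obs + f1^2 / (2 * f2)
    r <- f1 / f2
    var <- f2 * (r^2 / 2 + r^3 + r^4 / 4)
  } else {
    est <- s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
    var <- f1 * (f1 - 1) / 2 + f1 * (2 * f1 - 1)^2 / 4 -
      f1^4 / (4 * est)
    var <- max(var, 0)
  }
  list(S_obs = s_obs, F1 = f1, F2 = f2, estimate = est, se = sqrt(var))
}

#' Sampling completeness
#'
#' 100 * S_obs / Chao1 estimate: the percentage of the asymptotic richness
#' that the sample captured.
#'
#' @param s_obs observed richness (> 0).
#' @param chao Chao1 estimate (>= `s_obs`).
#' @return percentage.
#' @export
completeness <- function(s_obs, chao) {
  if (s_obs <= 0) abort_input("observed richness must be positive")
  if (chao < s_obs) abort_input("Chao1 estimate cannot fall below S_obs")
  100 * s_obs / chao
}

#' Individual-based rarefaction curve
#'
#' Exact hypergeometric expectation of the number of species in a random
#' subsample of n individuals, E[S_n] = sum_s (1 - C(N - N_s, n) / C(N, n)),
#' computed through [vegan::rarefy()].
#'
#' @param abund integer abundance vector.
#' @param sizes subsample sizes (each <= total individuals).
#' @return data.frame with columns `n` and `expected_richness`.
#' @export
rarefaction_curve <- function(abund, sizes) {
  if (any(abund < 1)) abort_input("observed species must have count >= 1")
  n_tot <- sum(abund)
  if (any(sizes < 1) || any(sizes > n_tot))
    abort_input("subsample sizes must lie in [1, total individuals]")
  # vegan::rarefy warns when no singletons are present; the expectation is
  # exact either way
  exp_s <- suppressWarnings(
    as.numeric(vegan::rarefy(matrix(abund, nrow = 1), sample = sizes)))
  data.frame(n = sizes, expected_richness = exp_s)
}

#' Module-wise trait comparison (one-way ANOVA + Tukey HSD)
#'
#' Tests whether the distribution of an individual-level morphological
#' variable (RSR/BCI for bats, FTL/COD for plants) differs across network
#' modules: a one-way ANOVA followed by Tukey honest significant
#' differences for the pairwise module contrasts.
#'
#' @param values numeric vector of individual trait values.
#' @param module factor/vector of module membership, parallel to `values`;
#'   at least 2 modules with at least 2 values each.
#' @return list: `F`, `df1`, `df2`, `p`, and `pairwise` (data.frame with
#'   contrast, diff, lwr, upr, p_adj).
#' @export
module_trait_anova <- function(values, module) {
  module <- factor(module)
  if (nlevels(module) < 2L)
    abort_input("at least two modules are required")
  if (any(table(module) < 2L))
    abort_input("every module needs at least two values")
  if (all(tapply(values, module, stats::var) == 0))
    abort_input("zero within-module variance everywhere; F undefined")
  fit <- stats::aov(values ~ module)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$module
  list(F = an[["F value"]][1], df1 = an[["Df"]][1], df2 = an[["Df"]][2],
       p = an[["Pr(>F)"]][1],
       pairwise = data.frame(contrast = rownames(tk), diff = tk[, "diff"],
                             lwr = tk[, "lwr"], upr = tk[, "upr"],
                             p_adj = tk[, "p adj"], row.names = NULL))
}
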