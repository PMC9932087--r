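bat_names <- function(n) paste0("bat", seq_len(n))
plant_names <- function(n) paste0("plant", seq_len(n))

occ_df <- function(species, site, month, count) {
  data.frame(species = species, site = site, month = month, count = count,
             stringsAsFactors = FALSE)
}

test_that("abundance model is the renormalized outer product", {
  u <- prob_abundance(c(bat1 = 0.5, bat2 = 0.5),
                      c(plant1 = 0.5, plant2 = 0.5))
  expect_equal(unclass(u), matrix(0.25, 2, 2,
               dimnames = list(bat_names(2), plant_names(2))),
               ignore_attr = TRUE)
  z <- prob_abundance(c(bat1 = 1, bat2 = 0), c(plant1 = 0.5, plant2 = 0.5))
  expect_equal(unname(unclass(z)[2, ]), c(0, 0))
  o <- prob_abundance(c(a = 0.6, b = 0.4), c(x = 0.5, y = 0.3, z = 0.2))
  expect_equal(unclass(o), outer(c(a = 0.6, b = 0.4), c(x = 0.5, y = 0.3, z = 0.2)),
               ignore_attr = TRUE)
  expect_error(prob_abundance(c(a = 0, b = 0), c(x = 1)), "zero|sum")
  expect_error(prob_abundance(c(a = 0.9, b = 0.3), c(x = 1)), "sum to one")
})

test_that("morphology model implements trait matching with renormalized indices", {
  traits <- list(
    bats = data.frame(species = bat_names(2), bsi_raw = c(1, 3)),
    plants = data.frame(species = plant_names(2), fsi_raw = c(0.2, 0.9)))
  m <- prob_morphology(traits, bat_names(2), plant_names(2))
  # raw indices min-max to (0,1) each side: cells [[1,0],[0,1]]/2
  expect_equal(unclass(m), matrix(c(0.5, 0, 0, 0.5), 2, 2),
               ignore_attr = TRUE)
  # all indices equal -> uniform matrix (degenerate normalization warns)
  traits_eq <- list(
    bats = data.frame(species = bat_names(2), bsi_raw = c(2, 2)),
    plants = data.frame(species = plant_names(2), fsi_raw = c(5, 5)))
  expect_warning(
    expect_warning(u <- prob_morphology(traits_eq, bat_names(2), plant_names(2)),
                   "degenerate"),
    "degenerate")   # one warning per degenerate side
  expect_equal(unname(unclass(u)), matrix(0.25, 2, 2), ignore_attr = TRUE)
  expect_error(prob_morphology(traits, c("bat1", "batX"), plant_names(2)),
               "batX")
})

test_that("phenology model counts co-occurrence months pooled over sites", {
  bat_occ <- occ_df("bat1", "s1", 1:6, 1)
  plant_occ <- rbind(occ_df("plant1", "s2", 4:9, 2),     # overlap {4,5,6}
                     occ_df("plant2", "s1", 10:12, 1))   # disjoint
  p <- suppressMessages(prob_phenology(bat_occ, plant_occ, "bat1",
                                       c("plant1", "plant2")))
  # raw cells (3, 0) normalized
  expect_equal(unname(unclass(p)[1, ]), c(1, 0))
  # identical year-round presence -> raw cell 12
  full_b <- occ_df("bat1", "s1", 1:12, 1)
  full_p <- rbind(occ_df("plant1", "s1", 1:12, 1), occ_df("plant2", "s1", 1, 1))
  p2 <- prob_phenology(full_b, full_p, "bat1", c("plant1", "plant2"))
  expect_equal(unname(unclass(p2)[1, ] * 13), c(12, 1))
})

test_that("spatial model sums bat captures over the plant's sites", {
  bat_occ <- rbind(occ_df("bat1", "site1", 1, 5), occ_df("bat1", "site2", 2, 2))
  plant_occ <- rbind(occ_df("plant1", "site1", 1, 3),
                     occ_df("plant2", "site1", 1, 1),
                     occ_df("plant2", "site2", 1, 1))
  s <- prob_spatial(bat_occ, plant_occ, "bat1", c("plant1", "plant2"))
  # raw cells (5, 7)
  expect_equal(unname(unclass(s)[1, ]), c(5, 7) / 12)
  # plant present nowhere: zero column (model still normalizes over the rest)
  plant_occ3 <- rbind(plant_occ, occ_df("plant3", "site9", 1, 0))
  expect_message(
    s3 <- prob_spatial(bat_occ, plant_occ3, "bat1", plant_names(3)),
    "zero spatial overlap")
  expect_equal(unname(unclass(s3)[1, 3]), 0)
})

test_that("compound models multiply cellwise and stay normalized", {
  set.seed(81)
  rows <- bat_names(3); cols <- plant_names(4)
  rand_model <- function(label) {
    m <- matrix(runif(12), 3, 4, dimnames = list(rows, cols))
    nectarnet:::new_prob_model(m, label)
  }
  A <- rand_model("A"); P <- rand_model("P"); S <- rand_model("S")
  U <- benchmark_null(rows, cols)
  # uniform factor is the identity element
  expect_equal(unclass(compound_model(U, A)), unclass(A), tolerance = 1e-12,
               ignore_attr = TRUE)
  # zeros propagate
  Z <- unclass(A); Z[1, 1] <- 0
  Az <- nectarnet:::new_prob_model(Z, "A")
  expect_equal(unclass(compound_model(Az, P))[1, 1], 0)
  # associative and commutative to 1e-12, label concatenates
  aps1 <- compound_model(A, P, S)
  aps2 <- compound_model(compound_model(A, P), S)
  expect_equal(unclass(aps1), unclass(aps2), tolerance = 1e-12)
  expect_equal(unclass(compound_model(P, A)), unclass(compound_model(A, P)),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(attr(aps1, "label"), "APS")
  # every constructed model sums to one within 1e-12
  for (mod in list(A, P, S, U, aps1)) expect_equal(sum(mod), 1, tolerance = 1e-12)
  # identically zero product is degenerate
  B1 <- nectarnet:::new_prob_model(matrix(c(1, 0, 0, 0), 2, 2), "A")
  B2 <- nectarnet:::new_prob_model(matrix(c(0, 0, 0, 1), 2, 2), "P")
  expect_error(compound_model(B1, B2), "degenerate")
})

test_that("benchmark null is uniform over cells", {
  expect_equal(unname(unclass(benchmark_null(bat_names(2), plant_names(2)))),
               matrix(0.25, 2, 2), ignore_attr = TRUE)
  expect_equal(as.numeric(benchmark_null("a", "x")), 1)
  expect_equal(sum(benchmark_null(bat_names(5), plant_names(7))), 1)
})

test_that("multinomial kernel matches direct arithmetic", {
  y <- named_matrix(c(2, 0, 0, 2), 2)
  u <- benchmark_null(rownames(y), colnames(y))
  expect_equal(multinomial_loglik(y, u), 4 * log(0.25), tolerance = 1e-9)
  expect_equal(multinomial_loglik(y, u), -5.5452, tolerance = 1e-4)
  # observed event on a zero-probability cell
  z <- nectarnet:::new_prob_model(matrix(c(1, 0, 0, 1), 2, 2,
                                         dimnames = dimnames(y)), "M")
  y2 <- y; y2[1, 2] <- 1
  expect_equal(multinomial_loglik(y2, z), -Inf)
  # the saturated model maximizes the kernel over random competitors
  set.seed(91)
  for (k in 1:20) {
    net <- random_network(3, 4)
    sat <- multinomial_loglik(net, saturated_model(net))
    rnd <- nectarnet:::new_prob_model(
      matrix(runif(12), 3, 4, dimnames = dimnames(net)), "R")
    expect_gte(sat, multinomial_loglik(net, rnd))
  }
  # multinomial coefficient is a constant shift
  expect_equal(multinomial_loglik(y, u, include_coef = TRUE) -
                 multinomial_loglik(y, u),
               lgamma(5) - 2 * lgamma(3))
})

test_that("fit_all ranks twelve models with shared K and sane deltas", {
  cfg <- community_config()
  comm <- suppressWarnings(generate_community(cfg, seed = 101))
  net <- sample_network(comm, seed = 102)
  fits <- fit_all(net, comm$traits, comm$bat_occ, comm$plant_occ,
                  reference = "best")
  expect_setequal(fits$label, c("A", "M", "P", "S", "SP", "AS", "AP", "APS",
                                "MS", "MP", "MPS", "Null"))
  expect_true(all(fits$K == nrow(net) + ncol(net)))
  expect_equal(min(fits$delta_aic), 0)
  fin_aic <- fits$AIC[is.finite(fits$AIC)]
  expect_true(all(diff(fin_aic) >= 0))
  expect_true(all(which(fits$unfittable) > length(fin_aic)))
  expect_true(all(is.infinite(fits$delta_aic[fits$unfittable])))
  # Null closed form: lnL = m ln(1/(r c))
  expect_equal(fits$loglik[fits$label == "Null"],
               sum(net) * log(1 / (nrow(net) * ncol(net))))
  # AIC for finite models
  fin <- is.finite(fits$loglik)
  expect_equal(fits$AIC[fin], -2 * fits$loglik[fin] + 2 * fits$K[fin])
  # saturated reference adds the observed-matrix model and shifts deltas
  sat <- fit_all(net, comm$traits, comm$bat_occ, comm$plant_occ,
                 reference = "saturated")
  expect_true("Saturated" %in% sat$label)
  expect_equal(sat$delta_aic[sat$label == "Saturated"], 0)
  expect_true(all(sat$delta_aic >= 0))
  # ranking is invariant to the multinomial-coefficient flag
  withc <- fit_all(net, comm$traits, comm$bat_occ, comm$plant_occ,
                   reference = "best", include_coef = TRUE)
  expect_identical(withc$label, fits$label)
})
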