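#' Configuration for a synthetic bat-flower community
#'
#' Defaults mirror the scale of a one-year Neotropical savanna study: 13
#' phyllostomid bat species (4 nectarivores, 8 frugivores, 1 insectivore),
#' 25 plant taxa (10 tubular, 10 open-flowered, 5 pseudanthium-forming),
#' 8 sampling sites (4 savanna, 2 forest edge, 2 forest interior), 12
#' monthly campaigns and 302 interaction events sampled multinomially from
#' the generating driver model.
#'
#' Three separation knobs control how much ecological signal the community
#' carries; each runs from 0 (none) to 1 (strong, the default):
#' \describe{
#'   \item{trait_separation}{divergence of guild/flower-class trait means
#'     (nectarivores long-rostrum light-bodied, frugivores the reverse;
#'     tubular flowers long-tubed and narrow). 0 makes all species draw
#'     from one common trait distribution.}
#'   \item{habitat_concentration}{how strongly guilds and flower classes
#'     prefer their habitat (frugivores/pseudanthia in forest, nectarivores
#'     and open flowers in savanna/edge). 0 means uniform site occupancy.}
#'   \item{season_concentration}{how narrow and guild-biased flowering and
#'     activity windows are (dry-season nectarivores and tubular flowers).
#'     0 gives every species a year-round window.}
#' }
#'
#' @param n_nectarivores,n_frugivores,n_insectivores bat species counts.
#' @param n_tubular,n_open,n_pseudanthium plant taxa per flower class.
#' @param n_savanna,n_edge,n_forest sampling sites per habitat.
#' @param n_months months in the phenological year (12).
#' @param m_events total interaction events to sample.
#' @param true_model generating model label: one of A, M, P, S, their
#'   concatenations (e.g. "SP", "MPS"), or "Null".
#' @param abund_sdlog log-normal abundance spread (sigma = 1 reproduces the
#'   strong dominance structure typical of bat assemblages).
#' @param trait_separation,habitat_concentration,season_concentration
#'   signal strengths in \[0, 1\], see Details.
#' @return a `community_config` list.
#' @export
community_config <- function(n_nectarivores = 4L, n_frugivores = 8L,
                             n_insectivores = 1L,
                             n_tubular = 10L, n_open = 10L,
                             n_pseudanthium = 5L,
                             n_savanna = 4L, n_edge = 2L, n_forest = 2L,
                             n_months = 12L, m_events = 302L,
                             true_model = "S", abund_sdlog = 1,
                             trait_separation = 1,
                             habitat_concentration = 1,
                             season_concentration = 1) {
  cfg <- as.list(environment())
  if (n_nectarivores + n_frugivores + n_insectivores < 2L)
    abort_input("at least two bat species are required")
  if (n_tubular + n_open + n_pseudanthium < 2L)
    abort_input("at least two plant taxa are required")
  if (n_savanna + n_edge + n_forest < 1L) abort_input("at least one site")
  if (n_months < 1L) abort_input("at least one month")
  ok_labels <- c("Null", "A", "M", "P", "S", "SP", "AS", "AP", "APS",
                 "MS", "MP", "MPS")
  if (!true_model %in% ok_labels)
    abort_input("unknown true_model label: ", true_model)
  for (k in c("trait_separation", "habitat_concentration",
              "season_concentration"))
    if (cfg[[k]] < 0 || cfg[[k]] > 1)
      abort_input(k, " must lie in [0, 1]")
  class(cfg) <- "community_config"
  cfg
}

# guild-level trait targets (mm, g); the common column is the s = 0 limit
.bat_trait_targets <- list(
  forearm = c(common = 40, nectarivore = 36, frugivore = 45, insectivore = 38),
  mass    = c(common = 20, nectarivore = 10, frugivore = 35, insectivore = 15),
  skull   = c(common = 25, nectarivore = 23, frugivore = 28, insectivore = 24),
  rsr     = c(common = 0.42, nectarivore = 0.52, frugivore = 0.33,
              insectivore = 0.40))

.flower_trait_targets <- list(
  ftl = c(common = 12, tubular = 32, open = 0.1, pseudanthium = 0.1),
  cod = c(common = 30, tubular = 12, open = 40, pseudanthium = 55))

# habitat preference weights per guild / flower class (savanna, edge, forest)
.habitat_prefs <- list(
  nectarivore = c(0.60, 0.35, 0.05), frugivore = c(0.10, 0.30, 0.60),
  insectivore = c(1, 1, 1) / 3,
  tubular = c(0.30, 0.55, 0.15), open = c(0.65, 0.25, 0.10),
  pseudanthium = c(0.05, 0.25, 0.70))

# preferred window centre (month); dry season = months 4-9
.season_centre <- c(nectarivore = 6, frugivore = 11, insectivore = 3,
                    tubular = 6, open = 12, pseudanthium = 7)

# contiguous month window of length len centred on centre, wrapping Dec->Jan
month_window <- function(centre, len, n_months) {
  start <- centre - len %/% 2
  ((start + seq_len(len) - 2) %% n_months) + 1
}

#' Generate a synthetic bat-flower community
#'
#' Draws individual-level bat morphometrics, flower morphometrics, monthly
#' occurrence tables over the sites, species metadata, and the generating
#' interaction-probability model specified by `cfg$true_model` (built with
#' the same probability-matrix constructors used for inference, so the
#' generator inverts the analysis's multinomial assumption). Fully
#' reproducible from `seed`.
#'
#' @param cfg a [community_config()].
#' @param seed integer seed.
#' @return a `synthetic_community` list: `bats`, `flowers` (individual
#'   level), `bat_occ`, `plant_occ`, `guild`, `flower_class`, `traits`
#'   (species-level index table), `prob` (generating model), `config`,
#'   `seed`.
#' @export
generate_community <- function(cfg, seed) {
  stopifnot(inherits(cfg, "community_config"))
  if (missing(seed)) abort_input("a seed is required")
  with_seed(seed, generate_community_impl(cfg))
}

generate_community_impl <- function(cfg) {
  s <- cfg$trait_separation
  h <- cfg$habitat_concentration
  w <- cfg$season_concentration

  guild <- rep(c("nectarivore", "frugivore", "insectivore"),
               c(cfg$n_nectarivores, cfg$n_frugivores, cfg$n_insectivores))
  bat_sp <- sprintf("bat_%02d", seq_along(guild))
  names(guild) <- bat_sp
  fclass <- rep(c("tubular", "open", "pseudanthium"),
                c(cfg$n_tubular, cfg$n_open, cfg$n_pseudanthium))
  plant_sp <- sprintf("plant_%02d", seq_along(fclass))
  names(fclass) <- plant_sp

  habitat <- rep(c("savanna", "edge", "forest"),
                 c(cfg$n_savanna, cfg$n_edge, cfg$n_forest))
  sites <- sprintf("%s_%d", habitat, stats::ave(seq_along(habitat), habitat,
                                                FUN = seq_along))
  names(habitat) <- sites

  mix <- function(targets, group) {
    (1 - s) * targets[["common"]] + s * targets[[group]]
  }

  # --- bat individuals: species means around guild targets, individuals
  # around species means; captures allocated by log-normal abundance
  bat_abund <- stats::rlnorm(length(bat_sp), 0, cfg$abund_sdlog)
  bat_rel <- bat_abund / sum(bat_abund)
  n_ind <- pmax(2L, round(bat_rel * 12 * length(bat_sp)))
  bats <- do.call(rbind, lapply(seq_along(bat_sp), function(i) {
    g <- unname(guild[i])
    fa_mu <- mix(.bat_trait_targets$forearm, g) * stats::rlnorm(1, 0, 0.04)
    ms_mu <- mix(.bat_trait_targets$mass, g) * stats::rlnorm(1, 0, 0.08)
    sk_mu <- mix(.bat_trait_targets$skull, g) * stats::rlnorm(1, 0, 0.04)
    rr_mu <- min(mix(.bat_trait_targets$rsr, g) * stats::rlnorm(1, 0, 0.04), 0.75)
    k <- n_ind[i]
    data.frame(
      species = bat_sp[i],
      individual_id = sprintf("%s_ind%02d", bat_sp[i], seq_len(k)),
      forearm = fa_mu * stats::rlnorm(k, 0, 0.03),
      mass = ms_mu * stats::rlnorm(k, 0, 0.06),
      skull_length = sk_mu * stats::rlnorm(k, 0, 0.02),
      rostrum_ratio = pmin(rr_mu * stats::rlnorm(k, 0, 0.03), 0.9),
      stringsAsFactors = FALSE)
  }))
  bats$rostrum_length <- bats$rostrum_ratio * bats$skull_length
  bats$rostrum_ratio <- NULL

  # --- flower specimens (5-18 per species, as in field morphometrics)
  plant_abund <- stats::rlnorm(length(plant_sp), 0, cfg$abund_sdlog)
  plant_rel <- plant_abund / sum(plant_abund)
  flowers <- do.call(rbind, lapply(seq_along(plant_sp), function(j) {
    cl <- unname(fclass[j])
    ftl_target <- mix(.flower_trait_targets$ftl, cl)
    dummy <- ftl_target <= 0.2      # open flowers / pseudanthia at full separation
    ftl_mu <- max(ftl_target * stats::rlnorm(1, 0, 0.08), 0.1)
    cod_mu <- mix(.flower_trait_targets$cod, cl) * stats::rlnorm(1, 0, 0.08)
    k <- sample(5:18, 1)
    data.frame(
      species = plant_sp[j],
      specimen_id = sprintf("%s_fl%02d", plant_sp[j], seq_len(k)),
      ftl = if (dummy) rep(0.1, k) else ftl_mu * stats::rlnorm(k, 0, 0.06),
      cod = cod_mu * stats::rlnorm(k, 0, 0.06),
      flower_class = cl,
      stringsAsFactors = FALSE)
  }))

  # --- site occupancy and monthly windows
  occupancy <- function(sp_names, group_of, rel) {
    occ <- matrix(FALSE, length(sp_names), length(sites),
                  dimnames = list(sp_names, sites))
    for (i in seq_along(sp_names)) {
      pref <- .habitat_prefs[[group_of[i]]]
      pw <- (1 - h) * rep(1 / 3, 3) + h * pref
      p_site <- pw[match(habitat, c("savanna", "edge", "forest"))]
      p_site <- pmin(p_site * 2.2, 0.95)
      occ[i, ] <- stats::runif(length(sites)) < p_site
      if (!any(occ[i, ]))
        occ[i, sample.int(length(sites), 1, prob = p_site)] <- TRUE
    }
    occ
  }
  windows <- function(sp_names, group_of) {
    lapply(seq_along(sp_names), function(i) {
      if (w == 0) return(seq_len(cfg$n_months))
      len <- sample(3:8, 1)
      len <- round((1 - w) * cfg$n_months + w * len)
      centre <- .season_centre[[group_of[i]]] + sample(-1:1, 1)
      month_window(centre, max(len, 1L), cfg$n_months)
    })
  }

  bat_sites <- occupancy(bat_sp, guild, bat_rel)
  plant_sites <- occupancy(plant_sp, fclass, plant_rel)
  bat_win <- windows(bat_sp, guild)
  plant_win <- windows(plant_sp, fclass)

  # --- monthly occurrence counts: Poisson intensity = species abundance
  # share x habitat suitability, restricted to the activity window
  occurrence <- function(sp_names, occ, win, rel, intensity) {
    rows <- list()
    for (i in seq_along(sp_names)) {
      my_sites <- sites[occ[i, ]]
      months <- win[[i]]
      lam <- rel[i] * intensity / (length(my_sites) * length(months))
      cnt <- stats::rpois(length(my_sites) * length(months), lam)
      if (all(cnt == 0)) cnt[sample.int(length(cnt), 1)] <- 1L
      rows[[i]] <- data.frame(
        species = sp_names[i],
        site = rep(my_sites, times = length(months)),
        month = rep(months, each = length(my_sites)),
        count = cnt, stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    out[out$count > 0, , drop = FALSE]
  }
  bat_occ <- occurrence(bat_sp, bat_sites, bat_win, bat_rel, 170)
  plant_occ <- occurrence(plant_sp, plant_sites, plant_win, plant_rel, 600)

  traits <- suppressWarnings(species_trait_table(bats, flowers))

  prob <- generating_model(cfg$true_model, traits, bat_occ, plant_occ,
                           bat_sp, plant_sp)

  structure(list(bats = bats, flowers = flowers, bat_occ = bat_occ,
                 plant_occ = plant_occ, guild = guild,
                 flower_class = fclass, habitat = habitat, traits = traits,
                 prob = prob, config = cfg),
            class = "synthetic_community")
}

# assemble the generating model from the same constructors inference uses
generating_model <- function(label, traits, bat_occ, plant_occ, rows, cols) {
  if (label == "Null") return(benchmark_null(rows, cols))
  factors <- strsplit(label, "")[[1]]
  build <- function(f) switch(f,
    A = {
      bt <- tapply(bat_occ$count, factor(bat_occ$species, levels = rows),
                   sum, default = 0)
      pt <- tapply(plant_occ$count, factor(plant_occ$species, levels = cols),
                   sum, default = 0)
      prob_abundance(bt / sum(bt), pt / sum(pt))
    },
    M = prob_morphology(traits, rows, cols),
    P = suppressMessages(prob_phenology(bat_occ, plant_occ, rows, cols)),
    S = suppressMessages(prob_spatial(bat_occ, plant_occ, rows, cols)))
  mods <- lapply(factors, build)
  if (length(mods) == 1L) mods[[1]] else {
    out <- compound_model(mods)
    attr(out, "label") <- label
    out
  }
}

#' Sample an interaction network from a synthetic community
#'
#' Draws `m_events` interaction events from the multinomial distribution
#' over the cells of the community's generating probability model; species
#' that receive no events are dropped (the observed matrix never holds
#' all-zero rows or columns).
#'
#' @param comm a [generate_community()] result.
#' @param seed integer seed.
#' @param m_events number of events; defaults to the community config's.
#' @return a bipartite network matrix.
#' @export
sample_network <- function(comm, seed, m_events = NULL) {
  stopifnot(inherits(comm, "synthetic_community"))
  if (missing(seed)) abort_input("a seed is required")
  m <- if (is.null(m_events)) comm$config$m_events else m_events
  if (m < 1) abort_input("m_events must be at least 1")
  p <- unclass(comm$prob)
  net <- with_seed(seed, {
    counts <- stats::rmultinom(1, m, prob = as.vector(p))
    matrix(counts, nrow(p), ncol(p), dimnames = dimnames(p))
  })
  net <- net[rowSums(net) > 0, colSums(net) > 0, drop = FALSE]
  storage.mode(net) <- "double"
  net
}

# factor set of a model label ("Null" is its own factor)
label_factors <- function(label) {
  if (label %in% c("Null", "Saturated")) return(label)
  strsplit(label, "")[[1]]
}

#' Driver-recovery experiment
#'
#' For each replicate: generate a community, sample a network from its
#' generating model, run [fit_all()], and record where the generating model
#' ranks and whether the top-ranked model's factors are a subset of the
#' generating model's (e.g. truth "SP" recovered by "S", "P" or "SP").
#'
#' @param cfg a [community_config()].
#' @param n_reps number of replicates.
#' @param seed integer seed; replicate seeds are derived by counter.
#' @return data.frame with one row per replicate (`rep`, `true_model`,
#'   `best_model`, `rank_true`, `top_factor_subset`, `delta_null`: AIC of
#'   the Null model minus the best AIC); summary fractions are attached as
#'   attribute `"summary"`.
#' @export
recovery_experiment <- function(cfg, n_reps, seed) {
  stopifnot(inherits(cfg, "community_config"), n_reps >= 1L)
  if (missing(seed)) abort_input("a seed is required")
  true_fac <- label_factors(cfg$true_model)
  rows <- lapply(seq_len(n_reps), function(r) {
    s1 <- (as.integer(seed) + r * 2111L) %% 2147483647L
    comm <- generate_community(cfg, seed = s1)
    net <- sample_network(comm, seed = s1 + 1L)
    fits <- fit_all(net, comm$traits, comm$bat_occ, comm$plant_occ,
                    reference = "best")
    rank_true <- match(cfg$true_model, fits$label)
    best <- fits$label[1]
    data.frame(
      rep = r, true_model = cfg$true_model, best_model = best,
      rank_true = rank_true,
      top_factor_subset = all(label_factors(best) %in% true_fac),
      delta_null = fits$AIC[fits$label == "Null"] - fits$AIC[1],
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "summary") <- c(
    top1 = mean(out$rank_true == 1),
    top_factor_subset = mean(out$top_factor_subset),
    null_within_2 = mean(out$delta_null <= 2))
  out
}
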