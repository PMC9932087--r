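#' Body condition index
#'
#' BCI = body mass (g) / forearm length (mm), a mass-per-size proxy of body
#' robustness: higher values indicate larger, heavier bats, which hover less
#' and handle delicate flowers poorly. The definition is exposed as a
#' replaceable callable in [species_trait_table()] so alternative condition
#' indices (e.g. residuals of mass on forearm) can be swapped in.
#'
#' @param mass body mass in grams.
#' @param forearm forearm length in millimetres.
#' @return the index (g/mm), vectorised.
#' @export
bci <- function(mass, forearm) {
  check_positive(mass, "mass")
  check_positive(forearm, "forearm")
  mass / forearm
}

#' Rostrum-skull ratio
#'
#' RSR (written RCR in some figures) = rostrum length / skull length, a proxy
#' of morphological specialisation towards nectar feeding; values approach 1
#' for proportionally very long rostra.
#'
#' @param rostrum rostrum length, mm (anterior eye edge to lower-lip edge).
#' @param skull longest skull length, mm.
#' @return ratio in (0, 1), vectorised.
#' @export
rsr <- function(rostrum, skull) {
  check_positive(rostrum, "rostrum")
  check_positive(skull, "skull")
  if (any(rostrum >= skull))
    abort_input("rostrum length must be smaller than skull length")
  rostrum / skull
}

# min-max normalization to [0,1]; a single value (degenerate range) maps to
# 0.5 with a warning, so downstream matching probabilities stay defined.
minmax <- function(x) {
  r <- range(x)
  if (diff(r) == 0) {
    warning("degenerate min-max normalization (single value); mapping to 0.5")
    return(rep(0.5, length(x)))
  }
  (x - r[1]) / diff(r)
}

#' Species-level specialization indices
#'
#' Computes per-individual raw indices — BSI_raw = RSR/BCI for bats, FSI_raw
#' = FTL/COD for flowers — averages them within species, and min-max
#' normalizes the species means to \[0, 1\] within each side of the network.
#' Non-tubular flowers and pseudanthia carry the conventional dummy floral
#' tube length of 0.1 mm, encoding low restriction.
#'
#' @param bats data.frame with columns `species`, `forearm`, `mass`,
#'   `skull_length`, `rostrum_length` (one row per individual).
#' @param flowers data.frame with columns `species`, `ftl`, `cod` (one row
#'   per specimen; `ftl` already set to 0.1 for open flowers/pseudanthia).
#' @param bci_fun callable computing the condition index from (mass, forearm).
#' @return list with data.frames `bats` (species, bci, rsr, bsi_raw, bsi) and
#'   `plants` (species, ftl, cod, fsi_raw, fsi).
#' @export
species_trait_table <- function(bats, flowers, bci_fun = bci) {
  stopifnot(is.data.frame(bats), is.data.frame(flowers))
  if (any(bats$rostrum_length >= bats$skull_length))
    abort_input("rostrum_length must be below skull_length for every individual")
  b_bci <- bci_fun(bats$mass, bats$forearm)
  b_rsr <- rsr(bats$rostrum_length, bats$skull_length)
  bsi_raw_ind <- b_rsr / b_bci
  bat_tab <- data.frame(
    species = names(tapply(bsi_raw_ind, bats$species, mean)),
    bci = as.numeric(tapply(b_bci, bats$species, mean)),
    rsr = as.numeric(tapply(b_rsr, bats$species, mean)),
    bsi_raw = as.numeric(tapply(bsi_raw_ind, bats$species, mean)),
    stringsAsFactors = FALSE)
  bat_tab$bsi <- minmax(bat_tab$bsi_raw)

  check_positive(flowers$ftl, "ftl")
  check_positive(flowers$cod, "cod")
  fsi_raw_ind <- flowers$ftl / flowers$cod
  pl_tab <- data.frame(
    species = names(tapply(fsi_raw_ind, flowers$species, mean)),
    ftl = as.numeric(tapply(flowers$ftl, flowers$species, mean)),
    cod = as.numeric(tapply(flowers$cod, flowers$species, mean)),
    fsi_raw = as.numeric(tapply(fsi_raw_ind, flowers$species, mean)),
    stringsAsFactors = FALSE)
  pl_tab$fsi <- minmax(pl_tab$fsi_raw)

  list(bats = bat_tab, plants = pl_tab)
}

#' Morphological matching probability
#'
#' P = 1 - |BSI - FSI|: species with matching degrees of specialization
#' (both high or both low) interact with probability near 1, strongly
#' mismatched pairs near 0.
#'
#' @param bsi bat specialization index in \[0, 1\].
#' @param fsi flower specialization index in \[0, 1\].
#' @return probability in \[0, 1\], vectorised.
#' @export
morph_match_prob <- function(bsi, fsi) {
  if (any(bsi < 0 | bsi > 1) || any(fsi < 0 | fsi > 1))
    abort_input("specialization indices must lie in [0, 1]")
  1 - abs(bsi - fsi)
}
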