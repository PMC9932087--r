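# small builders shared across test files

named_matrix <- function(x, nr, byrow = TRUE) {
  m <- matrix(x, nrow = nr, byrow = byrow)
  dimnames(m) <- list(paste0("bat", seq_len(nrow(m))),
                      paste0("plant", seq_len(ncol(m))))
  m
}

random_network <- function(nr, nc, lambda = 1.5) {
  repeat {
    m <- named_matrix(rpois(nr * nc, lambda), nr)
    if (all(rowSums(m) > 0) && all(colSums(m) > 0)) return(m)
  }
}

record_df <- function(bat, ind, pollen, grains, anem = FALSE,
                      site = "s1", month = 1L) {
  data.frame(bat_species = bat, individual_id = ind, pollen_type = pollen,
             grain_count = grains, site = site, month = month,
             anemophilous = anem, stringsAsFactors = FALSE)
}
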