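#' Validate a weighted bipartite interaction matrix
#'
#' The package represents a bat x plant network as a plain numeric matrix with
#' unique row names (bat species) and column names (plant taxa); cell (i, j)
#' holds the number of individuals of bat species i found carrying pollen of
#' taxon j. This helper enforces those invariants and is called by every
#' metric.
#'
#' @param net numeric matrix with unique dimnames, nonnegative integer cells.
#' @param min_dim minimum number of rows and columns required.
#' @param min_total minimum total weight required.
#' @return `net`, invisibly, after validation.
#' @export
validate_network <- function(net, min_dim = 1L, min_total = 1L) {
  if (!is.matrix(net) || !is.numeric(net))
    abort_input("network must be a numeric matrix")
  if (is.null(rownames(net)) || is.null(colnames(net)))
    abort_input("network must have row and column names")
  if (anyDuplicated(rownames(net)) || anyDuplicated(colnames(net)))
    abort_input("network row/column labels must be unique")
  if (any(!is.finite(net)) || any(net < 0))
    abort_input("network cells must be finite and nonnegative")
  if (any(abs(net - round(net)) > 1e-8))
    abort_input("network cells must be integers")
  if (nrow(net) < min_dim || ncol(net) < min_dim)
    abort_input(sprintf("network must have at least %d rows and columns", min_dim))
  if (sum(net) < min_total)
    abort_input("network total weight is below the required minimum")
  invisible(net)
}

#' Filter pollen records for contamination
#'
#' Removes records whose grain count falls at or below the contamination
#' threshold, and all records of wind-pollinated (anemophilous) taxa
#' regardless of grain number, since pollen of such taxa on a bat's fur
#' cannot be read as a visit. Record order is preserved.
#'
#' @param records data.frame with columns `bat_species`, `individual_id`,
#'   `pollen_type`, `grain_count`, `site`, `month` and logical `anemophilous`.
#' @param contamination_threshold integer; records with
#'   `grain_count <= contamination_threshold` are dropped (default 5).
#' @return the filtered data.frame.
#' @export
filter_pollen_records <- function(records, contamination_threshold = 5L) {
  stopifnot(is.data.frame(records))
  need <- c("bat_species", "individual_id", "pollen_type", "grain_count",
            "anemophilous")
  missing <- setdiff(need, names(records))
  if (length(missing))
    abort_input("records lack columns: ", paste(missing, collapse = ", "))
  gc <- records$grain_count
  if (any(is.na(gc)) || any(gc < 0))
    abort_input("grain_count must be present and nonnegative")
  keep <- gc > contamination_threshold & !records$anemophilous
  records[keep, , drop = FALSE]
}

#' Build the weighted adjacency matrix from interaction records
#'
#' Cell (i, j) counts the number of *distinct individuals* of bat species i
#' that carried pollen taxon j: an individual recaptured with the same pollen
#' taxon contributes once to the cell. All-zero rows and columns cannot arise
#' by construction.
#'
#' @param records filtered interaction records (see
#'   [filter_pollen_records()]).
#' @return a named integer matrix (bat species x pollen taxa).
#' @export
build_network <- function(records) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0L)
    abort_input("cannot build a network from an empty record list")
  uniq <- unique(records[, c("bat_species", "individual_id", "pollen_type")])
  net <- table(factor(uniq$bat_species), factor(uniq$pollen_type))
  net <- unclass(net)
  storage.mode(net) <- "double"
  names(dimnames(net)) <- NULL
  validate_network(net)
  net
}

#' Subset a network to a set of bat feeding guilds
#'
#' Retains the rows whose guild is in `guilds`; plant columns whose marginal
#' total drops to zero in the subset are removed. Cell values are unchanged.
#'
#' @param net bipartite network matrix.
#' @param guild named character vector mapping every row label to a guild
#'   (e.g. `"nectarivore"`, `"frugivore"`, `"insectivore"`).
#' @param guilds character vector of guilds to keep.
#' @return the sub-network matrix.
#' @export
subset_guild <- function(net, guild, guilds) {
  validate_network(net)
  unclassified <- setdiff(rownames(net), names(guild))
  if (length(unclassified))
    abort_input("rows without a guild: ", paste(unclassified, collapse = ", "))
  keep <- rownames(net)[guild[rownames(net)] %in% guilds]
  if (!length(keep)) abort_input("guild subset is empty")
  sub <- net[keep, , drop = FALSE]
  sub <- sub[, colSums(sub) > 0, drop = FALSE]
  if (ncol(sub) == 0L) abort_input("guild subset has no interactions")
  sub
}

#' Drop plant columns lacking complete covariates
#'
#' Plant taxa that cannot have all four interaction-probability matrices
#' measured (e.g. pollen types never registered in the study site) are
#' removed before the likelihood analysis. Bat rows whose marginal total
#' drops to zero as a consequence are also removed, with a message, because
#' the metrics are undefined on all-zero rows.
#'
#' @param net bipartite network matrix.
#' @param covariates_complete named logical vector over the plant columns.
#' @return the reduced network.
#' @export
drop_missing_covariates <- function(net, covariates_complete) {
  validate_network(net)
  missing <- setdiff(colnames(net), names(covariates_complete))
  if (length(missing))
    abort_input("columns without a covariate flag: ",
                paste(missing, collapse = ", "))
  keep <- colnames(net)[covariates_complete[colnames(net)]]
  if (!length(keep)) abort_input("all plant columns lack covariates")
  sub <- net[, keep, drop = FALSE]
  zero <- rowSums(sub) == 0
  if (any(zero)) {
    message("dropping bat rows with zero marginal after covariate filter: ",
            paste(rownames(sub)[zero], collapse = ", "))
    sub <- sub[!zero, , drop = FALSE]
  }
  if (nrow(sub) == 0L) abort_input("network empty after covariate filter")
  sub
}

#' Read / write an adjacency matrix as CSV
#'
#' First column holds the row labels, the header the column labels; cells are
#' integers. Write-then-read is the identity.
#'
#' @param path file path.
#' @return `read_network_csv` returns the network matrix.
#' @export
read_network_csv <- function(path) {
  if (!file.exists(path)) abort_input("no such file: ", path)
  df <- tryCatch(
    utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE),
    error = function(e) abort_input("cannot parse ", path, ": ", conditionMessage(e)))
  if (nrow(df) == 0L || ncol(df) < 2L)
    abort_input("network CSV must have at least one row and one data column")
  if (anyDuplicated(colnames(df)))
    abort_input("network CSV column labels must be unique")
  labels <- as.character(df[[1]])
  cells <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(cells) || any(is.na(cells)))
    abort_input("network CSV cells must be numeric")
  if (any(abs(cells - round(cells)) > 1e-8))
    abort_input("network CSV cells must be integers")
  rownames(cells) <- labels
  validate_network(cells)
  cells
}

#' @rdname read_network_csv
#' @param net bipartite network matrix.
#' @export
write_network_csv <- function(net, path) {
  validate_network(net)
  df <- data.frame(species = rownames(net), net, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Cumulative mist-netting effort
#'
#' Multiplies cumulative net area by nightly open hours, the standard
#' square-metre-hour measure of capture effort.
#'
#' @param net_area_m2 cumulative net area in square metres.
#' @param hours hours the nets stayed open.
#' @return effort in m2 h.
#' @export
netting_effort <- function(net_area_m2, hours) {
  check_positive(net_area_m2, "net_area_m2")
  check_positive(hours, "hours")
  net_area_m2 * hours
}
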