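#' Run manifest for machine-readable outputs
#'
#' Collects what a later reader needs to trace a stochastic result: the
#' command name, seed(s), package version, input file digests and a
#' timestamp. Written alongside every CLI output.
#'
#' @param command character name of the command.
#' @param seed integer seed(s) used, or NULL for deterministic commands.
#' @param inputs character vector of input file paths (digested with md5).
#' @return a list suitable for [jsonlite::write_json()].
#' @export
run_manifest <- function(command, seed = NULL, inputs = character()) {
  inputs <- inputs[file.exists(inputs)]
  list(command = command,
       seed = seed,
       package = "nectarnet",
       version = as.character(utils::packageVersion("nectarnet")),
       input_digests = as.list(tools::md5sum(inputs)),
       timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE))
}

#' Export a network as an edge list
#'
#' Long-format edge list (source, target, weight and, when a partition is
#' given, the module of each endpoint) suitable for external graph-drawing
#' tools.
#'
#' @param net bipartite network matrix.
#' @param partition optional [dirtlpawb_plus()] result.
#' @return data.frame with one row per positive cell.
#' @export
edge_list <- function(net, partition = NULL) {
  validate_network(net)
  idx <- which(net > 0, arr.ind = TRUE)
  out <- data.frame(source = rownames(net)[idx[, 1]],
                    target = colnames(net)[idx[, 2]],
                    weight = net[idx], stringsAsFactors = FALSE)
  if (!is.null(partition)) {
    out$source_module <- partition$row_modules[idx[, 1]]
    out$target_module <- partition$col_modules[idx[, 2]]
  }
  out[order(out$source, out$target), , drop = FALSE]
}
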