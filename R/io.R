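#' Network serialization (JSON) and GraphML export
#'
#' The JSON schema stores the three tables of a `trensh_network` (nodes,
#' vessels with cm / dyn s cm^-5 fields, EMFs) plus the nidus metadata and
#' the configuration, and round-trips losslessly (graph isomorphism and
#' exact numeric fields).
#'
#' @param network a `trensh_network`.
#' @param path file path.
#' @return `write_network` returns `path` invisibly; `read_network` returns
#'   the network.
#' @export
write_network <- function(network, path) {
  stopifnot(inherits(network, "trensh_network"))
  nid <- network$nidus
  payload <- list(
    format = "trensh-network",
    version = 1L,
    nodes = network$nodes,
    vessels = network$vessels,
    emfs = network$emfs,
    nidus = if (!is.null(nid)) list(
      n_compartments = nid$n_compartments,
      n_columns = nid$n_columns,
      middle_compartment = nid$middle_compartment,
      counts = as.vector(nid$counts),
      nodes = nid$nodes,
      vessels = nid$vessels,
      pedicles = nid$pedicles,
      boundary_attachments = nid$boundary_attachments,
      fistula_path = nid$fistula_path,
      seed = nid$seed
    ),
    config = if (!is.null(network$config)) config_payload(network$config)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       dataframe = "columns", na = "null")
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  raw <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) {
                    stop(sprintf("parse error reading '%s': %s", path,
                                 conditionMessage(e)), call. = FALSE)
                  })
  if (!identical(raw$format, "trensh-network")) {
    stop("parse error: field 'format' is not 'trensh-network'", call. = FALSE)
  }
  for (f in c("nodes", "vessels", "emfs")) {
    if (is.null(raw[[f]]) || !is.list(raw[[f]])) {
      stop(sprintf("parse error: missing field '%s'", f), call. = FALSE)
    }
  }
  as_df <- function(x) as.data.frame(x, stringsAsFactors = FALSE)
  nodes <- as_df(raw$nodes)
  vessels <- as_df(raw$vessels)
  if (any(!is.finite(vessels$radius_cm)) || any(vessels$radius_cm <= 0)) {
    bad <- vessels$id[!is.finite(vessels$radius_cm) | vessels$radius_cm <= 0]
    stop(sprintf("validation error: non-positive radius in vessel(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  nodes$compartment <- as.integer(nodes$compartment)
  nodes$column <- as.integer(nodes$column)
  vessels$compartment <- as.integer(vessels$compartment)
  vessels$column <- as.integer(vessels$column)
  nid <- NULL
  if (!is.null(raw$nidus)) {
    r <- raw$nidus
    nid_nodes <- as_df(r$nodes)
    nid_nodes$compartment <- as.integer(nid_nodes$compartment)
    nid_nodes$column <- as.integer(nid_nodes$column)
    nid_vessels <- as_df(r$vessels)
    nid_vessels$compartment <- as.integer(nid_vessels$compartment)
    nid_vessels$column <- as.integer(nid_vessels$column)
    ped <- as_df(r$pedicles)
    ped$compartment <- as.integer(ped$compartment)
    ped$column <- as.integer(ped$column)
    nid <- structure(list(
      n_compartments = as.integer(r$n_compartments),
      n_columns = as.integer(r$n_columns),
      middle_compartment = as.integer(r$middle_compartment),
      counts = matrix(as.integer(r$counts), nrow = r$n_compartments),
      nodes = nid_nodes, vessels = nid_vessels, pedicles = ped,
      boundary_attachments = as_df(r$boundary_attachments),
      fistula_path = unlist(r$fistula_path),
      seed = as.integer(r$seed)
    ), class = "trensh_nidus")
  }
  cfg <- if (!is.null(raw$config)) config_from_payload(raw$config)
  net <- new_network(nodes, vessels, as_df(raw$emfs), nidus = nid, config = cfg)
  validate_network(net)
  net
}

#' @rdname write_network
#' @export
write_network_graphml <- function(network, path) {
  igraph::write_graph(network_igraph(network), path, format = "graphml")
  invisible(path)
}

#' Export flow solutions as tidy CSV
#'
#' One row per vessel and pressure set, with units in the column headers.
#'
#' @param solutions list of `trensh_flow` (or a single one).
#' @param network the solved network.
#' @param path CSV path for the per-vessel table.
#' @param node_path optional CSV path for per-node pressures.
#' @return `path` invisibly.
#' @export
write_results_csv <- function(solutions, network, path, node_path = NULL) {
  if (inherits(solutions, "trensh_flow")) solutions <- list(solutions)
  rows <- lapply(solutions, function(s) {
    data.frame(
      pressure_set = s$pressure_set$id,
      vessel_id = s$vessel_id,
      category = network$vessels$category,
      `flow_mL_min` = flow_to_ml_min(s$flow_cm3s),
      `dp_mmHg` = s$dp_mmHg,
      check.names = FALSE, stringsAsFactors = FALSE
    )
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  if (!is.null(node_path)) {
    nrows <- lapply(solutions, function(s) {
      data.frame(pressure_set = s$pressure_set$id, node_id = s$node_id,
                 pressure_mmHg = s$node_pressure_mmHg,
                 stringsAsFactors = FALSE)
    })
    utils::write.csv(do.call(rbind, nrows), node_path, row.names = FALSE)
  }
  invisible(path)
}

#' Run manifest
#'
#' Records everything needed to reproduce a run byte-for-byte with the same
#' code version: the configuration snapshot, master seed, grid identifier,
#' output paths, package version and timings.
#'
#' @param seed master seed.
#' @param grid_id free-text grid identifier.
#' @param outputs named list/vector of output paths.
#' @param config the configuration used.
#' @param timings optional named numeric vector of per-stage seconds.
#' @param path where to write the manifest JSON.
#' @return the manifest list, invisibly.
#' @export
write_manifest <- function(seed, grid_id, outputs, config, timings = NULL,
                           path) {
  manifest <- list(
    tool = "trensh",
    version = as.character(utils::packageVersion("trensh")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    master_seed = as.integer(seed),
    grid = grid_id,
    outputs = as.list(outputs),
    timings_s = as.list(timings),
    config = config_payload(config)
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = I(17))
  invisible(manifest)
}
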