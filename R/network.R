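#' Vessel networks
#'
#' A `trensh_network` is a directed multigraph of vessels. It holds three
#' tables:
#' \describe{
#'   \item{nodes}{`id`, `role` (junction, AF-terminal, DV-terminal,
#'     source-terminal), layout coordinates `x`, `y`, and for intranidal
#'     nodes integer `compartment` and `column`.}
#'   \item{vessels}{`id`, `tail`, `head`, `class`, `length_cm`, `radius_cm`,
#'     precomputed `resistance` (dyn s cm^-5), `category` (one of
#'     extranidal-artery, AF, intranidal-plexiform, intranidal-fistula, DV,
#'     extranidal-vein), and for intranidal vessels `compartment`/`column`.}
#'   \item{emfs}{the nine electromotive forces: `id` (ESP, EAF1-EAF4,
#'     EDV1-EDV3, ECVP), the vessel each is attached to, its `kind`
#'     (`boundary` for the two pressure-reference sources ESP/ECVP, `series`
#'     otherwise), the boundary `node` it pins for boundary sources, and
#'     `orientation` (+1 drives flow tail-to-head, -1 retrograde; the DV
#'     EMFs are retrograde so that a positive value models a transvenous
#'     injection pushing back into the nidus).}
#' }
#'
#' Nominal edge orientation is arterial-to-venous; solved flows are signed
#' and may be negative (reversed), which is how retrograde injection is
#' expressed.
#'
#' @name trensh_network
NULL

INTRANIDAL_CATEGORIES <- c("intranidal-plexiform", "intranidal-fistula")

new_network <- function(nodes, vessels, emfs, nidus = NULL, config = NULL) {
  structure(list(nodes = nodes, vessels = vessels, emfs = emfs,
                 nidus = nidus, config = config),
            class = "trensh_network")
}

#' Build the fixed extranidal template
#'
#' Constructs the extranidal arterial and venous architecture to which a
#' generated nidus is attached: aortic arch, carotid / subclavian /
#' vertebral trunks, cerebral arteries, a transosseous feeder, four arterial
#' feeders (AF1, AF2 major with low resistance; AF3, AF4 minor with high
#' resistance), three draining veins, dural sinus and vena cava, and the
#' nine EMF pressure sources (ESP for the systemic pressure, one per AF, one
#' per DV, and ECVP for the central venous pressure).
#'
#' @param config a [sim_config()].
#' @return a `trensh_network` with no nidus attached: 4 AF terminals, 3 DV
#'   terminals, 9 EMFs, every vessel with precomputed resistance.
#' @export
build_extranidal_template <- function(config = sim_config()) {
  stopifnot(inherits(config, "trensh_config"))
  nodes <- data.frame(
    id   = c("sys_root", "n_arch", "n_cca", "n_sca", "n_ica", "n_eca",
             "n_va", "n_mca", "n_aca", "n_pca", "n_tfa",
             "AF1", "AF2", "AF3", "AF4",
             "DV1", "DV2", "DV3", "n_sinus", "n_svc", "cvp_terminal"),
    role = c("source-terminal", rep("junction", 10),
             rep("AF-terminal", 4), rep("DV-terminal", 3),
             "junction", "junction", "source-terminal"),
    x = c(-6, -5, -4, -4, -3, -3, -3, -1.5, -1.5, -1.5, -1.5,
          0, 0, 0, 0, 8, 8, 8, 9.5, 10.5, 12),
    y = c(0.5, 0.5, 0.30, 0.70, 0.20, 0.42, 0.70, 0.10, 0.35, 0.62, 0.88,
          0.125, 0.375, 0.625, 0.875,
          1 / 6, 3 / 6, 5 / 6, 0.5, 0.5, 0.5),
    compartment = NA_integer_, column = NA_integer_,
    stringsAsFactors = FALSE
  )

  edge <- function(id, tail, head, class) {
    d <- dims_for(config, class)
    cat_ <- config$vessel_dimensions$category[
      match(class, config$vessel_dimensions$class)]
    data.frame(id = id, tail = tail, head = head, class = class,
               length_cm = d$length, radius_cm = d$radius,
               resistance = vessel_resistance(d$length, d$radius, config$viscosity),
               category = cat_, compartment = NA_integer_, column = NA_integer_,
               kind = "extranidal", stringsAsFactors = FALSE)
  }
  vessels <- rbind(
    edge("aa",  "sys_root", "n_arch",  "aortic_arch"),
    edge("cca", "n_arch",   "n_cca",   "common_carotid"),
    edge("sca", "n_arch",   "n_sca",   "subclavian"),
    edge("ica", "n_cca",    "n_ica",   "internal_carotid"),
    edge("eca", "n_cca",    "n_eca",   "external_carotid"),
    edge("va",  "n_sca",    "n_va",    "vertebral"),
    edge("mca", "n_ica",    "n_mca",   "middle_cerebral"),
    edge("aca", "n_ica",    "n_aca",   "anterior_cerebral"),
    edge("pca", "n_va",     "n_pca",   "posterior_cerebral"),
    edge("tfa", "n_eca",    "n_tfa",   "transosseous_feeder"),
    edge("af1", "n_mca",    "AF1",     "af1"),
    edge("af2", "n_aca",    "AF2",     "af2"),
    edge("af3", "n_pca",    "AF3",     "af3"),
    edge("af4", "n_tfa",    "AF4",     "af4"),
    edge("dv1", "DV1",      "n_sinus", "dv1"),
    edge("dv2", "DV2",      "n_sinus", "dv2"),
    edge("dv3", "DV3",      "n_sinus", "dv3"),
    edge("dvs", "n_sinus",  "n_svc",   "dural_sinus"),
    edge("svc", "n_svc",    "cvp_terminal", "vena_cava")
  )

  # AF1/AF2 must be the low-resistance (major) feeders.
  r_af <- vessels$resistance[match(c("af1", "af2", "af3", "af4"), vessels$id)]
  if (!(max(r_af[1:2]) < min(r_af[3:4]))) {
    stop("configuration error: AF1/AF2 must have lower resistance than AF3/AF4",
         call. = FALSE)
  }

  emfs <- data.frame(
    id = c("ESP", "EAF1", "EAF2", "EAF3", "EAF4", "EDV1", "EDV2", "EDV3", "ECVP"),
    attached_edge = c("aa", "af1", "af2", "af3", "af4", "dv1", "dv2", "dv3", "svc"),
    kind = c("boundary", rep("series", 7), "boundary"),
    node = c("sys_root", rep(NA_character_, 7), "cvp_terminal"),
    orientation = c(1, 1, 1, 1, 1, -1, -1, -1, 1),
    stringsAsFactors = FALSE
  )
  new_network(nodes, vessels, emfs, nidus = NULL, config = config)
}

#' Attach a generated nidus to the extranidal template
#'
#' Merges the intranidal node and vessel tables and the boundary pedicles of
#' a sampled architecture into the template and validates the result: the
#' graph must be connected and every intranidal node must be reachable from
#' at least one AF terminal and reach at least one DV terminal (ignoring
#' flow signs).
#'
#' @param template a template from [build_extranidal_template()].
#' @param nidus a [sample_architecture()] result.
#' @return a connected `trensh_network` with `nidus` metadata attached.
#' @export
attach_nidus <- function(template, nidus) {
  stopifnot(inherits(template, "trensh_network"), inherits(nidus, "trensh_nidus"))
  if (!is.null(template$nidus)) stop("template already has a nidus attached", call. = FALSE)

  terminals <- c(nidus$boundary_attachments$terminal)
  known <- template$nodes$id[template$nodes$role %in% c("AF-terminal", "DV-terminal")]
  if (!all(terminals %in% known)) {
    stop(sprintf("topology error: attachment references unknown terminal(s): %s",
                 paste(setdiff(terminals, known), collapse = ", ")), call. = FALSE)
  }

  nodes <- template$nodes
  # Draining veins sit one layout column beyond the last nidus column.
  dvx <- nidus$n_columns + 1
  nodes$x[nodes$role == "DV-terminal"] <- dvx
  nodes$x[nodes$id == "n_sinus"] <- dvx + 1.5
  nodes$x[nodes$id == "n_svc"] <- dvx + 2.5
  nodes$x[nodes$id == "cvp_terminal"] <- dvx + 4

  nodes <- rbind(nodes, nidus$nodes)
  vessels <- rbind(template$vessels, nidus$vessels, nidus$pedicles)
  if (anyDuplicated(nodes$id)) stop("duplicate node ids", call. = FALSE)
  if (anyDuplicated(vessels$id)) stop("duplicate vessel ids", call. = FALSE)
  missing_ep <- setdiff(unique(c(vessels$tail, vessels$head)), nodes$id)
  if (length(missing_ep)) {
    stop(sprintf("topology error: dangling attachment to missing node(s): %s",
                 paste(missing_ep, collapse = ", ")), call. = FALSE)
  }
  net <- new_network(nodes, vessels, emfs = template$emfs, nidus = nidus,
                     config = template$config)
  validate_network(net)
  net
}

#' Validate a vessel network
#'
#' Checks the structural invariants: positive geometry, resistances equal to
#' the Hagen-Poiseuille value, nine EMFs, connectivity when a nidus is
#' attached, AF/DV terminal counts, and that every intranidal node lies on
#' an (undirected) AF-to-DV route.
#'
#' @param network a `trensh_network`.
#' @return the network, invisibly; errors describe the violated invariant.
#' @export
validate_network <- function(network) {
  stopifnot(inherits(network, "trensh_network"))
  v <- network$vessels
  if (any(v$length_cm <= 0) || any(v$radius_cm <= 0)) {
    bad <- v$id[v$length_cm <= 0 | v$radius_cm <= 0]
    stop(sprintf("validation error: non-positive geometry in vessel(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  mu <- if (!is.null(network$config)) network$config$viscosity else 0.035
  expect_r <- vessel_resistance(v$length_cm, v$radius_cm, mu)
  if (any(abs(v$resistance - expect_r) > 1e-12 * expect_r)) {
    stop("validation error: stored resistance disagrees with 8*L*mu/(pi*r^4)",
         call. = FALSE)
  }
  if (nrow(network$emfs) != 9L) {
    stop("validation error: a complete network carries exactly nine EMFs", call. = FALSE)
  }
  n_af <- sum(network$nodes$role == "AF-terminal")
  n_dv <- sum(network$nodes$role == "DV-terminal")
  if (n_af != 4L || n_dv != 3L) {
    stop("validation error: expected 4 AF terminals and 3 DV terminals", call. = FALSE)
  }
  intra <- v$category %in% INTRANIDAL_CATEGORIES
  if (any(intra & (is.na(v$compartment) | is.na(v$column)))) {
    stop("validation error: intranidal vessels must carry compartment/column",
         call. = FALSE)
  }
  if (any(!intra & (!is.na(v$compartment) | !is.na(v$column)))) {
    stop("validation error: only intranidal vessels carry compartment/column",
         call. = FALSE)
  }
  if (!is.null(network$nidus)) {
    g <- network_igraph(network)
    if (!igraph::is_connected(g, mode = "weak")) {
      comp <- igraph::components(g, mode = "weak")
      stop(sprintf("validation error: network is disconnected (%d components)",
                   comp$no), call. = FALSE)
    }
    # every intranidal node on an AF -> DV route, ignoring flow signs
    und <- igraph::as_undirected(g)
    af <- which(igraph::V(und)$role == "AF-terminal")
    dv <- which(igraph::V(und)$role == "DV-terminal")
    intra_n <- which(!is.na(igraph::V(und)$compartment))
    d_af <- suppressWarnings(igraph::distances(und, v = af, to = intra_n))
    d_dv <- suppressWarnings(igraph::distances(und, v = dv, to = intra_n))
    if (any(!is.finite(apply(d_af, 2, min))) || any(!is.finite(apply(d_dv, 2, min)))) {
      stop("validation error: intranidal node not on an AF-DV route", call. = FALSE)
    }
  }
  invisible(network)
}

#' Convert a network to an igraph object
#'
#' @param network a `trensh_network`.
#' @return a directed `igraph` graph whose vertices carry the node metadata
#'   and whose edges carry the vessel metadata.
#' @export
network_igraph <- function(network) {
  igraph::graph_from_data_frame(
    d = data.frame(from = network$vessels$tail, to = network$vessels$head,
                   network$vessels[setdiff(names(network$vessels), c("tail", "head"))],
                   stringsAsFactors = FALSE),
    directed = TRUE,
    vertices = network$nodes
  )
}

#' @export
print.trensh_network <- function(x, ...) {
  cat("<trensh_network>\n")
  cat(sprintf("  nodes: %d, vessels: %d, EMFs: %d\n",
              nrow(x$nodes), nrow(x$vessels), nrow(x$emfs)))
  if (!is.null(x$nidus)) {
    cat(sprintf("  nidus: %d compartments x %d columns, %d intranidal vessels (seed %s)\n",
                x$nidus$n_compartments, x$nidus$n_columns,
                nrow(x$nidus$vessels), format(x$nidus$seed)))
  } else {
    cat("  nidus: none (template)\n")
  }
  invisible(x)
}

# Vessel ids of the intranidal (plexiform + fistula) set.
intranidal_vessel_ids <- function(network) {
  network$vessels$id[network$vessels$category %in% INTRANIDAL_CATEGORIES]
}
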