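#' Simulation configuration
#'
#' Bundles every tunable quantity of the model: blood viscosity, the vessel
#' dimension table, the electromotive-force (EMF) values that encode the
#' physiological scenarios, the rupture-risk normalization constants, the
#' nidus generator settings, and the cardiac-phase pressure offsets.
#'
#' The default vessel dimension table is a calibrated stand-in for the
#' dimensions used by the prior lumped-parameter AVM circuit models this
#' model descends from: the extranidal tree and nidus dimensions were fixed
#' so that the baseline operating point of the network reproduces the
#' published physiology of the model family (mean systemic pressure 74 mmHg,
#' arterial-feeder nidal-entry pressures near 47 mmHg, draining-vein exit
#' pressures near 17 mmHg, CVP 6 mmHg, and a mean total nidal flow of
#' roughly 367 mL/min). Every entry can be overridden.
#'
#' @param viscosity blood (and sclerosant) dynamic viscosity in poise;
#'   default 0.035 (3.5 cP).
#' @param vessel_dimensions data frame with columns `class`, `length_cm`,
#'   `radius_cm`; must contain every class listed in
#'   [default_vessel_table()].
#' @param hypotension_mmHg named numeric vector mapping the systemic
#'   hypotension levels to mean systemic arterial pressure in mmHg.
#' @param cvp_mmHg named numeric vector mapping CVP levels to mmHg.
#' @param injection_pressures_mmHg retrograde injection pressures of the
#'   standard grid, mmHg.
#' @param phase_offset_frac fractional shift of the arterial-side EMFs in
#'   diastole (-) and systole (+); the intermediate/mid-cycle phase is the
#'   mean (zero offset).
#' @param emf_af_base_mmHg baseline value of each per-feeder EMF (EAF1-4),
#'   mmHg, oriented toward the nidus: the regional arterial drive that does
#'   not scale with controlled systemic hypotension.
#' @param emf_dv_base_mmHg baseline value of each per-vein EMF (EDV1-3),
#'   mmHg, oriented retrograde (toward the nidus): the downstream venous-bed
#'   pressure each draining vein empties against; a retrograde injection
#'   adds its pressure on top of this value at the injected vein only.
#' @param risk list with `p_min` and `p_max` (mmHg) for the rupture-risk
#'   normalization, and `pexp` choosing how a vessel's exposure pressure is
#'   measured: `"drop"` (longitudinal pressure difference R_v * Q, the
#'   default), `"mean"` (mean of endpoint node pressures) or `"entry"`
#'   (flow-entry node pressure).
#' @param nidus list of generator settings; see Details.
#'
#' @details The `nidus` list understands:
#' \describe{
#'   \item{compartments}{`c(mean, sd, low, high)` of the truncated-normal
#'     integer draw for the compartment count (default 4.5, 1, 3, 6).}
#'   \item{columns}{same for the column count (default 5, 1, 3, 7).}
#'   \item{nodes_end, nodes_interior}{inclusive integer ranges for the
#'     per-compartment node count of the end columns (default 30-34) and the
#'     interior columns (default 36-40).}
#'   \item{intercompartmental_sd}{sd of the end-column draw of
#'     intercompartmental vessels (default 2).}
#' }
#'
#' @return an object of class `trensh_config`.
#' @export
sim_config <- function(viscosity = 0.035,
                       vessel_dimensions = default_vessel_table(),
                       hypotension_mmHg = c(normo = 74, mild = 70,
                                            moderate = 50, profound = 25),
                       cvp_mmHg = c(normal = 6, high = 12),
                       injection_pressures_mmHg = c(10, 20, 30),
                       phase_offset_frac = 0.10,
                       emf_af_base_mmHg = 5,
                       emf_dv_base_mmHg = 5,
                       risk = list(p_min = 4, p_max = 74, pexp = "drop"),
                       nidus = list()) {
  if (!is.numeric(viscosity) || length(viscosity) != 1L || viscosity <= 0) {
    stop("viscosity must be a single positive number (poise)", call. = FALSE)
  }
  stopifnot(is.data.frame(vessel_dimensions),
            all(c("class", "length_cm", "radius_cm") %in% names(vessel_dimensions)))
  if (anyDuplicated(vessel_dimensions$class)) {
    stop("duplicate vessel class in dimension table", call. = FALSE)
  }
  nd <- utils::modifyList(list(
    compartments = c(mean = 4.5, sd = 1, low = 3, high = 6),
    columns      = c(mean = 5,   sd = 1, low = 3, high = 7),
    nodes_end      = c(30L, 34L),
    nodes_interior = c(36L, 40L),
    intercompartmental_sd = 2
  ), nidus)
  risk <- utils::modifyList(list(p_min = 4, p_max = 74, pexp = "drop"), risk)
  if (!(risk$p_min > 0 && risk$p_min < risk$p_max)) {
    stop("risk parameters require 0 < p_min < p_max", call. = FALSE)
  }
  risk$pexp <- match.arg(risk$pexp, c("drop", "mean", "entry"))
  structure(list(
    viscosity = viscosity,
    vessel_dimensions = vessel_dimensions,
    hypotension_mmHg = hypotension_mmHg,
    cvp_mmHg = cvp_mmHg,
    injection_pressures_mmHg = injection_pressures_mmHg,
    phase_offset_frac = phase_offset_frac,
    emf_af_base_mmHg = emf_af_base_mmHg,
    emf_dv_base_mmHg = emf_dv_base_mmHg,
    risk = risk,
    nidus = nd
  ), class = "trensh_config")
}

#' Default vessel dimension table
#'
#' Lengths and radii (cm) for every vessel class of the model: the fixed
#' extranidal arterial tree (aortic arch through the cerebral arteries and a
#' transosseous feeder), the four arterial feeders AF1-AF4 (AF1 and AF2 major
#' / low resistance, AF3 and AF4 minor / high resistance), the short
#' arteriolar and venular pedicles that attach the nidus boundary rows to
#' the feeders and draining veins, the intranidal plexiform microvessels and
#' the larger-radius intranidal fistula, the three draining veins DV1-DV3,
#' and the extranidal venous outflow (dural sinus, vena cava).
#'
#' @return data frame with columns `class`, `length_cm`, `radius_cm`,
#'   `category`.
#' @export
default_vessel_table <- function() {
  tab <- rbind(
    data.frame(class = "aortic_arch",         length_cm = 7.5,  radius_cm = 1.1906,  category = "extranidal-artery"),
    data.frame(class = "common_carotid",      length_cm = 15,   radius_cm = 0.3810,  category = "extranidal-artery"),
    data.frame(class = "subclavian",          length_cm = 10,   radius_cm = 0.3810,  category = "extranidal-artery"),
    data.frame(class = "internal_carotid",    length_cm = 15,   radius_cm = 0.2381,  category = "extranidal-artery"),
    data.frame(class = "external_carotid",    length_cm = 10,   radius_cm = 0.1429,  category = "extranidal-artery"),
    data.frame(class = "vertebral",           length_cm = 15,   radius_cm = 0.1429,  category = "extranidal-artery"),
    data.frame(class = "posterior_cerebral",  length_cm = 8,    radius_cm = 0.0952,  category = "extranidal-artery"),
    data.frame(class = "anterior_cerebral",   length_cm = 5,    radius_cm = 0.1429,  category = "extranidal-artery"),
    data.frame(class = "middle_cerebral",     length_cm = 5,    radius_cm = 0.1905,  category = "extranidal-artery"),
    data.frame(class = "transosseous_feeder", length_cm = 5,    radius_cm = 0.0476,  category = "extranidal-artery"),
    data.frame(class = "af1",                 length_cm = 3,    radius_cm = 0.1048,  category = "AF"),
    data.frame(class = "af2",                 length_cm = 3,    radius_cm = 0.1714,  category = "AF"),
    data.frame(class = "af3",                 length_cm = 4,    radius_cm = 0.0476,  category = "AF"),
    data.frame(class = "af4",                 length_cm = 4,    radius_cm = 0.0381,  category = "AF"),
    data.frame(class = "af_pedicle",          length_cm = 0.2,  radius_cm = 0.0181,  category = "AF"),
    data.frame(class = "plexiform",           length_cm = 0.1,  radius_cm = 0.01552, category = "intranidal-plexiform"),
    data.frame(class = "fistula",             length_cm = 0.3,  radius_cm = 0.0476,  category = "intranidal-fistula"),
    data.frame(class = "dv_pedicle",          length_cm = 0.2,  radius_cm = 0.01714, category = "DV"),
    data.frame(class = "dv1",                 length_cm = 5,    radius_cm = 0.05715, category = "DV"),
    data.frame(class = "dv2",                 length_cm = 5,    radius_cm = 0.08763, category = "DV"),
    data.frame(class = "dv3",                 length_cm = 5,    radius_cm = 0.05905, category = "DV"),
    data.frame(class = "dural_sinus",         length_cm = 10,   radius_cm = 0.3333,  category = "extranidal-vein"),
    data.frame(class = "vena_cava",           length_cm = 20,   radius_cm = 0.4762,  category = "extranidal-vein")
  )
  rownames(tab) <- NULL
  tab
}

# Look up (length, radius) for one vessel class; errors name the class.
dims_for <- function(config, class) {
  i <- match(class, config$vessel_dimensions$class)
  if (is.na(i)) {
    stop(sprintf("configuration error: no dimensions for vessel class '%s'", class),
         call. = FALSE)
  }
  list(length = config$vessel_dimensions$length_cm[i],
       radius = config$vessel_dimensions$radius_cm[i])
}

#' @export
print.trensh_config <- function(x, ...) {
  cat("<trensh_config>\n")
  cat(sprintf("  viscosity: %g poise\n", x$viscosity))
  cat(sprintf("  vessel classes: %d\n", nrow(x$vessel_dimensions)))
  cat(sprintf("  hypotension (mmHg): %s\n",
              paste(sprintf("%s=%g", names(x$hypotension_mmHg), x$hypotension_mmHg),
                    collapse = ", ")))
  cat(sprintf("  CVP (mmHg): %s\n",
              paste(sprintf("%s=%g", names(x$cvp_mmHg), x$cvp_mmHg), collapse = ", ")))
  cat(sprintf("  risk: p_min=%g, p_max=%g mmHg, pexp=%s\n",
              x$risk$p_min, x$risk$p_max, x$risk$pexp))
  invisible(x)
}

#' Read / write a configuration as JSON
#'
#' @param path file path.
#' @param config a `trensh_config`.
#' @return `read_config` returns a `trensh_config`; `write_config` returns
#'   `path` invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "trensh_config"))
  jsonlite::write_json(config_payload(config), path, auto_unbox = TRUE,
                       digits = I(17), dataframe = "rows")
  invisible(path)
}

# jsonlite drops names on named atomic vectors; convert them to objects
config_payload <- function(config) {
  p <- unclass(config)
  p$hypotension_mmHg <- as.list(p$hypotension_mmHg)
  p$cvp_mmHg <- as.list(p$cvp_mmHg)
  p$nidus <- lapply(p$nidus, as.list)
  p
}

config_from_payload <- function(rc) {
  sim_config(
    viscosity = rc$viscosity,
    vessel_dimensions = as.data.frame(rc$vessel_dimensions,
                                      stringsAsFactors = FALSE),
    hypotension_mmHg = unlist(rc$hypotension_mmHg),
    cvp_mmHg = unlist(rc$cvp_mmHg),
    injection_pressures_mmHg = unlist(rc$injection_pressures_mmHg),
    phase_offset_frac = rc$phase_offset_frac,
    emf_af_base_mmHg = unlist(rc$emf_af_base_mmHg),
    emf_dv_base_mmHg = unlist(rc$emf_dv_base_mmHg),
    risk = rc$risk,
    nidus = lapply(rc$nidus, unlist)
  )
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  config_from_payload(jsonlite::read_json(path, simplifyVector = TRUE))
}
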