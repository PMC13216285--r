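#' Pressure sets
#'
#' A pressure set is one physiological scenario: values for the nine EMFs
#' plus the metadata that generated them. Systemic hypotension changes the
#' systemic EMF (normotension 74 mmHg; mild / moderate / profound
#' hypotension 70 / 50 / 25 mmHg), CVP elevation changes ECVP (normal 6,
#' high 12 mmHg), a retrograde injection adds its pressure to the EMF of the
#' injected draining vein only, and the cardiac phase shifts the
#' arterial-side EMFs by the configured fractional offset (diastole down,
#' systole up; the intermediate / mid-cycle phase is the mean and has zero
#' offset). Temporary balloon occlusion (TBO) is pure topology metadata --
#' the occluded feeder's trunk edge is removed from the graph -- and never
#' an EMF modification.
#'
#' @param hypotension one of `"normo"`, `"mild"`, `"moderate"`, `"profound"`.
#' @param cvp `"normal"` or `"high"`.
#' @param tbo `"none"`, `"AF1"`, `"AF2"` or `"AF3"` (AF4 is never occluded).
#' @param injection `NULL`, or `list(site = "DV1"|"DV2"|"DV3",
#'   pressure_mmHg = <value >= 0>)`.
#' @param phase `"intermediate"`, `"diastole"` or `"systole"`.
#' @param config a [sim_config()].
#' @return an object of class `trensh_pressure_set`: the named `emf_mmHg`
#'   vector (ESP, EAF1-4, EDV1-3, ECVP) plus the scenario metadata.
#' @export
pressure_set <- function(hypotension = "normo", cvp = "normal", tbo = "none",
                         injection = NULL, phase = "intermediate",
                         config = sim_config()) {
  hypotension <- match.arg(hypotension, names(config$hypotension_mmHg))
  cvp <- match.arg(cvp, names(config$cvp_mmHg))
  tbo <- match.arg(tbo, c("none", "AF1", "AF2", "AF3"))
  phase <- match.arg(phase, c("intermediate", "diastole", "systole"))
  if (is.null(config$phase_offset_frac)) {
    stop("configuration error: no cardiac-phase offsets configured", call. = FALSE)
  }
  fac <- switch(phase,
                intermediate = 1,
                diastole = 1 - config$phase_offset_frac,
                systole = 1 + config$phase_offset_frac)
  af_base <- rep_len(config$emf_af_base_mmHg %||% 0, 4)
  dv_base <- rep_len(config$emf_dv_base_mmHg %||% 0, 3)
  emf <- c(ESP = unname(config$hypotension_mmHg[hypotension]) * fac,
           EAF1 = af_base[1] * fac, EAF2 = af_base[2] * fac,
           EAF3 = af_base[3] * fac, EAF4 = af_base[4] * fac,
           EDV1 = dv_base[1], EDV2 = dv_base[2], EDV3 = dv_base[3],
           ECVP = unname(config$cvp_mmHg[cvp]))
  site <- NA_character_
  inj_p <- 0
  if (!is.null(injection)) {
    site <- match.arg(injection$site, c("DV1", "DV2", "DV3"))
    inj_p <- injection$pressure_mmHg
    if (!is.numeric(inj_p) || inj_p < 0) {
      stop("parameter error: injection pressure must be >= 0 mmHg", call. = FALSE)
    }
    emf[paste0("E", site)] <- emf[paste0("E", site)] + inj_p
  }
  if (any(emf < 0)) stop("parameter error: EMF values must be >= 0", call. = FALSE)
  structure(list(
    emf_mmHg = emf,
    hypotension = hypotension, cvp = cvp, tbo = tbo,
    injection_site = site, injection_mmHg = inj_p, phase = phase,
    id = paste(hypotension, cvp, tbo,
               if (is.na(site)) "noinj" else sprintf("%s+%g", site, inj_p),
               phase, sep = "|")
  ), class = "trensh_pressure_set")
}

#' @export
print.trensh_pressure_set <- function(x, ...) {
  cat(sprintf("<pressure set> %s\n", x$id))
  print(round(x$emf_mmHg, 3))
  invisible(x)
}

#' The standard 320-scenario grid
#'
#' The full factorial design evaluated for every architecture: 32
#' no-injection sets (4 hypotension levels x 2 CVP levels x 4 TBO states)
#' plus 288 injection sets (x 3 DV sites x 3 injection pressures), all at
#' the intermediate cardiac phase.
#'
#' @param config a [sim_config()].
#' @return list of 320 `trensh_pressure_set` objects.
#' @export
standard_grid <- function(config = sim_config()) {
  hy <- names(config$hypotension_mmHg)
  cv <- names(config$cvp_mmHg)
  tb <- c("none", "AF1", "AF2", "AF3")
  out <- list()
  for (h in hy) for (cvl in cv) for (t in tb) {
    out[[length(out) + 1L]] <- pressure_set(h, cvl, t, NULL, "intermediate", config)
    for (site in c("DV1", "DV2", "DV3")) {
      for (p in config$injection_pressures_mmHg) {
        out[[length(out) + 1L]] <-
          pressure_set(h, cvl, t, list(site = site, pressure_mmHg = p),
                       "intermediate", config)
      }
    }
  }
  out
}

#' Fine injection-pressure sweeps
#'
#' Pressure sets sweeping the injection pressure in fixed increments (the
#' detailed TBO analyses sweep 20-30 mmHg in 1 mmHg steps) for each
#' combination of the requested hypotension levels, CVP levels, TBO states
#' and injection sites.
#'
#' @param low,high,step sweep bounds and increment, mmHg.
#' @param hypotension,cvp,tbo_states,sites,phases scenario levels to cross.
#' @param config a [sim_config()].
#' @return list of `trensh_pressure_set` objects.
#' @export
fine_sweep_grid <- function(low = 20, high = 30, step = 1,
                            hypotension = c("moderate", "profound"),
                            cvp = "normal",
                            tbo_states = c("none", "AF1", "AF2", "AF3"),
                            sites = "DV1",
                            phases = "intermediate",
                            config = sim_config()) {
  if (!(low <= high) || step <= 0) {
    stop("parameter error: need low <= high and step > 0", call. = FALSE)
  }
  pressures <- seq(low, high, by = step)
  out <- list()
  for (h in hypotension) for (cvl in cvp) for (t in tbo_states)
    for (s in sites) for (ph in phases) for (p in pressures) {
      out[[length(out) + 1L]] <-
        pressure_set(h, cvl, t, list(site = s, pressure_mmHg = p), ph, config)
    }
  out
}

#' Cardiac-phase study grid
#'
#' Pressure sets for the synchronized-retroinjection study: for every phase
#' (diastole / intermediate / systole) and every injection pressure of the
#' sweep, an injection through the configured site. The intermediate phase
#' carries zero offset and therefore equals the corresponding standard set.
#'
#' @param hypotension hypotension level(s).
#' @param site injection site.
#' @param pressures injection pressures, mmHg (default the 20-30 mmHg
#'   1-mmHg sweep).
#' @param cvp CVP level.
#' @param config a [sim_config()].
#' @return list of `trensh_pressure_set` objects.
#' @export
phase_grid <- function(hypotension = "mild", site = "DV1",
                       pressures = seq(20, 30, by = 1), cvp = "normal",
                       config = sim_config()) {
  out <- list()
  for (h in hypotension) for (ph in c("diastole", "intermediate", "systole"))
    for (p in pressures) {
      out[[length(out) + 1L]] <-
        pressure_set(h, cvp, "none", list(site = site, pressure_mmHg = p), ph, config)
    }
  out
}
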