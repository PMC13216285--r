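# Flow-oriented reachability: edges are passed already oriented (tail ->
# head along the local flow direction) and filtered to traversable ones.
# Returns a logical vector over nodes. Frontier expansion scans the edge
# list, so each sweep is O(E) vectorized; the number of sweeps is the
# reachability depth.
reach_nodes <- function(n_nodes, tails, heads, roots) {
  reached <- logical(n_nodes)
  reached[roots] <- TRUE
  if (!length(tails)) return(reached)
  repeat {
    newly <- reached[tails] & !reached[heads]
    if (!any(newly)) break
    reached[heads[newly]] <- TRUE
  }
  reached
}

# Flows below this magnitude (cm^3/s) are treated as zero for
# direction-dependent logic, so float noise cannot create reachability.
ZERO_FLOW <- 1e-12

# orient edge index vectors by flow sign; drops zero-flow edges
oriented_edges <- function(flow, tails, heads, keep) {
  keep <- keep & abs(flow) > ZERO_FLOW
  fwd <- flow > 0
  list(tail = ifelse(fwd, tails, heads)[keep],
       head = ifelse(fwd, heads, tails)[keep],
       idx = which(keep))
}

#' Sclerosant ingress filling
#'
#' Applies the retrograde-permeation rule to a solved injection scenario:
#' every vessel is oriented by the sign of its computed steady-state flow
#' (zero-flow vessels are non-traversable), and an intranidal vessel counts
#' as filled if and only if its flow-entry (origin) node can be reached from
#' the injection site's nidus boundary along flow-oriented vessels of the
#' nidus (the boundary pedicles are traversable, so the sclerosant can enter
#' through the injected vein's pedicles, but only intranidal vessels are
#' ever counted as filled).
#'
#' @param injection_solution a `trensh_flow` solved under the injection
#'   pressure set.
#' @param network the solved network.
#' @param injection_site `"DV1"`, `"DV2"` or `"DV3"`; defaults to the
#'   solution's own injection site.
#' @return an object of class `trensh_filled`: the filled intranidal vessel
#'   ids plus scenario bookkeeping (`phase_tag = "ingress"`).
#' @export
ingress_filling <- function(injection_solution, network, injection_site = NULL) {
  stopifnot(inherits(injection_solution, "trensh_flow"))
  if (is.null(injection_site)) {
    injection_site <- injection_solution$pressure_set$injection_site
  }
  if (is.na(injection_site) || !injection_site %in% network$nodes$id) {
    stop("parameter error: injection site absent from network", call. = FALSE)
  }
  v <- network$vessels
  nid <- network$nodes$id
  nn <- length(nid)
  intra <- v$category %in% INTRANIDAL_CATEGORIES
  trav <- (intra | v$class %in% c("af_pedicle", "dv_pedicle")) &
    !(v$id %in% injection_solution$occluded)
  t_idx <- match(v$tail, nid)
  h_idx <- match(v$head, nid)
  o <- oriented_edges(injection_solution$flow_cm3s, t_idx, h_idx, trav)
  reached <- reach_nodes(nn, o$tail, o$head, match(injection_site, nid))
  origin <- ifelse(injection_solution$flow_cm3s > 0, t_idx, h_idx)
  filled <- intra & abs(injection_solution$flow_cm3s) > ZERO_FLOW & reached[origin]
  new_filled(v$id[filled], injection_site,
             injection_solution$pressure_set$tbo, "ingress")
}

new_filled <- function(ids, site, tbo, tag) {
  structure(list(vessels = ids, injection_site = site, tbo = tbo,
                 phase_tag = tag), class = "trensh_filled")
}

#' @export
print.trensh_filled <- function(x, ...) {
  cat(sprintf("<trensh_filled> %s via %s: %d vessels\n",
              x$phase_tag, x$injection_site, length(x$vessels)))
  invisible(x)
}

#' Antegrade egress closure of a filled set
#'
#' After the injection stops, inflowing arterial blood carries the
#' sclerosant out of the nidus along the baseline (no-injection) flow
#' directions. A vessel joins the filled set if its baseline-flow origin
#' node is the head of a vessel already in the set; the rule is applied to
#' a fixed point (it is idempotent). The result is the ingress set united
#' with everything antegradely reachable from it.
#'
#' @param baseline_solution a `trensh_flow` for the matching no-injection
#'   pressure set (same TBO topology as the ingress run).
#' @param ingress a `trensh_filled` from [ingress_filling()].
#' @param network the solved network.
#' @return a `trensh_filled` with `phase_tag = "final"`.
#' @export
egress_closure <- function(baseline_solution, ingress, network) {
  stopifnot(inherits(baseline_solution, "trensh_flow"),
            inherits(ingress, "trensh_filled"))
  if (!identical(baseline_solution$pressure_set$tbo, ingress$tbo)) {
    stop("consistency error: baseline and ingress runs use different TBO topologies",
         call. = FALSE)
  }
  v <- network$vessels
  nid <- network$nodes$id
  nn <- length(nid)
  intra <- v$category %in% INTRANIDAL_CATEGORIES
  active <- intra & !(v$id %in% baseline_solution$occluded)
  t_idx <- match(v$tail, nid)
  h_idx <- match(v$head, nid)
  q <- baseline_solution$flow_cm3s
  o <- oriented_edges(q, t_idx, h_idx, active)

  in_set <- v$id %in% ingress$vessels
  if (!any(in_set)) return(new_filled(character(0), ingress$injection_site,
                                      ingress$tbo, "final"))
  # roots: baseline-flow heads of the already-filled vessels
  bhead <- ifelse(q > 0, h_idx, t_idx)
  roots <- unique(bhead[in_set & abs(q) > ZERO_FLOW])
  reached <- reach_nodes(nn, o$tail, o$head, roots)
  borigin <- ifelse(q > 0, t_idx, h_idx)
  extra <- active & abs(q) > ZERO_FLOW & reached[borigin]
  new_filled(union(ingress$vessels, v$id[extra]),
             ingress$injection_site, ingress$tbo, "final")
}

#' Percent of the nidus filled
#'
#' @param filled a `trensh_filled`.
#' @param network the network (supplies the intranidal denominator,
#'   fistula included).
#' @return percentage in \[0, 100\].
#' @export
percent_filling <- function(filled, network) {
  total <- length(intranidal_vessel_ids(network))
  if (total == 0L) stop("undefined: network has an empty nidus", call. = FALSE)
  100 * length(filled$vessels) / total
}

#' Normalized rupture-risk of a vessel
#'
#' \deqn{Risk = \ln(P_{exp}/P_{min}) / \ln(P_{max}/P_{min}) \times 100\%}
#' clamped to \[0, 100\]. `p_min` defaults to 4 mmHg (the minimum CVP of
#' the pressure sets) and `p_max` to 74 mmHg (the feeder pressure expected
#' under systemic hypertension), so the statistic reads as a normalized
#' probability of rupture.
#'
#' @param pressure exposure pressure(s) P_exp, mmHg (> 0).
#' @param params list with `p_min`, `p_max` (mmHg).
#' @return risk percentage(s) in \[0, 100\].
#' @examples
#' rupture_risk(4)                  # 0
#' rupture_risk(74)                 # 100
#' rupture_risk(sqrt(4 * 74))       # 50
#' @export
rupture_risk <- function(pressure, params = list(p_min = 4, p_max = 74)) {
  if (!(params$p_min > 0 && params$p_min < params$p_max)) {
    stop("risk parameters require 0 < p_min < p_max", call. = FALSE)
  }
  if (any(!is.finite(pressure)) || any(pressure <= 0)) {
    stop("domain error: rupture risk requires positive pressure", call. = FALSE)
  }
  pmin(pmax(log(pressure / params$p_min) / log(params$p_max / params$p_min) * 100,
            0), 100)
}

# vectorized risk that maps non-positive exposure pressures to 0 instead of
# erroring (a vessel with no flow has no longitudinal drop and no risk)
risk_clamped <- function(pressure, p_min, p_max) {
  out <- numeric(length(pressure))
  pos <- is.finite(pressure) & pressure > 0
  out[pos] <- pmin(pmax(log(pressure[pos] / p_min) / log(p_max / p_min) * 100, 0), 100)
  out
}

#' Mean and maximum rupture risk across the nidus
#'
#' The exposure pressure of each intranidal vessel follows the configured
#' convention (default `"drop"`: the longitudinal pressure difference
#' |R_v Q| across the vessel; alternatives `"mean"` and `"entry"` use the
#' endpoint node pressures).
#'
#' @param solution a `trensh_flow`.
#' @param network the solved network.
#' @param risk risk parameter list (`p_min`, `p_max`, `pexp`); defaults to
#'   the network config's.
#' @return list with `mean_pct` and `max_pct`.
#' @export
nidus_risk_summary <- function(solution, network, risk = NULL) {
  if (is.null(risk)) {
    risk <- if (!is.null(network$config)) network$config$risk else
      list(p_min = 4, p_max = 74, pexp = "drop")
  }
  v <- network$vessels
  intra <- which(v$category %in% INTRANIDAL_CATEGORIES)
  pexp <- switch(risk$pexp %||% "drop",
    drop = abs(solution$dp_mmHg[intra]),
    mean = {
      p <- solution$node_pressure_mmHg
      i <- match(v$tail[intra], network$nodes$id)
      j <- match(v$head[intra], network$nodes$id)
      (p[i] + p[j]) / 2
    },
    entry = {
      p <- solution$node_pressure_mmHg
      i <- match(v$tail[intra], network$nodes$id)
      j <- match(v$head[intra], network$nodes$id)
      ifelse(solution$flow_cm3s[intra] >= 0, p[i], p[j])
    })
  r <- risk_clamped(pexp, risk$p_min, risk$p_max)
  list(mean_pct = mean(r), max_pct = max(r))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Animation frames of a simulated treatment
#'
#' Reproduces the two-phase animation rule. The retrograde ingress phase has
#' one frame per integer injection pressure from 0 mmHg up to the target;
#' each frame re-solves the steady state and colors the vessels whose entry
#' node is reachable from the injection node in the flow-directed graph.
#' The antegrade exit phase then drops the injection to 0: in each
#' successive frame a vessel is colored if and only if a vessel pointing to
#' its entry node (under baseline flow) was colored in the previous frame,
#' until no vessel is colored or a frame repeats.
#'
#' @param network a `trensh_network` with nidus.
#' @param scenario a `trensh_pressure_set` carrying the scenario (its
#'   injection site is used; its injection pressure is ignored in favour of
#'   the sweep).
#' @param target_injection target injection pressure, integer mmHg >= 0.
#' @param config a [sim_config()]; defaults to the network's.
#' @return list of frames, each `list(phase, injection_mmHg, vessels)`.
#' @export
animation_frames <- function(network, scenario, target_injection,
                             config = NULL) {
  if (!is.numeric(target_injection) || length(target_injection) != 1L ||
      target_injection < 0 || target_injection != round(target_injection)) {
    stop("parameter error: target injection must be a non-negative integer mmHg",
         call. = FALSE)
  }
  if (is.null(config)) config <- network$config %||% sim_config()
  site <- scenario$injection_site
  if (is.na(site)) stop("parameter error: scenario has no injection site", call. = FALSE)

  pressures <- seq(0, target_injection)
  sets <- lapply(pressures, function(p) {
    pressure_set(scenario$hypotension, scenario$cvp, scenario$tbo,
                 if (p > 0) list(site = site, pressure_mmHg = p) else NULL,
                 scenario$phase, config)
  })
  sols <- solve_flow(network, sets)
  frames <- lapply(seq_along(sols), function(i) {
    f <- ingress_filling(sols[[i]], network, site)
    list(phase = "ingress", injection_mmHg = pressures[i], vessels = f$vessels)
  })

  # exit phase under the baseline (0 mmHg) orientation
  base <- sols[[1]]
  v <- network$vessels
  nid <- network$nodes$id
  intra <- v$category %in% INTRANIDAL_CATEGORIES
  active <- intra & !(v$id %in% base$occluded) & abs(base$flow_cm3s) > ZERO_FLOW
  t_idx <- match(v$tail, nid); h_idx <- match(v$head, nid)
  borigin <- ifelse(base$flow_cm3s > 0, t_idx, h_idx)
  bhead <- ifelse(base$flow_cm3s > 0, h_idx, t_idx)

  colored <- v$id %in% frames[[length(frames)]]$vessels
  seen <- list(paste(sort(v$id[colored]), collapse = ","))
  repeat {
    roots <- unique(bhead[colored & active])
    colored <- active & borigin %in% roots
    sig <- paste(sort(v$id[colored]), collapse = ",")
    if (!any(colored) || sig %in% seen) {
      if (any(colored)) break else {
        frames[[length(frames) + 1L]] <-
          list(phase = "exit", injection_mmHg = 0, vessels = character(0))
        break
      }
    }
    seen[[length(seen) + 1L]] <- sig
    frames[[length(frames) + 1L]] <-
      list(phase = "exit", injection_mmHg = 0, vessels = v$id[colored])
  }
  frames
}
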