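#' Run a scenario grid over many stochastic architectures
#'
#' The main batch runner: for each of `n_architectures` seeds (architecture
#' `i` uses `seed + i`, so a rerun with the same master seed reproduces the
#' table exactly), samples a nidus, attaches it to the extranidal template,
#' solves every pressure set of the grid (one sparse factorization per TBO
#' topology, all right-hand sides of a topology solved together), and
#' computes per-simulation outcomes: total nidal flow, percent filling
#' (final egress-closed set, plus the raw ingress set), and mean / maximum
#' intranidal rupture risk.
#'
#' If an injection set's no-injection parent (same hypotension, CVP, TBO
#' and phase) is not part of the grid it is solved internally anyway, since
#' the egress closure needs the baseline flow directions.
#'
#' @param n_architectures number of architectures (>= 1).
#' @param seed master seed.
#' @param config a [sim_config()].
#' @param grid list of pressure sets; default [standard_grid()] (320 sets).
#' @param progress print a dot every 25 architectures.
#' @return data frame with one row per (architecture, pressure set):
#'   `arch_seed`, scenario fields, `total_flow_ml_min`, `pct_filling`
#'   (NA for no-injection sets), `pct_filling_ingress`, `mean_risk_pct`,
#'   `max_risk_pct`, `n_nidus_vessels`.
#' @export
run_main_grid <- function(n_architectures, seed = 1, config = sim_config(),
                          grid = NULL, progress = FALSE) {
  stopifnot(n_architectures >= 1)
  if (is.null(grid)) grid <- standard_grid(config)
  template <- build_extranidal_template(config)

  # ensure every injection set has a baseline (no-injection) parent in the
  # solve batch; parents are solved but reported only if part of the grid
  key <- function(s) paste(s$hypotension, s$cvp, s$tbo, s$phase)
  keys <- vapply(grid, key, "")
  noinj <- vapply(grid, function(s) is.na(s$injection_site), TRUE)
  need <- unique(keys[!noinj])
  have <- keys[noinj]
  extra <- lapply(setdiff(need, have), function(k) {
    p <- strsplit(k, " ", fixed = TRUE)[[1]]
    pressure_set(p[1], p[2], p[3], NULL, p[4], config)
  })
  sets <- c(grid, extra)
  keys_all <- vapply(sets, key, "")
  noinj_all <- vapply(sets, function(s) is.na(s$injection_site), TRUE)
  parent_of <- vapply(seq_along(sets), function(i) {
    if (noinj_all[i]) NA_integer_ else which(noinj_all & keys_all == keys_all[i])[1]
  }, 1L)

  rows <- vector("list", n_architectures)
  for (a in seq_len(n_architectures)) {
    arch_seed <- as.integer(seed) + a
    nid <- sample_architecture(arch_seed, config)
    net <- attach_nidus(template, nid)
    rows[[a]] <- grid_metrics(net, sets, parent_of, config,
                              report = seq_along(grid), arch_seed)
    if (progress && a %% 25L == 0L) cat(".")
  }
  if (progress) cat("\n")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# metrics for one architecture over a solved batch of sets
grid_metrics <- function(net, sets, parent_of, config, report, arch_seed) {
  mats <- flow_matrices(net, sets)
  v <- net$vessels
  nid_ids <- net$nodes$id
  nn <- length(nid_ids)
  t_idx <- match(v$tail, nid_ids)
  h_idx <- match(v$head, nid_ids)
  intra <- v$category %in% INTRANIDAL_CATEGORIES
  trav <- intra | v$class %in% c("af_pedicle", "dv_pedicle")
  n_intra <- sum(intra)
  bnd <- boundary_edges(net)
  p_min <- config$risk$p_min
  p_max <- config$risk$p_max
  pexp_mode <- config$risk$pexp

  occl_of <- vapply(seq_along(sets), function(i) {
    oc <- mats$occluded[[mats$group_of[i]]]
    if (length(oc)) oc else ""
  }, "")

  n_rep <- length(report)
  total_flow <- mean_risk <- max_risk <- fill_final <- fill_ingress <-
    rep(NA_real_, n_rep)

  for (r in seq_len(n_rep)) {
    i <- report[r]
    q <- mats$Q[, i]
    total_flow[r] <- flow_to_ml_min(sum(q[bnd$af]))
    pe <- switch(pexp_mode,
      drop = abs(mats$DP[intra, i]),
      mean = (mats$P[t_idx[intra], i] + mats$P[h_idx[intra], i]) / 2,
      entry = ifelse(q[intra] >= 0, mats$P[t_idx[intra], i], mats$P[h_idx[intra], i]))
    rk <- risk_clamped(pe, p_min, p_max)
    mean_risk[r] <- mean(rk)
    max_risk[r] <- max(rk)

    s <- sets[[i]]
    if (!is.na(s$injection_site)) {
      occluded_edge <- occl_of[i]
      active_t <- trav & v$id != occluded_edge
      o <- oriented_edges(q, t_idx, h_idx, active_t)
      reached <- reach_nodes(nn, o$tail, o$head, match(s$injection_site, nid_ids))
      origin <- ifelse(q > 0, t_idx, h_idx)
      filled <- intra & abs(q) > ZERO_FLOW & reached[origin]
      fill_ingress[r] <- 100 * sum(filled) / n_intra

      qb <- mats$Q[, parent_of[i]]
      active_b <- intra & v$id != occluded_edge & abs(qb) > ZERO_FLOW
      ob <- oriented_edges(qb, t_idx, h_idx, active_b)
      bhead <- ifelse(qb > 0, h_idx, t_idx)
      roots <- unique(bhead[filled & abs(qb) > ZERO_FLOW])
      if (length(roots)) {
        rb <- reach_nodes(nn, ob$tail, ob$head, roots)
        borigin <- ifelse(qb > 0, t_idx, h_idx)
        final <- filled | (active_b & rb[borigin])
      } else final <- filled
      fill_final[r] <- 100 * sum(final) / n_intra
    }
  }

  data.frame(
    arch_seed = arch_seed,
    hypotension = vapply(sets[report], `[[`, "", "hypotension"),
    cvp = vapply(sets[report], `[[`, "", "cvp"),
    tbo = vapply(sets[report], `[[`, "", "tbo"),
    site = vapply(sets[report], `[[`, "", "injection_site"),
    injection_mmHg = vapply(sets[report], `[[`, 1, "injection_mmHg"),
    phase = vapply(sets[report], `[[`, "", "phase"),
    total_flow_ml_min = total_flow,
    pct_filling = fill_final,
    pct_filling_ingress = fill_ingress,
    mean_risk_pct = mean_risk,
    max_risk_pct = max_risk,
    n_nidus_vessels = n_intra,
    stringsAsFactors = FALSE
  )
}

#' Aggregate a result table
#'
#' Group means, standard deviations and group sizes for the numeric
#' outcome columns, in the style of the bar-chart summaries.
#'
#' @param table a [run_main_grid()] result.
#' @param by character vector of grouping fields.
#' @param metrics outcome columns to summarize.
#' @return data frame: grouping fields, then `mean_*`, `sd_*` per metric
#'   and `n`.
#' @export
aggregate_results <- function(table,
                              by = c("hypotension", "injection_mmHg", "cvp"),
                              metrics = c("total_flow_ml_min", "pct_filling",
                                          "mean_risk_pct", "max_risk_pct")) {
  missing_f <- setdiff(c(by, metrics), names(table))
  if (length(missing_f)) {
    stop(sprintf("parameter error: unknown field(s): %s",
                 paste(missing_f, collapse = ", ")), call. = FALSE)
  }
  if (!nrow(table)) stop("parameter error: empty table", call. = FALSE)
  g <- interaction(table[by], drop = TRUE, lex.order = TRUE)
  out <- do.call(rbind, lapply(split(table[by], g), function(d) d[1, , drop = FALSE]))
  for (m in metrics) {
    x <- split(table[[m]], g)
    out[[paste0("mean_", m)]] <- vapply(x, function(z) mean(z, na.rm = TRUE), 1)
    out[[paste0("sd_", m)]] <- vapply(x, function(z) {
      z <- z[!is.na(z)]
      if (length(z) < 2) 0 else stats::sd(z)
    }, 1)
  }
  out$n <- as.integer(table(g))
  rownames(out) <- NULL
  out
}

#' Compare outcome groups with the study's statistics
#'
#' Unpaired two-tailed Student's t-test (pooled variance by default, Welch
#' optional) for two groups differing in a single factor, or a one-way
#' ANOVA when the factor has three levels (as used for the draining-vein
#' site comparison). Significance at alpha = 0.05.
#'
#' @param table a result table.
#' @param response outcome column name.
#' @param factor column whose levels define the groups.
#' @param fixed named list of values the other scenario fields are held at.
#' @param levels optional subset/order of factor levels.
#' @param welch use Welch's unequal-variance t-test.
#' @return list: `method`, `statistic`, `df`, `p_value`, `group_means`,
#'   `significant` (alpha 0.05).
#' @export
compare_groups <- function(table, response, factor, fixed = list(),
                           levels = NULL, welch = FALSE) {
  keep <- rep(TRUE, nrow(table))
  for (f in names(fixed)) {
    if (!f %in% names(table)) {
      stop(sprintf("parameter error: unknown field '%s'", f), call. = FALSE)
    }
    keep <- keep & table[[f]] %in% fixed[[f]]
  }
  d <- table[keep & !is.na(table[[response]]), ]
  if (!is.null(levels)) d <- d[d[[factor]] %in% levels, ]
  groups <- split(d[[response]], d[[factor]])
  groups <- groups[vapply(groups, length, 1L) > 0]
  if (any(vapply(groups, length, 1L) < 2)) {
    stop("insufficient data: every group needs >= 2 observations", call. = FALSE)
  }
  if (length(groups) == 2L) {
    tt <- stats::t.test(groups[[1]], groups[[2]], var.equal = !welch)
    out <- list(method = if (welch) "Welch t-test" else "Student t-test (pooled)",
                statistic = unname(tt$statistic), df = unname(tt$parameter),
                p_value = tt$p.value)
  } else if (length(groups) >= 3L) {
    dd <- data.frame(y = unlist(groups),
                     gglab = rep(names(groups), vapply(groups, length, 1L)))
    fit <- stats::aov(y ~ gglab, data = dd)
    an <- summary(fit)[[1]]
    out <- list(method = "one-way ANOVA", statistic = an$`F value`[1],
                df = an$Df, p_value = an$`Pr(>F)`[1])
  } else {
    stop("insufficient data: need at least two groups", call. = FALSE)
  }
  out$group_means <- vapply(groups, mean, 1)
  out$n <- vapply(groups, length, 1L)
  out$significant <- out$p_value < 0.05
  out
}

#' Sensitivity of baseline flow to vessel-dimension jitter
#'
#' Re-samples every vessel's length and radius uniformly within a relative
#' jitter band around its tabulated value and recomputes the baseline
#' (normotension, normal CVP, no occlusion, no injection) total nidal flow
#' for each of `n_architectures` fresh architectures.
#'
#' @param n_architectures number of jittered architectures.
#' @param jitter relative half-width in \[0, 0.5); 0.10 means +/-10 percent.
#' @param seed master seed.
#' @param config a [sim_config()].
#' @return list: `flows_ml_min` (vector), `min`, `mean`, `max`.
#' @export
sensitivity_analysis <- function(n_architectures = 1000, jitter = 0.10,
                                 seed = 1, config = sim_config()) {
  stopifnot(jitter >= 0, jitter < 0.5)
  template <- build_extranidal_template(config)
  base_set <- pressure_set("normo", "normal", "none", NULL, "intermediate", config)
  flows <- numeric(n_architectures)
  set.seed(as.integer(seed))
  for (a in seq_len(n_architectures)) {
    nid <- sample_architecture(as.integer(seed) + a, config)
    net <- attach_nidus(template, nid)
    if (jitter > 0) {
      w <- nrow(net$vessels)
      net$vessels$length_cm <- net$vessels$length_cm *
        stats::runif(w, 1 - jitter, 1 + jitter)
      net$vessels$radius_cm <- net$vessels$radius_cm *
        stats::runif(w, 1 - jitter, 1 + jitter)
      net$vessels$resistance <- vessel_resistance(
        net$vessels$length_cm, net$vessels$radius_cm, config$viscosity)
    }
    sol <- solve_flow(net, base_set)[[1]]
    flows[a] <- total_nidal_flow(sol, net)
  }
  list(flows_ml_min = flows, min = min(flows), mean = mean(flows),
       max = max(flows))
}

#' Cardiac-phase retroinjection study
#'
#' Sweeps injection pressures through one draining vein for the three
#' cardiac phases (diastole / intermediate / systole) at the requested
#' hypotension levels, and summarizes filling per phase and pressure.
#'
#' @param n_architectures number of architectures (the sub-analyses use 61).
#' @param seed master seed.
#' @param pressures injection-pressure sweep, mmHg.
#' @param hypotension hypotension levels to test.
#' @param site injection site.
#' @param config a [sim_config()].
#' @return list: `table` (per-simulation rows) and `summary` (mean filling
#'   per hypotension x phase x pressure).
#' @export
phase_study <- function(n_architectures = 61, seed = 1,
                        pressures = seq(20, 30, by = 1),
                        hypotension = c("mild", "moderate", "profound"),
                        site = "DV1", config = sim_config()) {
  grid <- list()
  for (h in hypotension) {
    grid <- c(grid, phase_grid(h, site, pressures, "normal", config))
  }
  tab <- run_main_grid(n_architectures, seed, config, grid = grid)
  summ <- aggregate_results(tab, by = c("hypotension", "phase", "injection_mmHg"),
                            metrics = "pct_filling")
  list(table = tab, summary = summ)
}
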