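#' Truncated-normal integer draws
#'
#' Draws integers by rounding normal variates and rejecting values outside
#' `[low, high]` (truncation by rejection, not clipping, so boundary mass is
#' not inflated). With `sd = 0` the draw degenerates to `round(mean)`
#' clamped to the bounds.
#'
#' @param n number of draws.
#' @param mean,sd normal parameters.
#' @param low,high inclusive integer bounds, `low <= high`.
#' @return integer vector of length `n` with values in `[low, high]`.
#' @export
rtrunc_norm_int <- function(n, mean, sd, low, high) {
  if (low > high) stop("parameter error: low > high", call. = FALSE)
  if (sd < 0) stop("parameter error: sd < 0", call. = FALSE)
  if (sd == 0) {
    return(rep.int(as.integer(pmin(pmax(round(mean), low), high)), n))
  }
  out <- integer(n)
  todo <- seq_len(n)
  while (length(todo)) {
    cand <- as.integer(round(stats::rnorm(length(todo), mean, sd)))
    ok <- cand >= low & cand <= high
    out[todo[ok]] <- cand[ok]
    todo <- todo[!ok]
  }
  out
}

# Truncated-normal integer draw excluding one value (used for the end
# column of intercompartmental vessels: centered on, but excluding, the
# start column).
rtrunc_norm_int_excl <- function(n, mean, sd, low, high, exclude) {
  out <- integer(n)
  todo <- seq_len(n)
  while (length(todo)) {
    cand <- as.integer(round(stats::rnorm(length(todo), mean, sd)))
    ok <- cand >= low & cand <= high & cand != exclude
    out[todo[ok]] <- cand[ok]
    todo <- todo[!ok]
  }
  out
}

# uniform draw from a vector without R's scalar-x surprise
sample1 <- function(x) x[sample.int(length(x), 1L)]

# Fixed layout positions of the feeder and draining-vein terminals
# (evenly spaced on the vertical axis; nidus columns run x = 1..K).
af_layout_y <- function() (seq_len(4) - 0.5) / 4
dv_layout_y <- function() (seq_len(3) - 0.5) / 3

#' Sample a stochastic nidus architecture
#'
#' Generates one compartmentalized plexiform nidus. The number of
#' compartments is a truncated-normal integer on \[3, 6\] (mean 4.5, sd 1)
#' and the number of columns on \[3, 7\] (mean 5, sd 1). Each compartment
#' spans all columns; end columns hold 30-34 nodes per compartment and
#' interior columns 36-40. Intracompartmental vessels guarantee that every
#' node has at least one incoming vessel from the previous column and one
#' outgoing vessel to the next. `2 * C * K` intercompartmental vessels
#' connect distinct compartments, their end column drawn from a normal (sd
#' 2) centered on, but excluding, the start column. A single larger-radius
#' fistula runs from AF2 through one node of every column of the middle
#' compartment to DV2. Finally each first-column node is attached to its
#' nearest AF (and each last-column node to its nearest DV) by Euclidean
#' distance in the layout, with short pedicle vessels; a feeder or vein left
#' without any attachment is attached to its nearest intranidal node.
#'
#' Generation is deterministic for a fixed seed.
#'
#' @param seed integer seed.
#' @param config a [sim_config()].
#' @return an object of class `trensh_nidus` with fields
#'   `n_compartments`, `n_columns`, `nodes`, `vessels` (intranidal only,
#'   with a `kind` of intracompartmental / intercompartmental / fistula),
#'   `pedicles` (AF/DV boundary attachment vessels), `fistula_path`
#'   (ordered vessel ids AF2 -> DV2), `boundary_attachments`, and `seed`.
#' @export
sample_architecture <- function(seed, config = sim_config()) {
  stopifnot(inherits(config, "trensh_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(as.integer(seed))

  nd <- config$nidus
  C <- rtrunc_norm_int(1, nd$compartments["mean"], nd$compartments["sd"],
                       nd$compartments["low"], nd$compartments["high"])
  K <- rtrunc_norm_int(1, nd$columns["mean"], nd$columns["sd"],
                       nd$columns["low"], nd$columns["high"])

  # node counts per (compartment, column); end columns sparser than interior
  counts <- matrix(0L, nrow = C, ncol = K)
  for (c_ in seq_len(C)) {
    for (k_ in seq_len(K)) {
      rng <- if (k_ == 1L || k_ == K) nd$nodes_end else nd$nodes_interior
      counts[c_, k_] <- sample1(seq.int(rng[1], rng[2]))
    }
  }

  node_id <- function(c_, k_, i) sprintf("n_c%d_k%d_%02d", c_, k_, i)
  nodes_list <- vector("list", C * K)
  idx <- 0L
  for (c_ in seq_len(C)) {
    for (k_ in seq_len(K)) {
      m <- counts[c_, k_]
      idx <- idx + 1L
      nodes_list[[idx]] <- data.frame(
        id = node_id(c_, k_, seq_len(m)),
        role = "junction",
        x = k_,
        # compartments stacked top to bottom, nodes evenly spaced in band
        y = (c_ - 1) / C + (seq_len(m) - 0.5) / (m * C),
        compartment = c_, column = k_,
        stringsAsFactors = FALSE
      )
    }
  }
  nodes <- do.call(rbind, nodes_list)
  ids_at <- function(c_, k_) node_id(c_, k_, seq_len(counts[c_, k_]))

  d_plex <- dims_for(config, "plexiform")
  d_fist <- dims_for(config, "fistula")
  r_plex <- vessel_resistance(d_plex$length, d_plex$radius, config$viscosity)
  r_fist <- vessel_resistance(d_fist$length, d_fist$radius, config$viscosity)

  mk_edges <- function(ids, tails, heads, class, length_cm, radius_cm,
                       resistance, category, compartment, column, kind) {
    data.frame(id = ids, tail = tails, head = heads, class = class,
               length_cm = length_cm, radius_cm = radius_cm,
               resistance = resistance, category = category,
               compartment = compartment, column = column, kind = kind,
               stringsAsFactors = FALSE)
  }

  # --- intracompartmental skeleton -------------------------------------
  intra_list <- list()
  for (c_ in seq_len(C)) {
    for (k_ in 2L:K) {
      prev <- ids_at(c_, k_ - 1L)
      cur <- ids_at(c_, k_)
      tails <- prev[sample.int(length(prev), length(cur), replace = TRUE)]
      intra_list[[length(intra_list) + 1L]] <-
        list(tail = tails, head = cur, comp = c_, col = k_)
      # any previous-column node left without an outgoing vessel gets one
      # to a uniformly chosen node of this column
      lonely <- setdiff(prev, tails)
      if (length(lonely)) {
        heads2 <- cur[sample.int(length(cur), length(lonely), replace = TRUE)]
        intra_list[[length(intra_list) + 1L]] <-
          list(tail = lonely, head = heads2, comp = c_, col = k_)
      }
    }
  }
  tails <- unlist(lapply(intra_list, `[[`, "tail"))
  heads <- unlist(lapply(intra_list, `[[`, "head"))
  comps <- unlist(lapply(intra_list, function(e) rep(e$comp, length(e$tail))))
  cols <- unlist(lapply(intra_list, function(e) rep(e$col, length(e$tail))))
  intra <- mk_edges(sprintf("p%05d", seq_along(tails)), tails, heads,
                    "plexiform", d_plex$length, d_plex$radius, r_plex,
                    "intranidal-plexiform", comps, cols, "intracompartmental")

  # --- intercompartmental vessels --------------------------------------
  inter <- generate_intercompartmental_vessels(C, K, counts, ids_at, config)

  # --- intranidal fistula ----------------------------------------------
  mid <- as.integer(ceiling(C / 2))
  path_nodes <- vapply(seq_len(K), function(k_) sample1(ids_at(mid, k_)), "")
  f_tails <- c("AF2", path_nodes)
  f_heads <- c(path_nodes, "DV2")
  fistula <- mk_edges(sprintf("f%02d", seq_len(K + 1L)), f_tails, f_heads,
                      "fistula", d_fist$length, d_fist$radius, r_fist,
                      "intranidal-fistula", mid,
                      c(seq_len(K), K), "fistula")

  vessels <- rbind(intra, inter, fistula)

  # --- boundary attachments (nearest terminal by Euclidean layout) -----
  att <- attach_boundaries(nodes, counts, C, K, config)

  structure(list(
    n_compartments = C, n_columns = K,
    middle_compartment = mid,
    counts = counts,
    nodes = nodes, vessels = vessels,
    pedicles = att$pedicles,
    boundary_attachments = att$attachments,
    fistula_path = fistula$id,
    seed = as.integer(seed)
  ), class = "trensh_nidus")
}

#' Intercompartmental vessel generation
#'
#' Internal engine behind [sample_architecture()], exposed for testing.
#' Produces exactly `2 * C * K` vessels; each starts on a uniform node of a
#' uniform column of a uniform compartment, ends in a different compartment,
#' and its end column is a truncated-normal draw (sd from the config,
#' default 2) centered on, but excluding, the start column.
#'
#' @param C,K compartment and column counts.
#' @param counts C x K matrix of per-cell node counts.
#' @param ids_at function(c, k) returning the node ids of a cell.
#' @param config a [sim_config()].
#' @return data frame of vessels (category intranidal-plexiform, kind
#'   intercompartmental).
#' @keywords internal
generate_intercompartmental_vessels <- function(C, K, counts, ids_at, config) {
  n_ic <- 2L * C * K
  d_plex <- dims_for(config, "plexiform")
  r_plex <- vessel_resistance(d_plex$length, d_plex$radius, config$viscosity)
  sd_ic <- config$nidus$intercompartmental_sd
  tail <- head <- character(n_ic)
  comp0 <- col0 <- integer(n_ic)
  for (i in seq_len(n_ic)) {
    c0 <- sample.int(C, 1L)
    k0 <- sample.int(K, 1L)
    tail[i] <- sample1(ids_at(c0, k0))
    c1 <- sample1(setdiff(seq_len(C), c0))
    k1 <- rtrunc_norm_int_excl(1L, k0, sd_ic, 1L, K, k0)
    head[i] <- sample1(ids_at(c1, k1))
    comp0[i] <- c0; col0[i] <- k0
  }
  data.frame(id = sprintf("ic%04d", seq_len(n_ic)), tail = tail, head = head,
             class = "plexiform", length_cm = d_plex$length,
             radius_cm = d_plex$radius, resistance = r_plex,
             category = "intranidal-plexiform",
             compartment = comp0, column = col0,
             kind = "intercompartmental", stringsAsFactors = FALSE)
}

# Attach nidus boundary rows to the AF/DV terminals: every first-column
# node to its nearest AF, every last-column node to its nearest DV
# (Euclidean distance in the layout; ties break to the lower terminal
# index). A terminal left without any attachment (possible for AF4, whose
# feeding pedigree is weakest) is attached to the nearest intranidal node.
attach_boundaries <- function(nodes, counts, C, K, config) {
  d_afp <- dims_for(config, "af_pedicle")
  d_dvp <- dims_for(config, "dv_pedicle")
  r_afp <- vessel_resistance(d_afp$length, d_afp$radius, config$viscosity)
  r_dvp <- vessel_resistance(d_dvp$length, d_dvp$radius, config$viscosity)

  nearest <- function(node_y, node_x, term_y, term_x) {
    # ties broken toward the lower terminal index via order stability
    d <- sqrt((term_x - node_x)^2 + (term_y - node_y)^2)
    which.min(round(d, 12))
  }

  first <- nodes[nodes$column == 1L, ]
  last <- nodes[nodes$column == K, ]
  af_y <- af_layout_y(); dv_y <- dv_layout_y()

  af_idx <- vapply(seq_len(nrow(first)),
                   function(i) nearest(first$y[i], first$x[i], af_y, 0), 1L)
  dv_idx <- vapply(seq_len(nrow(last)),
                   function(i) nearest(last$y[i], last$x[i], dv_y, K + 1), 1L)

  att <- rbind(
    data.frame(boundary_node = first$id, terminal = paste0("AF", af_idx),
               side = "AF", stringsAsFactors = FALSE),
    data.frame(boundary_node = last$id, terminal = paste0("DV", dv_idx),
               side = "DV", stringsAsFactors = FALSE)
  )

  ped_af <- data.frame(
    id = sprintf("paf%04d", seq_len(nrow(first))),
    tail = paste0("AF", af_idx), head = first$id, class = "af_pedicle",
    length_cm = d_afp$length, radius_cm = d_afp$radius, resistance = r_afp,
    category = "AF", compartment = NA_integer_, column = NA_integer_,
    kind = "pedicle", stringsAsFactors = FALSE)
  ped_dv <- data.frame(
    id = sprintf("pdv%04d", seq_len(nrow(last))),
    tail = last$id, head = paste0("DV", dv_idx), class = "dv_pedicle",
    length_cm = d_dvp$length, radius_cm = d_dvp$radius, resistance = r_dvp,
    category = "DV", compartment = NA_integer_, column = NA_integer_,
    kind = "pedicle", stringsAsFactors = FALSE)

  # rescue any unattached terminal (nearest intranidal node overall)
  extra <- list()
  for (i in seq_len(4)) {
    term <- paste0("AF", i)
    if (!term %in% ped_af$tail) {
      j <- which.min(sqrt((nodes$x - 0)^2 + (nodes$y - af_y[i])^2))
      extra[[length(extra) + 1L]] <- data.frame(
        id = sprintf("paf_x%d", i), tail = term, head = nodes$id[j],
        class = "af_pedicle", length_cm = d_afp$length, radius_cm = d_afp$radius,
        resistance = r_afp, category = "AF", compartment = NA_integer_,
        column = NA_integer_, kind = "pedicle", stringsAsFactors = FALSE)
      att <- rbind(att, data.frame(boundary_node = nodes$id[j], terminal = term,
                                   side = "AF", stringsAsFactors = FALSE))
    }
  }
  for (i in seq_len(3)) {
    term <- paste0("DV", i)
    if (!term %in% ped_dv$head) {
      j <- which.min(sqrt((nodes$x - (K + 1))^2 + (nodes$y - dv_y[i])^2))
      extra[[length(extra) + 1L]] <- data.frame(
        id = sprintf("pdv_x%d", i), tail = nodes$id[j], head = term,
        class = "dv_pedicle", length_cm = d_dvp$length, radius_cm = d_dvp$radius,
        resistance = r_dvp, category = "DV", compartment = NA_integer_,
        column = NA_integer_, kind = "pedicle", stringsAsFactors = FALSE)
      att <- rbind(att, data.frame(boundary_node = nodes$id[j], terminal = term,
                                   side = "DV", stringsAsFactors = FALSE))
    }
  }
  pedicles <- rbind(ped_af, ped_dv, do.call(rbind, extra))
  list(pedicles = pedicles, attachments = att)
}

#' @export
print.trensh_nidus <- function(x, ...) {
  cat("<trensh_nidus>\n")
  cat(sprintf("  seed %d: %d compartments x %d columns, %d nodes\n",
              x$seed, x$n_compartments, x$n_columns, nrow(x$nodes)))
  tk <- table(x$vessels$kind)
  cat(sprintf("  intranidal vessels: %d (%s)\n", nrow(x$vessels),
              paste(sprintf("%s %d", names(tk), tk), collapse = ", ")))
  invisible(x)
}
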