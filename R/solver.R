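#' Steady-state flow solution of a vessel network
#'
#' Solves the Kirchhoff equations of the vessel circuit. The implementation
#' assembles the equivalent nodal-potential system: one flow-conservation
#' equation per free node, with the two boundary EMFs (ESP, ECVP) entering
#' as fixed node pressures and the seven series EMFs (per-feeder and
#' per-vein sources) entering as pressure jumps along their edges. The
#' resulting sparse symmetric positive-definite system is factorized once
#' per topology (a Cholesky factor is shared by every pressure set with the
#' same TBO state) and solved for all right-hand sides simultaneously. The
#' cycle law holds by construction and can be verified post hoc with
#' [kirchhoff_residuals()].
#'
#' @param network a `trensh_network` with a nidus attached.
#' @param sets a `trensh_pressure_set` or a list of them.
#' @return a list of `trensh_flow` objects (one per set), each with signed
#'   per-vessel flow (`flow_cm3s`, positive along the nominal
#'   arterial-to-venous orientation), per-vessel hydraulic pressure drop
#'   `dp_mmHg` (= R_v Q), absolute per-node pressures `node_pressure_mmHg`
#'   (anchored at the CVP terminal), and the originating pressure set.
#' @export
solve_flow <- function(network, sets) {
  if (inherits(sets, "trensh_pressure_set")) sets <- list(sets)
  stopifnot(length(sets) > 0, all(vapply(sets, inherits, TRUE, "trensh_pressure_set")))
  mats <- flow_matrices(network, sets)
  lapply(seq_along(sets), function(i) {
    structure(list(
      vessel_id = network$vessels$id,
      flow_cm3s = mats$Q[, i],
      dp_mmHg = mats$DP[, i],
      node_id = network$nodes$id,
      node_pressure_mmHg = mats$P[, i],
      pressure_set = sets[[i]],
      occluded = mats$occluded[[mats$group_of[i]]]
    ), class = "trensh_flow")
  })
}

# Internal batched solver. Returns Q (w x n, cm^3/s), DP (w x n, mmHg,
# hydraulic drop R*Q), P (nodes x n, mmHg), plus bookkeeping. Pressure sets
# are grouped by TBO state; one sparse Cholesky factorization per group.
flow_matrices <- function(network, sets) {
  v <- network$vessels
  nn <- nrow(network$nodes)
  w <- nrow(v)
  node_idx <- seq_len(nn)
  names(node_idx) <- network$nodes$id
  t_idx <- unname(node_idx[v$tail])
  h_idx <- unname(node_idx[v$head])
  g <- 1 / v$resistance

  emfs <- network$emfs
  series <- emfs[emfs$kind == "series", ]
  series_edge <- match(series$attached_edge, v$id)
  d_sys <- unname(node_idx[emfs$node[emfs$id == "ESP"]])
  d_cvp <- unname(node_idx[emfs$node[emfs$id == "ECVP"]])
  dirichlet <- c(d_sys, d_cvp)

  tbo_of <- vapply(sets, `[[`, "", "tbo")
  groups <- unique(tbo_of)
  group_of <- match(tbo_of, groups)

  n <- length(sets)
  Q <- matrix(0, w, n, dimnames = list(v$id, NULL))
  P <- matrix(0, nn, n, dimnames = list(network$nodes$id, NULL))
  occluded <- vector("list", length(groups))

  # per-set signed series EMF per edge (cgs), and boundary pressures
  E_edge <- matrix(0, w, n)
  p_sys <- p_cvp <- numeric(n)
  for (i in seq_len(n)) {
    emf <- mmhg_to_cgs(sets[[i]]$emf_mmHg)
    E_edge[series_edge, i] <- series$orientation * unname(emf[series$id])
    p_sys[i] <- unname(emf["ESP"])
    p_cvp[i] <- unname(emf["ECVP"])
  }

  free <- setdiff(seq_len(nn), dirichlet)
  free_pos <- integer(nn)
  free_pos[free] <- seq_along(free)

  for (gi in seq_along(groups)) {
    tbo <- groups[gi]
    active <- rep(TRUE, w)
    if (tbo != "none") {
      tr <- which(v$id == tolower(tbo))
      if (!length(tr)) stop(sprintf("unknown TBO target '%s'", tbo), call. = FALSE)
      active[tr] <- FALSE
      occluded[[gi]] <- v$id[tr]
    } else {
      occluded[[gi]] <- character(0)
    }
    check_connected(nn, t_idx[active], h_idx[active], network$nodes$id)

    ta <- t_idx[active]; ha <- h_idx[active]; ga <- g[active]
    tf <- free_pos[ta]; hf <- free_pos[ha]      # 0 when dirichlet
    both <- tf > 0 & hf > 0
    ii <- c(tf[tf > 0], hf[hf > 0], tf[both], hf[both])
    jj <- c(tf[tf > 0], hf[hf > 0], hf[both], tf[both])
    xx <- c(ga[tf > 0], ga[hf > 0], -ga[both], -ga[both])
    A <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                              dims = c(length(free), length(free)))
    ch <- Matrix::Cholesky(methods::as(Matrix::forceSymmetric(A), "CsparseMatrix"),
                           LDL = FALSE)

    in_g <- which(group_of == gi)
    B <- matrix(0, length(free), length(in_g))
    Ew <- E_edge[active, in_g, drop = FALSE]
    for (k in seq_along(in_g)) {
      s <- in_g[k]
      pd <- numeric(nn)
      pd[d_sys] <- p_sys[s]; pd[d_cvp] <- p_cvp[s]
      Ek <- Ew[, k]
      # row(tail): + g*E moves to rhs as -g*E; dirichlet head adds +g*P_head
      # row(head): - g*E moves to rhs as +g*E; dirichlet tail adds +g*P_tail
      contrib_t <- -ga * Ek + ifelse(hf == 0, ga * pd[ha], 0)
      contrib_h <- ga * Ek + ifelse(tf == 0, ga * pd[ta], 0)
      bt <- tf > 0
      bh <- hf > 0
      B[, k] <- tabulate_sum(c(tf[bt], hf[bh]),
                             c(contrib_t[bt], contrib_h[bh]),
                             length(free))
    }
    Pf <- as.matrix(Matrix::solve(ch, B))
    for (k in seq_along(in_g)) {
      s <- in_g[k]
      pfull <- numeric(nn)
      pfull[free] <- Pf[, k]
      pfull[d_sys] <- p_sys[s]; pfull[d_cvp] <- p_cvp[s]
      q <- g * (pfull[t_idx] + E_edge[, s] - pfull[h_idx])
      q[!active] <- 0
      if (any(!is.finite(q))) stop("numeric error: non-finite flow", call. = FALSE)
      Q[, s] <- q
      P[, s] <- cgs_to_mmhg(pfull)
    }
  }
  DP <- cgs_to_mmhg(v$resistance * Q)
  list(Q = Q, DP = DP, P = P, occluded = occluded, group_of = group_of,
       groups = groups)
}

# sum `vals` into `n` bins given 1-based bin indices
tabulate_sum <- function(idx, vals, n) {
  out <- numeric(n)
  agg <- rowsum(vals, group = idx, reorder = TRUE)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

check_connected <- function(n_nodes, t_idx, h_idx, node_ids) {
  seen <- logical(n_nodes)
  seen[1L] <- TRUE
  repeat {
    newly <- (seen[t_idx] & !seen[h_idx]) | (seen[h_idx] & !seen[t_idx])
    if (!any(newly)) break
    seen[h_idx[newly]] <- TRUE
    seen[t_idx[newly]] <- TRUE
  }
  if (!all(seen)) {
    stop(sprintf(
      "singular-system error: network is disconnected; unreached node(s): %s",
      paste(utils::head(node_ids[!seen], 5), collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

#' Absolute node pressures of a solution
#'
#' Pressures are anchored at the CVP terminal (held at the active set's CVP
#' value) and are path-independent by the cycle law; two routes to the same
#' node agree to solver precision.
#'
#' @param solution a `trensh_flow`.
#' @return named numeric vector, mmHg.
#' @export
node_pressures <- function(solution) {
  stopifnot(inherits(solution, "trensh_flow"))
  stats::setNames(solution$node_pressure_mmHg, solution$node_id)
}

#' Kirchhoff residuals of a solution
#'
#' Recomputes both conservation laws from the solved flows: the per-node
#' flow imbalance (excluding the two pressure-boundary terminals, which
#' exchange flow with the outside), and the cycle-law residual
#' \eqn{\sum_j (R_j Q_j - E_j)} summed around every fundamental cycle of a
#' spanning-tree cycle basis of the active graph.
#'
#' @param solution a `trensh_flow`.
#' @param network the network it was solved on.
#' @return list with `node_cm3s` (max absolute node imbalance, cm^3/s) and
#'   `cycle_mmHg` (max absolute cycle residual, mmHg).
#' @export
kirchhoff_residuals <- function(solution, network) {
  v <- network$vessels
  active <- !(v$id %in% solution$occluded)
  q <- solution$flow_cm3s[active]
  nid <- network$nodes$id
  nn <- length(nid)
  tl <- match(v$tail[active], nid)
  hd <- match(v$head[active], nid)

  imb <- tabulate_sum(tl, q, nn) - tabulate_sum(hd, q, nn)
  bnd <- network$nodes$role == "source-terminal"
  node_res <- max(abs(imb[!bnd]))

  # u_e = R_e Q_e - E_e is the drop the cycle law sums; around every
  # fundamental cycle of a spanning tree it must vanish. Build a BFS
  # spanning tree, integrate u along it to a tree potential phi, and
  # measure each chord's cycle residual as u_chord - (phi_tail - phi_head).
  emf <- mmhg_to_cgs(solution$pressure_set$emf_mmHg)
  series <- network$emfs[network$emfs$kind == "series", ]
  E <- numeric(sum(active))
  m <- match(series$attached_edge, v$id[active])
  ok <- !is.na(m)
  E[m[ok]] <- series$orientation[ok] * unname(emf[series$id[ok]])
  u <- v$resistance[active] * q - E

  phi <- rep(NA_real_, nn)
  tree_edge <- logical(length(u))
  phi[1L] <- 0
  repeat {
    fwd <- which(!tree_edge & !is.na(phi[tl]) & is.na(phi[hd]))
    bwd <- which(!tree_edge & !is.na(phi[hd]) & is.na(phi[tl]))
    if (!length(fwd) && !length(bwd)) break
    fwd <- fwd[!duplicated(hd[fwd])]
    phi[hd[fwd]] <- phi[tl[fwd]] - u[fwd]
    tree_edge[fwd] <- TRUE
    bwd <- bwd[is.na(phi[tl[bwd]])]
    bwd <- bwd[!duplicated(tl[bwd])]
    if (length(bwd)) {
      phi[tl[bwd]] <- phi[hd[bwd]] + u[bwd]
      tree_edge[bwd] <- TRUE
    }
  }
  chords <- which(!tree_edge)
  cyc <- if (length(chords)) max(abs(u[chords] - (phi[tl[chords]] - phi[hd[chords]]))) else 0
  list(node_cm3s = node_res, cycle_mmHg = cgs_to_mmhg(cyc))
}

#' Total flow through the nidus
#'
#' Sums the signed flows on the arterial-side nidus boundary vessels (the
#' feeder pedicles plus the feeder end of the fistula). By conservation this
#' equals the venous-side boundary sum; `side` selects which one is
#' measured.
#'
#' @param solution a `trensh_flow`.
#' @param network the solved network.
#' @param side `"AF"` or `"DV"`.
#' @return total nidal flow in mL/min (positive = arterial-to-venous).
#' @export
total_nidal_flow <- function(solution, network, side = c("AF", "DV")) {
  side <- match.arg(side)
  b <- boundary_edges(network)
  idx <- if (side == "AF") b$af else b$dv
  flow_to_ml_min(sum(solution$flow_cm3s[idx]))
}

# indices of arterial-side and venous-side nidus boundary vessels
boundary_edges <- function(network) {
  v <- network$vessels
  ped <- !is.na(match(v$class, c("af_pedicle", "dv_pedicle")))
  af <- which(v$class == "af_pedicle")
  dv <- which(v$class == "dv_pedicle")
  fist <- which(v$category == "intranidal-fistula")
  if (length(fist)) {
    af <- c(af, fist[v$tail[fist] %in% c("AF1", "AF2", "AF3", "AF4")])
    dv <- c(dv, fist[v$head[fist] %in% c("DV1", "DV2", "DV3")])
  }
  list(af = af, dv = dv)
}

#' @export
print.trensh_flow <- function(x, ...) {
  cat(sprintf("<trensh_flow> %s\n", x$pressure_set$id))
  cat(sprintf("  vessels: %d, |Q| range %.4g..%.4g cm^3/s\n",
              length(x$flow_cm3s), min(abs(x$flow_cm3s)), max(abs(x$flow_cm3s))))
  invisible(x)
}
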