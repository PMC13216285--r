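# Toy circuits and independent oracles used across the suite.

# Minimal hand-built network the solver accepts: `emfs` must contain the two
# boundary rows (ESP at the arterial root, ECVP at the venous outlet) and any
# series EMF rows referenced by the pressure set.
toy_network <- function(vessels, source_node, sink_node, series = NULL) {
  node_ids <- unique(c(vessels$tail, vessels$head))
  nodes <- data.frame(
    id = node_ids,
    role = ifelse(node_ids %in% c(source_node, sink_node),
                  "source-terminal", "junction"),
    x = seq_along(node_ids), y = 0,
    compartment = NA_integer_, column = NA_integer_,
    stringsAsFactors = FALSE
  )
  emfs <- data.frame(
    id = c("ESP", "ECVP"),
    attached_edge = c(vessels$id[1], vessels$id[nrow(vessels)]),
    kind = "boundary",
    node = c(source_node, sink_node),
    orientation = 1,
    stringsAsFactors = FALSE
  )
  if (!is.null(series)) emfs <- rbind(emfs, series)
  trensh:::new_network(nodes, vessels, emfs)
}

toy_vessels <- function(tail, head, R, id = NULL, category = "extranidal-artery") {
  n <- length(tail)
  if (is.null(id)) id <- sprintf("v%02d", seq_len(n))
  # store a geometry consistent with the requested resistance at mu = 0.035
  radius <- 0.05
  length_cm <- R * pi * radius^4 / (8 * 0.035)
  data.frame(id = id, tail = tail, head = head, class = "toy",
             length_cm = length_cm, radius_cm = radius, resistance = R,
             category = rep_len(category, n),
             compartment = NA_integer_, column = NA_integer_,
             kind = "toy", stringsAsFactors = FALSE)
}

# a pressure set driving the toy: only emf_mmHg and tbo are consulted
toy_set <- function(esp = 10, ecvp = 0, ..., tbo = "none") {
  extra <- c(...)
  emf <- c(ESP = esp, EAF1 = 0, EAF2 = 0, EAF3 = 0, EAF4 = 0,
           EDV1 = 0, EDV2 = 0, EDV3 = 0, ECVP = ecvp)
  emf[names(extra)] <- extra
  structure(list(emf_mmHg = emf, hypotension = "normo", cvp = "normal",
                 tbo = tbo, injection_site = NA_character_,
                 injection_mmHg = 0, phase = "intermediate",
                 id = "toy"),
            class = "trensh_pressure_set")
}

# Independent dense nodal-potential oracle: assembles the full Laplacian with
# plain loops and solves with base R. Deliberately shares no code with the
# package solver.
dense_flow_oracle <- function(network, set) {
  v <- network$vessels
  nid <- network$nodes$id
  nn <- length(nid)
  emf_cgs <- trensh::mmhg_to_cgs(set$emf_mmHg)
  series <- network$emfs[network$emfs$kind == "series", , drop = FALSE]
  E <- numeric(nrow(v))
  if (nrow(series)) {
    for (r in seq_len(nrow(series))) {
      k <- which(v$id == series$attached_edge[r])
      E[k] <- E[k] + series$orientation[r] * emf_cgs[[series$id[r]]]
    }
  }
  d_sys <- which(nid == network$emfs$node[network$emfs$id == "ESP"])
  d_cvp <- which(nid == network$emfs$node[network$emfs$id == "ECVP"])
  fixed <- c(d_sys, d_cvp)
  pfix <- c(emf_cgs[["ESP"]], emf_cgs[["ECVP"]])

  A <- matrix(0, nn, nn)
  b <- numeric(nn)
  for (k in seq_len(nrow(v))) {
    i <- which(nid == v$tail[k]); j <- which(nid == v$head[k])
    g <- 1 / v$resistance[k]
    A[i, i] <- A[i, i] + g; A[j, j] <- A[j, j] + g
    A[i, j] <- A[i, j] - g; A[j, i] <- A[j, i] - g
    b[i] <- b[i] - g * E[k]; b[j] <- b[j] + g * E[k]
  }
  free <- setdiff(seq_len(nn), fixed)
  bb <- b[free] - A[free, fixed, drop = FALSE] %*% pfix
  p <- numeric(nn)
  p[fixed] <- pfix
  p[free] <- solve(A[free, free, drop = FALSE], bb)
  q <- numeric(nrow(v))
  for (k in seq_len(nrow(v))) {
    i <- which(nid == v$tail[k]); j <- which(nid == v$head[k])
    q[k] <- (p[i] + E[k] - p[j]) / v$resistance[k]
  }
  list(flow_cm3s = q, node_pressure_mmHg = trensh::cgs_to_mmhg(p))
}

# random connected resistor network with a few series EMFs
random_toy_network <- function(n_nodes, n_extra_edges, seed) {
  set.seed(seed)
  ids <- sprintf("n%02d", seq_len(n_nodes))
  tail <- head <- character(0)
  for (i in 2:n_nodes) {       # random spanning tree
    tail <- c(tail, ids[sample.int(i - 1, 1)])
    head <- c(head, ids[i])
  }
  for (k in seq_len(n_extra_edges)) {
    ab <- sample.int(n_nodes, 2)
    tail <- c(tail, ids[ab[1]]); head <- c(head, ids[ab[2]])
  }
  R <- stats::runif(length(tail), 100, 10000)
  v <- toy_vessels(tail, head, R)
  series <- data.frame(
    id = c("EAF1", "EDV1"),
    attached_edge = sample(v$id, 2),
    kind = "series", node = NA_character_,
    orientation = c(1, -1), stringsAsFactors = FALSE)
  toy_network(v, ids[1], ids[n_nodes], series = series)
}

# Exhaustive reachability oracle: adjacency-matrix powers over the
# flow-oriented graph (independent of the package's frontier BFS).
reach_oracle <- function(n_nodes, tails, heads, root) {
  A <- matrix(FALSE, n_nodes, n_nodes)
  A[cbind(tails, heads)] <- TRUE
  reach <- rep(FALSE, n_nodes)
  reach[root] <- TRUE
  for (step in seq_len(n_nodes)) {
    nxt <- reach | apply(A & matrix(reach, n_nodes, n_nodes), 2, any)
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  reach
}

# small config for fast full-model tests: forces the smallest nidus
small_config <- function(...) {
  sim_config(nidus = list(compartments = c(mean = 3, sd = 0, low = 3, high = 3),
                          columns = c(mean = 3, sd = 0, low = 3, high = 3),
                          nodes_end = c(6L, 8L), nodes_interior = c(8L, 10L)),
             ...)
}
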