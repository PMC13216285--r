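test_that("two equal resistances in series reproduce the hand-derived solution", {
  R <- 2000
  v <- toy_vessels(c("A", "M"), c("M", "B"), c(R, R))
  net <- toy_network(v, "A", "B")
  sol <- solve_flow(net, toy_set(esp = 10, ecvp = 0))[[1]]
  expect_equal(unname(sol$flow_cm3s), rep(10 * 1333.22 / (2 * R), 2),
               tolerance = 1e-12)
  expect_equal(unname(node_pressures(sol)["M"]), 5, tolerance = 1e-12)
})

test_that("no pressure gradient means no flow", {
  v <- toy_vessels(c("A", "M", "M"), c("M", "B", "B"), c(500, 800, 1200))
  net <- toy_network(v, "A", "B")
  sol <- solve_flow(net, toy_set(esp = 7, ecvp = 7))[[1]]
  expect_equal(max(abs(sol$flow_cm3s)), 0, tolerance = 1e-12)
})

test_that("flows are linear in the EMF vector (superposition)", {
  net <- random_toy_network(12, 10, seed = 4)
  sA <- toy_set(esp = 10, ecvp = 2, EAF1 = 3)
  sB <- toy_set(esp = 5, ecvp = 1, EDV1 = 7)
  sAB <- toy_set(esp = 15, ecvp = 3, EAF1 = 3, EDV1 = 7)
  sol <- solve_flow(net, list(sA, sB, sAB))
  expect_equal(sol[[1]]$flow_cm3s + sol[[2]]$flow_cm3s, sol[[3]]$flow_cm3s,
               tolerance = 1e-9)
})

test_that("batched and one-at-a-time solves agree bit-compatibly", {
  net <- random_toy_network(15, 12, seed = 6)
  sets <- list(toy_set(10), toy_set(20, ecvp = 3), toy_set(30, EAF1 = 5))
  batched <- solve_flow(net, sets)
  for (i in seq_along(sets)) {
    single <- solve_flow(net, sets[i])[[1]]
    expect_equal(batched[[i]]$flow_cm3s, single$flow_cm3s, tolerance = 1e-12)
  }
})

test_that("solver matches the independent dense nodal oracle on random networks", {
  for (seed in 1:8) {
    net <- random_toy_network(sample(6:20, 1), sample(3:25, 1), seed = seed)
    set <- toy_set(esp = runif(1, 5, 80), ecvp = runif(1, 0, 8),
                   EAF1 = runif(1, 0, 10), EDV1 = runif(1, 0, 20))
    sol <- solve_flow(net, set)[[1]]
    ora <- dense_flow_oracle(net, set)
    scale <- max(abs(ora$flow_cm3s), 1e-12)
    expect_lt(max(abs(sol$flow_cm3s - ora$flow_cm3s)) / scale, 1e-8)
    expect_equal(unname(sol$node_pressure_mmHg), ora$node_pressure_mmHg,
                 tolerance = 1e-8)
  }
})

test_that("Kirchhoff residuals vanish on the full AVM model", {
  cfg <- sim_config()
  net <- attach_nidus(build_extranidal_template(cfg), sample_architecture(31, cfg))
  sets <- list(pressure_set(config = cfg),
               pressure_set("profound", "high", "AF2",
                            list(site = "DV2", pressure_mmHg = 30), config = cfg))
  sols <- solve_flow(net, sets)
  for (sol in sols) {
    kr <- kirchhoff_residuals(sol, net)
    expect_lt(kr$node_cm3s, 1e-9 * max(abs(sol$flow_cm3s), 1))
    expect_lt(kr$cycle_mmHg, 1e-9)
  }
})

test_that("per-vessel drop satisfies dP = R*Q and boundary sums conserve", {
  cfg <- sim_config()
  net <- attach_nidus(build_extranidal_template(cfg), sample_architecture(32, cfg))
  sol <- solve_flow(net, pressure_set("moderate", config = cfg))[[1]]
  expect_equal(mmhg_to_cgs(sol$dp_mmHg),
               net$vessels$resistance * sol$flow_cm3s, tolerance = 1e-9)
  expect_equal(total_nidal_flow(sol, net, "AF"), total_nidal_flow(sol, net, "DV"),
               tolerance = 1e-9 * abs(total_nidal_flow(sol, net, "AF")))
  # pressures fall along the (EMF-free) arterial tree toward the nidus
  p <- node_pressures(sol)
  expect_true(p["sys_root"] > p["n_cca"])
  expect_true(p["n_cca"] > p["n_ica"])
  expect_true(p["n_ica"] > p["n_mca"])
  # nidus-entry pressures exceed nidus-exit pressures without injection
  expect_true(mean(p[c("AF1", "AF2", "AF3", "AF4")]) >
              mean(p[c("DV1", "DV2", "DV3")]))
})

test_that("feeder occlusion never increases total throughput on a toy with one source", {
  # two parallel feeders from one source into a shared drainage
  v <- toy_vessels(c("A", "A", "F1", "F2", "N"),
                   c("F1", "F2", "N", "N", "B"),
                   c(1000, 2000, 500, 500, 800))
  net <- toy_network(v, "A", "B")
  q_all <- solve_flow(net, toy_set(esp = 20))[[1]]
  net_cut <- net
  net_cut$vessels <- net_cut$vessels[net_cut$vessels$id != "v01", ]
  q_cut <- solve_flow(net_cut, toy_set(esp = 20))[[1]]
  total <- function(s, vv) sum(s$flow_cm3s[match("v05", vv$vessels$id)])
  expect_lt(total(q_cut, net_cut), total(q_all, net))
})

test_that("TBO removes the feeder edge and is reported as occluded", {
  cfg <- sim_config()
  net <- attach_nidus(build_extranidal_template(cfg), sample_architecture(33, cfg))
  sol <- solve_flow(net, pressure_set(tbo = "AF2", config = cfg))[[1]]
  expect_equal(sol$occluded, "af2")
  expect_equal(unname(sol$flow_cm3s[match("af2", sol$vessel_id)]), 0)
})
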