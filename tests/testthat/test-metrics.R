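# toy: A -(feeder pedicle)-> N1 -> N2 -> N3 -> N4 -(vein pedicle)-> B
chain_toy <- function(R = 1000) {
  v <- rbind(
    toy_vessels("A", "N1", R, id = "af", category = "AF"),
    toy_vessels(c("N1", "N2", "N3"), c("N2", "N3", "N4"), R,
                id = c("p1", "p2", "p3"), category = "intranidal-plexiform"),
    toy_vessels("N4", "B", R, id = "dv", category = "DV")
  )
  v$class[v$id == "af"] <- "af_pedicle"
  v$class[v$id == "dv"] <- "dv_pedicle"
  series <- data.frame(id = "EDV1", attached_edge = "dv", kind = "series",
                       node = NA_character_, orientation = -1,
                       stringsAsFactors = FALSE)
  toy_network(v, "A", "B", series = series)
}

test_that("ingress filling on a chain: full reversal fills all, weak injection none", {
  net <- chain_toy()
  # strong retrograde injection reverses the whole chain
  sol <- solve_flow(net, toy_set(esp = 10, EDV1 = 60))[[1]]
  expect_true(all(sol$flow_cm3s[2:4] < 0))
  f <- ingress_filling(sol, net, injection_site = "B")
  expect_setequal(f$vessels, c("p1", "p2", "p3"))
  expect_equal(percent_filling(f, net), 100)
  # injection too weak to reverse anything fills nothing
  sol0 <- solve_flow(net, toy_set(esp = 10, EDV1 = 1))[[1]]
  expect_true(all(sol0$flow_cm3s > 0))
  f0 <- ingress_filling(sol0, net, injection_site = "B")
  expect_length(f0$vessels, 0L)
  expect_error(ingress_filling(sol, net, injection_site = "nope"),
               "injection site")
})

test_that("egress closure is idempotent, empty-safe, and matches brute force", {
  # two-path nidus: N1 splits to N2/N3, rejoins at N4, with a side chain
  v <- rbind(
    toy_vessels("A", "N1", 500, id = "af", category = "AF"),
    toy_vessels(c("N1", "N1", "N2", "N3", "N2", "N5"),
                c("N2", "N3", "N4", "N4", "N5", "N4"),
                c(800, 900, 800, 900, 700, 700),
                id = paste0("p", 1:6), category = "intranidal-plexiform"),
    toy_vessels("N4", "B", 500, id = "dv", category = "DV")
  )
  v$class[v$id == "af"] <- "af_pedicle"
  v$class[v$id == "dv"] <- "dv_pedicle"
  net <- toy_network(v, "A", "B")
  base <- solve_flow(net, toy_set(esp = 20))[[1]]

  ing <- trensh:::new_filled("p1", "B", "none", "ingress")
  fin <- egress_closure(base, ing, net)
  # brute-force oracle: literal fixed-point application of the joining rule
  flows <- stats::setNames(base$flow_cm3s, base$vessel_id)
  tails <- stats::setNames(v$tail, v$id); heads <- stats::setNames(v$head, v$id)
  origin <- ifelse(flows > 0, tails, heads)[v$id]
  endpt <- ifelse(flows > 0, heads, tails)[v$id]
  intra <- v$id[v$category == "intranidal-plexiform"]
  filled <- "p1"
  repeat {
    add <- intra[origin[intra] %in% endpt[filled] & !(intra %in% filled)]
    if (!length(add)) break
    filled <- c(filled, add)
  }
  expect_setequal(fin$vessels, filled)
  # idempotence
  fin2 <- egress_closure(base, fin, net)
  expect_setequal(fin2$vessels, fin$vessels)
  # empty ingress stays empty
  fe <- egress_closure(base, trensh:::new_filled(character(0), "B", "none", "ingress"), net)
  expect_length(fe$vessels, 0L)
  # topology mismatch is rejected
  ing_tbo <- trensh:::new_filled("p1", "B", "AF1", "ingress")
  expect_error(egress_closure(base, ing_tbo, net), "consistency error")
})

test_that("rupture risk matches the closed form at its anchors", {
  expect_equal(rupture_risk(4), 0)
  expect_equal(rupture_risk(74), 100)
  # logarithmic midpoint: sqrt(4*74) ~ 17.205 -> 50%
  expect_equal(rupture_risk(sqrt(4 * 74)), 50, tolerance = 1e-12)
  # clamped to [0, 100] outside the anchor range
  expect_equal(rupture_risk(2), 0)
  expect_equal(rupture_risk(200), 100)
  expect_true(all(diff(rupture_risk(seq(4, 74, by = 1))) >= 0))
  expect_error(rupture_risk(0), "domain error")
  expect_error(rupture_risk(-3), "domain error")
  expect_error(rupture_risk(10, list(p_min = 5, p_max = 5)), "p_min")
})

test_that("uniform per-vessel drops give mean = max = rupture_risk(drop)", {
  net <- chain_toy(R = 3000)
  sol <- solve_flow(net, toy_set(esp = 40))[[1]]
  dp <- abs(sol$dp_mmHg[2:4])
  expect_equal(max(dp) - min(dp), 0, tolerance = 1e-12)
  rs <- nidus_risk_summary(sol, net, risk = list(p_min = 4, p_max = 74, pexp = "drop"))
  expect_equal(rs$mean_pct, rs$max_pct)
  expect_equal(rs$mean_pct, unname(rupture_risk(dp[1])))
})

test_that("ingress reachability equals the exhaustive matrix-power oracle", {
  for (seed in c(41, 42, 43, 44)) {
    net <- random_toy_network(10, sample(5:18, 1), seed)
    # mark everything except the boundary edges as intranidal
    w <- nrow(net$vessels)
    net$vessels$category[2:(w - 1)] <- "intranidal-plexiform"
    sol <- solve_flow(net, toy_set(esp = runif(1, 10, 50),
                                   EDV1 = runif(1, 0, 40)))[[1]]
    root_id <- net$nodes$id[sample.int(nrow(net$nodes), 1)]
    f <- ingress_filling(sol, net, injection_site = root_id)
    # oracle on the flow-oriented traversable graph
    q <- sol$flow_cm3s
    trav <- (net$vessels$category == "intranidal-plexiform" |
             net$vessels$class %in% c("af_pedicle", "dv_pedicle")) &
            abs(q) > 1e-12
    t_idx <- match(net$vessels$tail, net$nodes$id)
    h_idx <- match(net$vessels$head, net$nodes$id)
    ot <- ifelse(q > 0, t_idx, h_idx)[trav]
    oh <- ifelse(q > 0, h_idx, t_idx)[trav]
    reach <- reach_oracle(nrow(net$nodes), ot, oh,
                          match(root_id, net$nodes$id))
    origin <- ifelse(q > 0, t_idx, h_idx)
    expected <- net$vessels$id[net$vessels$category == "intranidal-plexiform" &
                               abs(q) > 1e-12 & reach[origin]]
    expect_setequal(f$vessels, expected)
  }
})

test_that("animation frames follow the ingress/exit rules and terminate", {
  cfg <- small_config()
  net <- attach_nidus(build_extranidal_template(cfg), sample_architecture(3, cfg))
  scen <- pressure_set("profound", "normal", "none",
                       list(site = "DV2", pressure_mmHg = 12), config = cfg)
  frames <- animation_frames(net, scen, target_injection = 12, config = cfg)
  ing <- Filter(function(f) f$phase == "ingress", frames)
  expect_length(ing, 13L)  # 0..12 inclusive
  expect_equal(vapply(ing, `[[`, 1, "injection_mmHg"), 0:12)
  # exit frames: each equals the frame rule applied to its predecessor
  base <- solve_flow(net, pressure_set("profound", "normal", config = cfg))[[1]]
  q <- stats::setNames(base$flow_cm3s, base$vessel_id)
  v <- net$vessels
  intra <- v$category %in% c("intranidal-plexiform", "intranidal-fistula")
  active <- intra & abs(q[v$id]) > 1e-12
  orig <- ifelse(q[v$id] > 0, v$tail, v$head)
  endp <- ifelse(q[v$id] > 0, v$head, v$tail)
  ex <- Filter(function(f) f$phase == "exit", frames)
  prev <- ing[[length(ing)]]$vessels
  for (f in ex) {
    expected <- v$id[active & orig %in% endp[match(prev, v$id)]]
    expect_setequal(f$vessels, expected)
    prev <- f$vessels
  }
  expect_error(animation_frames(net, scen, -1, cfg), "parameter error")
})
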