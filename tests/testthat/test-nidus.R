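cfg <- sim_config()

test_that("truncated-normal integer draws respect their bounds and limits", {
  set.seed(1)
  x <- rtrunc_norm_int(1e5, 4.5, 1, 3, 6)
  expect_true(all(x %in% 3:6))
  # symmetric around 4.5: mass at 4 and 5 equal to ~1%
  tab <- table(x) / length(x)
  expect_equal(unname(tab["4"]), unname(tab["5"]), tolerance = 0.03)
  expect_true(all(rtrunc_norm_int(50, 5, 0, 3, 7) == 5L))
  expect_error(rtrunc_norm_int(1, 5, 1, 7, 3), "low > high")
})

test_that("truncated draws match a direct rejection-sampling oracle", {
  set.seed(2)
  x <- rtrunc_norm_int(1e5, 5, 1, 3, 7)
  # oracle: raw normal draws, rounded, restricted
  set.seed(99)
  raw <- round(rnorm(4e5, 5, 1))
  raw <- raw[raw >= 3 & raw <= 7][1:1e5]
  px <- table(factor(x, levels = 3:7)) / length(x)
  po <- table(factor(raw, levels = 3:7)) / length(raw)
  expect_equal(as.numeric(px), as.numeric(po), tolerance = 0.02)
  expect_equal(names(which.max(px)), "5")
})

test_that("architecture sampling is deterministic and respects its invariants", {
  a <- sample_architecture(11, cfg)
  b <- sample_architecture(11, cfg)
  expect_identical(a$vessels, b$vessels)
  expect_identical(a$nodes, b$nodes)
  expect_identical(a$pedicles, b$pedicles)

  for (seed in c(3, 14, 158)) {
    nid <- sample_architecture(seed, cfg)
    C <- nid$n_compartments; K <- nid$n_columns
    expect_true(C >= 3 && C <= 6)
    expect_true(K >= 3 && K <= 7)
    v <- nid$vessels
    # exact intercompartmental count and cross-compartment endpoints
    ic <- v[v$kind == "intercompartmental", ]
    expect_equal(nrow(ic), 2L * C * K)
    comp_of <- stats::setNames(nid$nodes$compartment, nid$nodes$id)
    col_of <- stats::setNames(nid$nodes$column, nid$nodes$id)
    expect_true(all(comp_of[ic$tail] != comp_of[ic$head]))
    expect_true(all(col_of[ic$tail] != col_of[ic$head]))
    # no self loops anywhere
    expect_true(all(v$tail != v$head))
    # intracompartmental skeleton is layered by column (a DAG)
    intra <- v[v$kind == "intracompartmental", ]
    expect_true(all(comp_of[intra$tail] == comp_of[intra$head]))
    expect_true(all(col_of[intra$head] - col_of[intra$tail] == 1))
    # every node has an incoming vessel from the previous column (or is in
    # column 1) and an outgoing vessel to the next (or is in the last column)
    need_in <- nid$nodes$id[nid$nodes$column > 1]
    expect_true(all(need_in %in% intra$head))
    need_out <- nid$nodes$id[nid$nodes$column < K]
    expect_true(all(need_out %in% intra$tail))
    # fistula: starts at AF2, ends at DV2, one node per column of the middle
    # compartment, larger radius than the plexiform vessels
    f <- v[v$kind == "fistula", ]
    expect_equal(nrow(f), K + 1L)
    expect_equal(f$tail[1], "AF2")
    expect_equal(f$head[nrow(f)], "DV2")
    mid_nodes <- f$head[-nrow(f)]
    expect_true(all(comp_of[mid_nodes] == nid$middle_compartment))
    expect_equal(sort(unname(col_of[mid_nodes])), seq_len(K))
    expect_true(min(f$radius_cm) >
                max(v$radius_cm[v$category == "intranidal-plexiform"]))
    # boundary attachments: every first-column node has exactly one feeder
    # pedicle, every last-column node one vein pedicle; no terminal is bare
    ped <- nid$pedicles
    first <- nid$nodes$id[nid$nodes$column == 1]
    last <- nid$nodes$id[nid$nodes$column == K]
    af_heads <- ped$head[ped$class == "af_pedicle"]
    dv_tails <- ped$tail[ped$class == "dv_pedicle"]
    expect_true(all(first %in% af_heads))
    expect_true(all(table(af_heads[af_heads %in% first]) == 1))
    expect_true(all(last %in% dv_tails))
    expect_true(all(table(dv_tails[dv_tails %in% last]) == 1))
    expect_true(all(paste0("DV", 1:3) %in% ped$head[ped$class == "dv_pedicle"]))
    expect_true(all(paste0("AF", 1:4) %in% ped$tail[ped$class == "af_pedicle"]))
  }
})

test_that("forced 3x3 configuration gives exactly 18 intercompartmental vessels", {
  nid <- sample_architecture(5, small_config())
  expect_equal(nid$n_compartments, 3L)
  expect_equal(nid$n_columns, 3L)
  expect_equal(sum(nid$vessels$kind == "intercompartmental"), 18L)
})

test_that("intercompartmental end columns follow the excluded-center normal", {
  set.seed(8)
  draws <- replicate(4e4, trensh:::rtrunc_norm_int_excl(1, 4, 2, 1, 7, 4))
  expect_true(all(draws != 4) && all(draws >= 1) && all(draws <= 7))
  # rejection-sampling oracle for the same law
  set.seed(9)
  raw <- round(rnorm(4e5, 4, 2))
  raw <- raw[raw >= 1 & raw <= 7 & raw != 4][1:4e4]
  pd <- table(factor(draws, levels = c(1:3, 5:7))) / length(draws)
  po <- table(factor(raw, levels = c(1:3, 5:7))) / length(raw)
  expect_equal(as.numeric(pd), as.numeric(po), tolerance = 0.025)
})

test_that("every sampled architecture yields a solvable flow system", {
  tpl <- build_extranidal_template(cfg)
  for (seed in c(21, 22, 23)) {
    net <- attach_nidus(tpl, sample_architecture(seed, cfg))
    sol <- solve_flow(net, pressure_set(config = cfg))[[1]]
    expect_true(all(is.finite(sol$flow_cm3s)))
    expect_true(total_nidal_flow(sol, net) > 0)
  }
})
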