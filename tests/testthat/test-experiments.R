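cfg_small <- small_config()

test_that("the batch runner yields one row per architecture and scenario", {
  tab <- run_main_grid(2, seed = 5, config = cfg_small)
  expect_equal(nrow(tab), 2L * 320L)
  expect_equal(length(unique(tab$arch_seed)), 2L)
  # grid completeness: every scenario appears exactly once per architecture
  key <- with(tab, paste(arch_seed, hypotension, cvp, tbo, site, injection_mmHg))
  expect_equal(anyDuplicated(key), 0L)
  # no-injection rows carry no filling; injection rows always do
  expect_true(all(is.na(tab$pct_filling[is.na(tab$site)])))
  expect_true(all(!is.na(tab$pct_filling[!is.na(tab$site)])))
  # deterministic rerun
  tab2 <- run_main_grid(2, seed = 5, config = cfg_small)
  expect_identical(tab, tab2)
})

test_that("aggregation reports group means, SDs and sizes", {
  tab <- run_main_grid(2, seed = 5, config = cfg_small)
  inj <- tab[!is.na(tab$site) & tab$tbo == "none", ]
  a <- aggregate_results(inj, by = c("hypotension", "injection_mmHg", "cvp"),
                         metrics = "pct_filling")
  # sites aggregated: per-group n = 3 sites x n_architectures
  expect_true(all(a$n == 3L * 2L))
  expect_equal(nrow(a), 4L * 3L * 2L)
  one <- aggregate_results(tab[1, ], by = "hypotension",
                           metrics = "total_flow_ml_min")
  expect_equal(one$mean_total_flow_ml_min, tab$total_flow_ml_min[1])
  expect_equal(one$sd_total_flow_ml_min, 0)
  expect_error(aggregate_results(tab, by = "nonexistent"), "unknown field")
})

test_that("group comparison reproduces the pooled t-test by hand", {
  tab <- data.frame(hypotension = rep(c("a", "b"), each = 3),
                    y = c(1, 2, 3, 4, 5, 6))
  r <- compare_groups(tab, "y", "hypotension")
  expect_equal(unname(r$statistic), -3.674, tolerance = 1e-3)
  expect_equal(r$p_value, 0.0214, tolerance = 1e-2)
  expect_equal(unname(r$df), 4)
  expect_true(r$significant)
  # identical groups: t = 0, p = 1
  tab0 <- data.frame(g = rep(c("a", "b"), each = 3), y = rep(c(1, 2, 3), 2))
  r0 <- compare_groups(tab0, "y", "g")
  expect_equal(unname(r0$statistic), 0)
  expect_equal(r0$p_value, 1)
  # three groups go through one-way ANOVA
  tab3 <- data.frame(g = rep(c("a", "b", "c"), each = 4),
                     y = c(rnorm(4, 0), rnorm(4, 3), rnorm(4, 6)))
  r3 <- compare_groups(tab3, "y", "g")
  expect_match(r3$method, "ANOVA")
  expect_length(r3$group_means, 3L)
  expect_error(compare_groups(tab[1:2, ], "y", "hypotension"),
               "insufficient data")
})

test_that("sensitivity analysis respects the jitter bounds", {
  s0 <- sensitivity_analysis(2, jitter = 0, seed = 9, config = cfg_small)
  # jitter 0 reproduces the unperturbed generator's flows
  tpl <- build_extranidal_template(cfg_small)
  net <- attach_nidus(tpl, sample_architecture(10, cfg_small))
  sol <- solve_flow(net, pressure_set(config = cfg_small))[[1]]
  expect_equal(s0$flows_ml_min[1], total_nidal_flow(sol, net), tolerance = 1e-9)
  s1 <- sensitivity_analysis(3, jitter = 0.10, seed = 9, config = cfg_small)
  expect_length(s1$flows_ml_min, 3L)
  expect_true(all(s1$flows_ml_min > 0))
  expect_equal(s1$min, min(s1$flows_ml_min))
  expect_error(sensitivity_analysis(2, jitter = 0.6, config = cfg_small))
})

test_that("the phase study orders filling diastole >= systole and nests the standard grid", {
  ps <- phase_study(n_architectures = 3, seed = 2, pressures = c(24, 27),
                    hypotension = "moderate", config = cfg_small)
  expect_equal(nrow(ps$table), 3L * 2L * 3L)
  # intermediate phase equals the standard grid at matching settings
  std <- run_main_grid(3, seed = 2, config = cfg_small,
                       grid = list(pressure_set("moderate", "normal", "none",
                                                list(site = "DV1", pressure_mmHg = 24),
                                                "intermediate", cfg_small)))
  inter <- ps$table[ps$table$phase == "intermediate" & ps$table$injection_mmHg == 24, ]
  expect_equal(inter$pct_filling, std$pct_filling, tolerance = 1e-12)
  # mean filling: diastole >= systole in the sweep range
  m <- tapply(ps$table$pct_filling, ps$table$phase, mean)
  expect_gte(m["diastole"], m["systole"])
})
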