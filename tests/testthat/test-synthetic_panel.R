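test_that("simulation configs validate their parameters", {
  expect_error(simulation_config(attrition = 1.5),
               class = "randelphi_config_error")
  expect_error(simulation_config(n_modified = 99),
               class = "randelphi_config_error")
  expect_error(item_archetype("consensus"), class = "randelphi_config_error")
  expect_error(item_archetype("polarized", poles = c(0, 9)),
               class = "randelphi_config_error")
  cfg <- simulation_config(seed = 3)
  expect_length(cfg$archetypes, 20)
  expect_equal(cfg$n_modified, 13)
})

test_that("the bundled design-shape config loads and matches the study shape", {
  cfg <- read_simulation_config(
    system.file("extdata", "design_shape_simulation.yaml",
                package = "randelphi", mustWork = TRUE))
  expect_equal(cfg$n_panellists, 24L)
  expect_equal(cfg$n_items, 20L)
  expect_equal(cfg$n_modified, 13L)
  locs <- vapply(cfg$archetypes, `[[`, numeric(1), "location")
  expect_equal(sum(locs == 2), 15)
  expect_equal(sum(locs == 5), 5)
  expect_equal(24 * (1 - cfg$attrition), 19, tolerance = 1e-4)
})

test_that("the same seed reproduces the study byte for byte", {
  a <- simulate_study(simulation_config(seed = 99))
  b <- simulate_study(simulation_config(seed = 99))
  expect_identical(a$records, b$records)
  c <- simulate_study(simulation_config(seed = 100))
  expect_false(identical(a$records, c$records))
})

test_that("simulated studies have the configured shape and valid ratings", {
  study <- simulate_study(simulation_config(seed = 5))
  expect_true(all(study$records$rating %in% 1:9))
  roster <- dplyr::count(study$panellists, round)
  expect_equal(roster$n[1], 24)
  expect_lte(roster$n[2], 24)
  # round-2 roster is a subset of round 1
  expect_true(all(
    study$panellists$panellist_id[study$panellists$round == 2] %in%
      study$panellists$panellist_id[study$panellists$round == 1]))
  expect_equal(nrow(study$items), 33)
  expect_equal(nrow(study$lineage), 13)
  # every item carries the full roster of its round (no skips by default)
  per_item <- dplyr::count(study$records, item_id, round)
  expect_true(all(per_item$n[per_item$round == 1] == 24))
  expect_true(all(per_item$n[per_item$round == 2] == roster$n[2]))
})

test_that("adding items does not perturb existing items' draws", {
  small <- simulate_study(simulation_config(n_items = 5, n_modified = 0,
                                            seed = 7))
  big <- simulate_study(simulation_config(n_items = 8, n_modified = 0,
                                          seed = 7))
  for (id in unique(small$records$item_id)) {
    expect_identical(small$records$rating[small$records$item_id == id &
                                            small$records$round == 1],
                     big$records$rating[big$records$item_id == id &
                                          big$records$round == 1])
  }
})

test_that("a zero-dispersion consensus item is degenerate at its location", {
  arch <- replicate(1, item_archetype("consensus", 2, 0), simplify = FALSE)
  cfg <- simulation_config(n_items = 1, n_modified = 0, archetypes = arch,
                           seed = 2)
  study <- simulate_study(cfg)
  expect_true(all(study$records$rating == 2))
  s <- summarize_items(study)
  expect_true(all(s$di == 0))
  expect_true(all(classify(s$median, s$di)$label == "A/IA"))
})

test_that("attrition hits its expected round-2 panel size on average", {
  sizes <- vapply(1:300, function(i) {
    cfg <- simulation_config(n_items = 1, n_modified = 0, seed = 1000 + i)
    study <- simulate_study(cfg)
    sum(study$panellists$round == 2)
  }, numeric(1))
  expected <- 24 * (1 - 5 / 24)  # 19
  se <- sqrt(24 * (5 / 24) * (1 - 5 / 24) / 300)
  expect_lt(abs(mean(sizes) - expected), 3 * se)
})

test_that("the feedback shift moves round-2 ratings toward the round-1 median", {
  arch <- replicate(1, item_archetype("consensus", 3, 2), simplify = FALSE)
  pull_dist <- function(shift) {
    cfg <- simulation_config(n_items = 1, n_modified = 0, archetypes = arch,
                             feedback_shift = shift, seed = 31)
    study <- simulate_study(cfg)
    med1 <- median(study$records$rating[study$records$round == 1])
    mean(abs(study$records$rating[study$records$round == 2] - med1))
  }
  # with certain shift the round-2 panel sits (weakly) closer to the
  # round-1 median than with no shift, holding all draws fixed by seed
  expect_lte(pull_dist(1), pull_dist(0))
})

test_that("recovery_experiment reports coherent operating characteristics", {
  arch <- list(item_archetype("consensus", 2, 0),
               item_archetype("consensus", 2, 1),
               item_archetype("uniform"))
  oc <- recovery_experiment(arch, n_panellists = 24, replicates = 60,
                            seed = 12)
  expect_equal(nrow(oc), 3)
  expect_true(all(oc$p_agreement >= 0 & oc$p_agreement <= 1))
  expect_true(all(oc$accuracy >= 0 & oc$accuracy <= 1))
  # degenerate consensus is always recovered exactly
  expect_equal(oc$accuracy[1], 1)
  expect_equal(oc$mean_di[1], 0)
  # structureless panels reach agreement far less often than tight consensus
  expect_lt(oc$p_agreement[3], oc$p_agreement[2])
  expect_error(recovery_experiment(list(), replicates = 5),
               class = "randelphi_config_error")
  # reproducibility under a fixed seed
  oc2 <- recovery_experiment(arch, n_panellists = 24, replicates = 60,
                             seed = 12)
  expect_equal(oc, oc2)
})

test_that("classification accuracy is non-decreasing in panel size", {
  arch <- list(item_archetype("consensus", 2, 1))
  oc <- recovery_experiment(arch, n_panellists = c(6, 12, 24, 48),
                            replicates = 150, seed = 8)
  acc <- oc$accuracy[order(oc$n)]
  # common random numbers across n; allow one MC standard error of slack
  expect_true(all(diff(acc) >= -max(oc$se_accuracy)))
})
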