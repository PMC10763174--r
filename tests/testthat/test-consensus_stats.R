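test_that("percentile_score matches the stated plotting-position rules", {
  expect_equal(percentile_score(rep(2, 5), 0.30), 2)
  # hand evaluation of (n-1)q + 1 on 1..9 at q = 0.3: h = 3.4 -> 3.4
  expect_equal(percentile_score(1:9, 0.30), 3.4)
  expect_equal(percentile_score(1:9, 0.70), 6.6)
  # nearest rank and (n+1)q variants
  expect_equal(percentile_score(1:9, 0.30, method = "nearest"), 3)
  expect_equal(percentile_score(1:9, 0.30, method = "weibull"), 3)
  expect_error(percentile_score(integer(), 0.3),
               class = "randelphi_empty_panel")
  expect_error(percentile_score(1:9, 1.2), class = "randelphi_domain_error")
})

test_that("percentiles are permutation-invariant, bounded and reflective", {
  set.seed(7)
  for (i in 1:30) {
    x <- sample(1:9, sample(2:30, 1), replace = TRUE)
    q <- runif(1, 0.05, 0.95)
    p <- percentile_score(x, q)
    expect_equal(p, percentile_score(sample(x), q))
    expect_gte(p, min(x))
    expect_lte(p, max(x))
    # reflection: the default rule treats the scale ends symmetrically
    expect_equal(percentile_score(10L - x, 1 - q), 10 - p)
  }
})

test_that("disagreement_index follows IPR / (2.35 + 1.5 * |5 - IPRCP|)", {
  full <- disagreement_index(1, 9)
  expect_equal(full$ipr, 8)
  expect_equal(full$iprcp, 5)
  expect_equal(full$ai, 0)
  expect_equal(full$ipras, 2.35)
  expect_equal(full$di, 8 / 2.35)

  expect_equal(disagreement_index(2, 2)$di, 0)

  low <- disagreement_index(2, 3)
  expect_equal(low$ipr, 1)
  expect_equal(low$iprcp, 2.5)
  expect_equal(low$ipras, 6.10)
  expect_equal(low$di, 1 / 6.10, tolerance = 1e-12)

  expect_error(disagreement_index(3, 2), class = "randelphi_domain_error")
  expect_error(disagreement_index(0, 5), class = "randelphi_domain_error")
})

test_that("summarize_item populates the whole statistics block", {
  s <- summarize_item(rep(2L, 19))
  expect_equal(s$median, 2)
  expect_equal(s$p_low, 2)
  expect_equal(s$p_high, 2)
  expect_equal(s$di, 0)
  expect_equal(c(s$n_low, s$n_mid, s$n_high), c(19, 0, 0))

  half <- summarize_item(c(1, 1, 1, 9, 9, 9))
  expect_equal(half$median, 5)
  expect_lte(half$p_low, 3)
  expect_gte(half$p_high, 7)
  expect_gt(half$di, 1)

  x <- c(3L, 7L, 2L, 2L, 5L, 8L)
  expect_equal(summarize_item(x), summarize_item(rev(sort(x))))
  expect_error(summarize_item(integer()), class = "randelphi_empty_panel")
})

test_that("classification combines the DI threshold with the median bands", {
  expect_equal(classify(2, 0.203)$label, "A/IA")
  expect_equal(classify(5, 0.599)$label, "Neutral")
  expect_equal(classify(8, 0.2)$label, "A/A")
  expect_equal(classify(5, 3.40)$agreement, "disagreement")
  # DI exactly at the threshold counts as disagreement
  expect_equal(classify(2, 1)$label, "Disagreement")
  # half-integer medians fall with their nearest integers; edges to equivocal
  expect_equal(classify(2.5, 0.3)$band, "inappropriate")
  expect_equal(classify(4.5, 0.3)$band, "equivocal")
  expect_equal(classify(3.5, 0.3)$band, "equivocal")
  expect_equal(classify(6.5, 0.3)$band, "equivocal")
  expect_equal(classify(7, 0.3)$band, "appropriate")
})

test_that("label_classification inverts the label composition", {
  cls <- label_classification(c("A/IA", "Neutral", "A/A", "Disagreement"))
  expect_equal(cls$agreement,
               c("agreement", "agreement", "agreement", "disagreement"))
  expect_equal(cls$band,
               c("inappropriate", "equivocal", "appropriate", NA))
  expect_error(label_classification("??"), class = "randelphi_domain_error")
})

test_that("summarize_items aggregates per item and round, ignoring row order", {
  study <- rating_study(toy_records())
  summ <- summarize_items(study)
  expect_equal(nrow(summ), 4)  # 2 items x 2 rounds
  a1 <- summ[summ$item_id == "A" & summ$round == 1, ]
  expect_equal(a1$median, 2)
  expect_equal(a1$n, 4)

  shuffled <- toy_records()[sample(nrow(toy_records())), ]
  expect_equal(summarize_items(rating_study(shuffled)), summ)

  expect_error(summarize_items(study, dimension = "feasibility"),
               class = "randelphi_empty_panel")
})

test_that("reflection r -> 10 - r mirrors the summary and swaps bands", {
  set.seed(23)
  for (i in 1:30) {
    x <- sample(1:9, sample(3:24, 1), replace = TRUE)
    s <- summarize_item(x)
    r <- summarize_item(10L - x)
    expect_equal(r$median, 10 - s$median)
    expect_equal(r$ipr, s$ipr)
    expect_equal(r$ai, s$ai)
    expect_equal(r$ipras, s$ipras)
    expect_equal(r$di, s$di)
    expect_equal(c(r$n_low, r$n_mid, r$n_high), c(s$n_high, s$n_mid, s$n_low))
    band <- classify(s$median, s$di)$band
    mirrored <- classify(r$median, r$di)$band
    swap <- c(inappropriate = "appropriate", equivocal = "equivocal",
              appropriate = "inappropriate")
    expect_equal(mirrored, unname(swap[band]))
  }
})

test_that("adding a rating at the current median never increases the DI", {
  for (size in 2:4) {
    sets <- enumerate_multisets(size)
    for (j in seq_len(ncol(sets))) {
      x <- sets[, j]
      med <- median(x)
      if (med != round(med)) next  # nothing on the scale equals the median
      before <- summarize_item(x)$di
      after <- summarize_item(c(x, as.integer(med)))$di
      expect_lte(after, before + 1e-12)
    }
  }
})

test_that("config knobs change the statistics coherently", {
  cfg <- consensus_config(ipras_intercept = 3, ipras_slope = 1)
  expect_equal(disagreement_index(1, 9, cfg)$di, 8 / 3)
  wide <- consensus_config(q_low = 0.1, q_high = 0.9)
  s <- summarize_item(1:9, wide)
  expect_equal(s$p_low, 1.8)
  expect_equal(s$p_high, 8.2)
  expect_error(consensus_config(q_low = 0), class = "randelphi_config_error")
  expect_error(consensus_config(band_edges = c(7, 3)),
               class = "randelphi_config_error")
})

test_that("consensus configs round-trip through YAML and JSON", {
  cfg <- list(q_low = 0.25, q_high = 0.75, method = "weibull",
              di_threshold = 1.2)
  yml <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, yml)
  loaded <- read_consensus_config(yml)
  expect_equal(loaded$q_low, 0.25)
  expect_equal(loaded$method, "weibull")
  expect_equal(loaded$di_threshold, 1.2)

  jsn <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(cfg, jsn, auto_unbox = TRUE)
  expect_equal(read_consensus_config(jsn)$method, "weibull")

  bad <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(qq_low = 0.2), bad)
  expect_error(read_consensus_config(bad), class = "randelphi_config_error")
})
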