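test_that("a degenerate one-component scenario concentrates at its mean", {
  sc <- group_scenario("GW", 150, 2, p1 = 1, mu1 = 20, sd1 = 0.05,
                       mu2 = 20, sd2 = 0.05, outlier_rate = 0,
                       head_sd = 1e-6)
  sim <- simulate_group(sc, seed = 5)
  n <- nrow(sim$records)
  se <- 0.05 / sqrt(n)
  expect_lt(abs(mean(sim$records$weight) - 20), 3 * se + 1e-6)
})

test_that("simulation is reproducible and seed-sensitive", {
  sc <- group_scenario("MP", 225, 5, p1 = 0.9, mu1 = 53.6, sd1 = 10.1,
                       mu2 = 26.5, sd2 = 5.5)
  a <- simulate_group(sc, seed = 11)
  b <- simulate_group(sc, seed = 11)
  expect_identical(a$records, b$records)
  c <- simulate_group(sc, seed = 12)
  expect_false(identical(a$records, c$records))
})

test_that("group means track the mixture moments", {
  # a strongly right-weighted near-harvest mixture: mean 50.89 mg
  sc <- group_scenario("MP", 225, 5, p1 = 0.9, mu1 = 53.6, sd1 = 10.1,
                       mu2 = 26.5, sd2 = 5.5, n_heads = 5,
                       grains_range = c(60, 60), outlier_rate = 0,
                       head_sd = 0.01)
  sim <- simulate_group(sc, seed = 31)
  expect_equal(nrow(sim$records), 300)
  expect_lt(abs(mean(sim$records$weight) - 50.89), 1.5)

  # closed-form moment check on a large outlier-free group
  big <- group_scenario("GW", 300, 5, p1 = 0.5, mu1 = 41.1, sd1 = 11.4,
                        mu2 = 57.2, sd2 = 4.1, n_heads = 200,
                        grains_range = c(60, 60), outlier_rate = 0,
                        head_sd = 0)
  sim <- simulate_group(big, seed = 7)
  w <- sim$records$weight
  n <- length(w)
  m_true <- 0.5 * 41.1 + 0.5 * 57.2
  v_true <- 0.5 * (11.4^2 + 41.1^2) + 0.5 * (4.1^2 + 57.2^2) - m_true^2
  expect_gt(n, 1e4)
  expect_lt(abs(mean(w) - m_true), 4 * sqrt(v_true / n))
  # variance of the sample variance ~ (mu4 - v^2)/n; bound loosely via
  # normal-theory SE inflated for the mixture's heavier shape
  expect_lt(abs(var(w) - v_true), 6 * v_true * sqrt(2 / n))
})

test_that("positivity is enforced by redraw, not clipping", {
  sc <- group_scenario("SY", 150, 2, p1 = 0.5, mu1 = 2, sd1 = 3,
                       mu2 = 8, sd2 = 3, outlier_rate = 0)
  sim <- simulate_group(sc, seed = 3)
  expect_true(all(sim$records$weight > 0))
  # no point mass near zero
  expect_lt(mean(sim$records$weight < 1e-6), 0.01)
})

test_that("study simulation writes a round-trippable long-format table", {
  sc1 <- group_scenario("GW", 150, 4, 0.54, 34.3, 6.6, 49.1, 5.1)
  sc2 <- group_scenario("GW", 225, 4, 0.65, 39.0, 7.7, 52.6, 4.1)
  path <- tempfile(fileext = ".csv")
  out <- simulate_study(list(sc1, sc2), path, seed = 9)

  rec <- read_grain_table(path)
  expect_equal(nrow(rec), nrow(out$records))
  groups <- split_groups(rec)
  expect_equal(names(groups), c("GW_150kg_4WAH", "GW_225kg_4WAH"))
  expect_true(file.exists(out$manifest_path))
  manifest <- jsonlite::read_json(out$manifest_path)
  expect_equal(manifest$n_groups, 2L)

  expect_error(simulate_study(list(sc1, sc1), tempfile(), seed = 1),
               "duplicate")
})

test_that("the default study covers 36 groups with plausible sizes", {
  scen <- default_scenarios()
  expect_length(scen, 36)
  keys <- vapply(scen, function(s)
    group_label(s$cultivar, s$seeding_rate, s$wah), character(1))
  expect_equal(anyDuplicated(keys), 0L)
  expect_equal(keys, sort(keys))

  # one mid-sized group end to end: after selecting 5 heads and IQR
  # filtering, the size should sit in the 5-head x grains-per-head band
  sc <- scen[[which(keys == "GW_300kg_5WAH")]]
  sim <- simulate_group(sc, seed = 41)
  picked <- select_heaviest_heads(sim$records, 5)
  kept <- iqr_filter(picked$weight)$kept
  expect_gte(length(kept), 5 * 40)
  expect_lte(length(kept), 5 * 82)
})
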