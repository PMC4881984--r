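test_that("ph_index computes the engulfed fraction and guards its domain", {
  expect_equal(ph_index(15, 30), 0.5)
  expect_equal(ph_index(0, 7), 0)
  expect_equal(ph_index(12, 12), 1)
  expect_error(ph_index(0, 0, sample_id = "ctrl_01"),
               class = "phagoquant_undefined_metric")
  expect_error(ph_index(0, 0, sample_id = "ctrl_01"), "ctrl_01")
  expect_true(is.na(ph_index(0, 0, strict = FALSE)))
  expect_error(ph_index(5, 3), class = "phagoquant_validation_error")
  expect_error(ph_index(-1, 3), class = "phagoquant_validation_error")
})

test_that("ph_index recovers the engulfment probability of a binomial census", {
  withr::with_seed(101, {
    n <- 1e4
    engulfed <- rbinom(1, n, 0.9)
    expect_equal(ph_index(engulfed, n), 0.9, tolerance = 0.01)
  })
})

test_that("weighted capacity is the mean pouch load per microglia", {
  expect_equal(weighted_capacity(c(`1` = 15, `2` = 5), 100), 0.25)
  expect_equal(weighted_capacity(tibble::tibble(n_pouches = c(1, 2),
                                                count = c(15, 5)), 100), 0.25)
  expect_equal(weighted_capacity(numeric(0), 50), 0)
  expect_equal(weighted_capacity(c(`7` = 40), 40), 7)
  expect_error(weighted_capacity(c(`1` = 60), 50),
               class = "phagoquant_validation_error")
  expect_error(weighted_capacity(c(`0` = 5), 50),
               class = "phagoquant_validation_error")
  expect_error(weighted_capacity(c(`1` = 5), 0),
               class = "phagoquant_undefined_metric")
})

test_that("weighted capacity equals per-cell enumeration on random censuses", {
  withr::with_seed(42, {
    for (i in 1:200) {
      cc <- random_cell_census()
      expect_equal(weighted_capacity(cc$histogram, cc$n_microglia),
                   mean(cc$per_cell))
    }
  })
})

test_that("net phagocytosis multiplies microglia count by capacity", {
  expect_equal(net_phagocytosis(c(`1` = 15, `2` = 5), 100), 25)
  expect_equal(net_phagocytosis(numeric(0), 100), 0)
  # every microglia holding exactly one pouch gives the microglia count
  expect_equal(net_phagocytosis(c(`1` = 80), 80), 80)
  expect_equal(net_phagocytosis(c(`1` = 5), 0), 0)
})

test_that("Ph/A coupling ratio and its invariances", {
  expect_equal(ph_a_coupling(0.25, 100, 50), 0.5)
  # scaling net phagocytosis and apoptosis together leaves the ratio fixed
  expect_equal(ph_a_coupling(0.25, 300, 150), 0.5)
  expect_equal(ph_a_coupling(0.5, 100, 100), ph_a_coupling(0.5, 200, 200))
  expect_error(ph_a_coupling(0.25, 100, 0),
               class = "phagoquant_undefined_metric")
})

test_that("cell density divides count by volume and round-trips", {
  expect_equal(cell_density(150, 0.05), 3000)
  expect_equal(cell_density(0, 1), 0)
  expect_equal(cell_density(150, 0.05) * 0.05, 150)
  expect_error(cell_density(10, 0), class = "phagoquant_validation_error")
})

test_that("distance histogram bins half-open and normalizes", {
  h <- distance_histogram(c(0.2, 0.4, 5, 12, 0.3), c(0, 0.5, 3, 10))
  expect_equal(h$prop, c(0.6, 0, 0.2, 0.2))
  expect_equal(sum(h$n), 5)

  h0 <- distance_histogram(rep(0, 8))
  expect_equal(h0$prop[1], 1)

  withr::with_seed(7, {
    for (i in 1:20) {
      d <- runif(sample(1:50, 1), 0, 20)
      h <- distance_histogram(d)
      expect_equal(sum(h$prop), 1, tolerance = 1e-12)
      expect_equal(h$prop, distance_histogram(sample(d))$prop)
    }
  })
  expect_error(distance_histogram(numeric(0)),
               class = "phagoquant_undefined_metric")
  expect_error(distance_histogram(1:3, c(3, 1)),
               class = "phagoquant_validation_error")
})

test_that("linear_r2 matches the residual-sum definition", {
  expect_equal(linear_r2(1:10, 2 * (1:10) + 3), 1)
  withr::with_seed(11, {
    x <- rnorm(2000); y <- rnorm(2000)
    expect_lt(linear_r2(x, y), 0.01)
    x <- rnorm(15); y <- 1.5 * x + rnorm(15)
    fit <- lm(y ~ x)
    r2_direct <- 1 - sum(residuals(fit)^2) / sum((y - mean(y))^2)
    expect_equal(linear_r2(x, y), r2_direct)
  })
  expect_error(linear_r2(rep(1, 5), 1:5), class = "phagoquant_undefined_metric")
  expect_error(linear_r2(1:2, 1:2), class = "phagoquant_validation_error")
})

test_that("phagocytosis_summary computes per-sample metrics with baseline fold", {
  census <- tibble::tibble(
    sample_id = c("a", "b", "c"),
    group = c("control", "control", "challenge"),
    apo_total = c(20, 40, 60),
    apo_phagocytosed = c(18, 36, 54),
    microglia_total = c(100, 100, 100),
    region_volume_mm3 = 0.2
  )
  pouches <- tibble::tibble(
    sample_id = c("a", "b", "c", "c"),
    n_pouches = c(1, 1, 1, 2),
    count = c(18, 36, 40, 7)
  )
  s <- phagocytosis_summary(census, pouches, baseline = "control")
  expect_equal(s$ph_index, c(0.9, 0.9, 0.9))
  expect_equal(s$ph_capacity, c(0.18, 0.36, 0.54))
  expect_equal(s$net_phagocytosis, c(18, 36, 54))
  expect_equal(s$ph_a_raw, c(0.9, 0.9, 0.9))
  expect_equal(s$ph_a_fold, c(1, 1, 1))
  expect_equal(s$apo_density, c(100, 200, 300))
  expect_equal(s$microglia_density, rep(500, 3))
  # identical census twice gives identical summaries
  expect_identical(s, phagocytosis_summary(census, pouches, baseline = "control"))

  g <- phagocytosis_group_summary(s)
  expect_equal(sort(g$group), c("challenge", "control"))
  expect_equal(g$n_samples[g$group == "control"], 2L)
})

test_that("undefined metrics surface as NA with a reason, not as zero", {
  census <- tibble::tibble(
    sample_id = c("ca1", "dg"), group = "control",
    apo_total = c(0, 10), apo_phagocytosed = c(0, 9),
    microglia_total = c(50, 50), region_volume_mm3 = 0.1
  )
  s <- phagocytosis_summary(census)
  expect_true(is.na(s$ph_index[1]))
  expect_match(s$notes[1], "apo_total = 0")
  expect_equal(s$ph_index[2], 0.9)
})

test_that("census validation reports offending rows", {
  census <- tibble::tibble(
    sample_id = c("a", "b"), group = "g",
    apo_total = c(5, 5), apo_phagocytosed = c(6, 2),
    microglia_total = c(10, 10)
  )
  expect_error(validate_census(census), "row\\(s\\) 1")
  census$apo_phagocytosed <- c(5, 2)
  expect_silent(validate_census(census))
  pouches <- tibble::tibble(sample_id = "a", n_pouches = 1, count = 99)
  expect_error(validate_census(census, pouches), "exceed microglia_total")
  expect_error(
    validate_census(census[, setdiff(names(census), "apo_total")]),
    "missing column"
  )
})
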