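test_that("dilution standard curves yield the amplification efficiency", {
  m <- efficiency_from_dilutions(c(20, 21, 22), c(1, 0.5, 0.25))
  expect_equal(m$efficiency, 1, tolerance = 1e-9)
  expect_equal(m$r_squared, 1)

  # slope of -1/log10(2) per decade is perfect doubling
  conc <- 2^-(0:4)
  cts <- 18 - log10(conc) / log10(2)
  m2 <- efficiency_from_dilutions(cts, conc)
  expect_equal(m2$slope, -1 / log10(2), tolerance = 1e-9)
  expect_equal(m2$efficiency, 1, tolerance = 1e-9)

  # steeper slopes mean lower efficiency
  effs <- vapply(seq(3.33, 4.5, by = 0.2), function(s) {
    efficiency_from_dilutions(20 + s * (0:3), 10^-(0:3))$efficiency
  }, numeric(1))
  expect_true(all(diff(effs) < 0))

  expect_error(efficiency_from_dilutions(c(20, 21), c(1, 0.5)),
               class = "phagoquant_validation_error")
  expect_error(efficiency_from_dilutions(c(20, 21, 22), c(0.25, 0.5, 1)),
               class = "phagoquant_validation_error")
  expect_warning(efficiency_from_dilutions(c(20, 19, 22, 23), c(1, .5, .25, .125)),
                 "not monotone")
})

test_that("efficiency inversion round-trips to high precision", {
  for (eff in c(0.8, 0.9, 0.95, 1, 1.05)) {
    conc <- 2^-(0:5)
    cts <- 25 - log10(conc) / log10(1 + eff)
    expect_equal(efficiency_from_dilutions(cts, conc)$efficiency, eff,
                 tolerance = 1e-9)
  }
})

test_that("tidy and glance expose the standard-curve fit", {
  m <- efficiency_from_dilutions(c(20, 21, 22), c(1, 0.5, 0.25), gene = "il1b")
  td <- tidy(m)
  expect_equal(td$term, c("intercept", "slope"))
  g <- glance(m)
  expect_equal(g$gene, "il1b")
  expect_named(g, c("gene", "efficiency", "slope", "r_squared"))
})

test_that("relative amount reduces to 2^-ddCt at perfect efficiency", {
  # no change anywhere
  expect_equal(relative_amount(20, 20, 18, 18, 1, 1), 1)
  expect_equal(relative_amount(20, 20, 18, 18, 0.87, 1.05), 1)
  # target down 3 cycles, reference down 1 -> 2^3/2^1
  expect_equal(relative_amount(17, 20, 17, 18, 1, 1), 4)
  # hand table of 2^-ddCt values
  cases <- expand.grid(dt = c(-2, 0, 1, 3), dr = c(-1, 0, 2))
  for (i in seq_len(nrow(cases))) {
    dt <- cases$dt[i]; dr <- cases$dr[i]
    expect_equal(relative_amount(20 - dt, 20, 18 - dr, 18, 1, 1),
                 2^(dt - dr))
  }
})

test_that("swapping sample and control inverts the fold change", {
  f <- relative_amount(17, 20, 17.5, 18, 0.95, 1.02)
  f_swapped <- relative_amount(20, 17, 18, 17.5, 0.95, 1.02)
  expect_equal(f_swapped, 1 / f)
  # the as-printed exponent convention is the exact reciprocal
  f_printed <- relative_amount(17, 20, 17.5, 18, 0.95, 1.02,
                               convention = "as_printed")
  expect_equal(f_printed, 1 / f)
  expect_error(relative_amount(17, 20, 18, 18, eff_target = 1.4),
               class = "phagoquant_validation_error")
})

test_that("the lower-variability candidate is chosen as reference", {
  withr::with_seed(31, {
    tb <- tidyr::expand_grid(group = c("a", "b"), rep = 1:6) %>%
      dplyr::mutate(sample_id = paste0(group, rep))
    ct <- dplyr::bind_rows(
      dplyr::mutate(tb, gene = "stable", ct = 20 + rnorm(12, sd = 0.1)),
      dplyr::mutate(tb, gene = "wobbly", ct = 20 + rnorm(12, sd = 1.5))
    )
    expect_equal(choose_reference_gene(ct, c("stable", "wobbly")), "stable")
    expect_error(choose_reference_gene(ct, c("stable", "ghost")),
                 class = "phagoquant_validation_error")
  })
})

test_that("relative expression recovers noiseless simulated fold changes", {
  sim <- simulate_ct_table(fold_changes = c(il1b = 4, tnfa = 0.5),
                           efficiencies = c(il1b = 0.9, tnfa = 1, l27a = 0.95),
                           noise_sd = 0, seed = 5)
  out <- relative_expression(sim$ct_table,
                             efficiencies = c(il1b = 0.9, tnfa = 1, l27a = 0.95),
                             reference_gene = "l27a",
                             control_group = "control")
  treated <- out[out$group == "treated", ]
  expect_equal(treated$fold_change[treated$gene == "il1b"], 4, tolerance = 1e-9)
  expect_equal(treated$fold_change[treated$gene == "tnfa"], 0.5, tolerance = 1e-9)
  control <- out[out$group == "control", ]
  expect_equal(control$fold_change, c(1, 1))

  # as-printed convention reports the reciprocal fold
  out2 <- relative_expression(sim$ct_table,
                              efficiencies = c(il1b = 0.9, tnfa = 1, l27a = 0.95),
                              reference_gene = "l27a",
                              control_group = "control",
                              convention = "as_printed")
  expect_equal(out2$fold_change[out2$group == "treated" & out2$gene == "il1b"],
               0.25, tolerance = 1e-9)
})

test_that("noisy triplicates still recover fold changes approximately", {
  sim <- simulate_ct_table(fold_changes = c(il1b = 4), noise_sd = 0.2,
                           n_per_group = 4, replicates = 3, seed = 17)
  out <- relative_expression(sim$ct_table, reference_gene = "l27a",
                             control_group = "control")
  got <- out$fold_change[out$group == "treated" & out$gene == "il1b"]
  expect_equal(got, 4, tolerance = 0.25)
})
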