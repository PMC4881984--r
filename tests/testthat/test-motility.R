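test_that("reorientation: identity, 90-degree tube, and round trip", {
  ph <- simulate_process_stack(lengths_um = c(12, 12), nx = 200, ny = 200,
                               amplitude_x = 0, seed = 2)
  st <- ph$stack

  same <- reorient_process(st, angle = 0)
  expect_identical(same$intensities, st$intensities)

  # swap axes so the tube runs along x, then rotate it back to vertical
  ax <- aperm(st$intensities, c(1, 2, 4, 3))
  st_x <- zstack_series(ax, st$voxel_size, st$frame_interval)
  rot <- reorient_process(st_x, angle = 90)
  expect_equal(sum(rot$intensities), sum(ax), tolerance = 0.01)
  pm <- measure_process(rot)
  expect_equal(tidy(pm)$length_um, ph$truth$lengths$length_um,
               tolerance = 0.02)

  # theta then -theta returns the original away from the swept edges
  r1 <- reorient_process(st, angle = 35)
  r2 <- reorient_process(r1, angle = -35)
  core_y <- 60:140; core_x <- 60:140
  expect_equal(r2$intensities[, , core_y, core_x],
               st$intensities[, , core_y, core_x], tolerance = 0.02)

  expect_error(reorient_process(st, roi = c(0, 500, 1, 10)),
               class = "phagoquant_validation_error")
})

test_that("border detection handles flat, triangular, and Gaussian profiles", {
  expect_null(detect_borders(rep(3, 10), background = 3))
  expect_null(detect_borders(rep(0, 10), background = 1))

  b <- detect_borders(c(0, 1, 2, 3, 2, 1, 0), background = 0)
  expect_equal(unname((b["xL"] + b["xR"]) / 2), 4)  # symmetric about the peak

  mu <- 30.3; sig <- 5
  prof <- 80 * exp(-0.5 * ((1:60 - mu) / sig)^2)
  for (infl in c(TRUE, FALSE)) {
    b <- detect_borders(prof, background = 0, use_inflexion = infl)
    expect_equal(unname((b["xL"] + b["xR"]) / 2), mu, tolerance = 0.1)
  }

  # prominence floor suppresses weak lines
  expect_null(detect_borders(prof, background = 0, min_prominence = 100))
  # edge guard suppresses maxima hugging the profile ends
  edge_prof <- c(50, 40, 5, 4, 3, 2, 1, 1, 1, 1)
  expect_null(detect_borders(edge_prof, 0, edge_margin = 3))
  expect_error(detect_borders(c(1, NA, 3), 0),
               class = "phagoquant_validation_error")
})

test_that("center rule: integer, virtual, and degenerate z-centers", {
  b <- tibble::tibble(z = 2:4, xL = c(6, 7, 8), xR = c(10, 11, 12))
  cp <- center_point(b)
  expect_equal(cp[["zC"]], 3)
  expect_equal(cp[["xC"]], (7 + 11) / 2)  # borders of slice z = 3 only

  # virtual center slice: borders averaged across the flanking slices first
  b2 <- tibble::tibble(z = c(2, 3), xL = c(6, 8), xR = c(10, 12))
  cp2 <- center_point(b2)
  expect_equal(cp2[["zC"]], 2.5)
  expect_equal(cp2[["xC"]], 9)  # xR = 11, xL = 7

  b3 <- tibble::tibble(z = 5, xL = 3, xR = 9)
  cp3 <- center_point(b3)
  expect_equal(cp3[["zC"]], 5)
  expect_equal(cp3[["xC"]], 6)

  # gap at the slice the rule needs
  b4 <- tibble::tibble(z = c(2, 4), xL = c(6, 6), xR = c(10, 10))
  expect_error(center_point(b4), class = "phagoquant_gap")
})

test_that("skeleton length sums consecutive center distances in um", {
  straight <- tibble::tibble(y = 1:11, xC = 5, zC = 3)
  expect_equal(skeleton_length(straight, c(1, 1, 1)), 10)

  two <- tibble::tibble(y = c(1, 2), xC = c(0, 0.75), zC = 1)
  expect_equal(skeleton_length(two, c(1, 1, 1)), 1.25)  # 3-4-5 triangle

  # anisotropic voxels convert each axis before the norm
  aniso <- tibble::tibble(y = c(1, 2), xC = c(0, 3), zC = c(1, 2))
  expect_equal(skeleton_length(aniso, c(0.1, 0.1, 1)),
               sqrt(0.1^2 + 0.3^2 + 1^2))
  expect_error(skeleton_length(straight[1, ], c(1, 1, 1)),
               class = "phagoquant_undefined_metric")
})

test_that("skeleton extraction matches a naive per-line reference", {
  ny <- 40
  vol <- tiny_tube_volume(ny = ny, xc = 16 + 3 * sin(seq_len(ny) / 6),
                          zc = rep(3, ny))
  got <- extract_skeleton(vol, background = 0, smooth_sigma = 0,
                          use_inflexion = FALSE, floor_fraction = 0.1)
  ref <- naive_skeleton(vol, background = 0)
  expect_equal(got$y, ref$y)
  expect_equal(got$xC, ref$xC, tolerance = 1e-8)
  expect_equal(got$zC, ref$zC)
})

test_that("motility trace reproduces the hand-worked arithmetic", {
  tr <- motility_trace(c(10, 13, 7), frame_interval = 1.5)
  expect_equal(tr$motility, c(2, 4))
  g <- glance(tr)
  expect_equal(g$mean_motility, 3)
  expect_equal(g$mean_protraction, 2)
  expect_equal(g$mean_retraction, 4)

  # static process: zero motility, directional means undefined
  gs <- glance(motility_trace(c(5, 5, 5, 5)))
  expect_equal(gs$mean_motility, 0)
  expect_true(is.na(gs$mean_protraction) && is.na(gs$mean_retraction))

  # time reversal preserves motility and swaps protraction/retraction
  gr <- glance(motility_trace(c(7, 13, 10), frame_interval = 1.5))
  expect_equal(gr$mean_motility, g$mean_motility)
  expect_equal(gr$mean_protraction, g$mean_retraction)
  expect_equal(gr$mean_retraction, g$mean_protraction)

  expect_error(motility_trace(10), class = "phagoquant_undefined_metric")
  expect_equal(nrow(tidy(tr)), 3)
})

test_that("dropped frames invalidate both adjacent pairs", {
  tr <- motility_trace(c(10, NA, 13, 16), frame_interval = 1)
  g <- glance(tr)
  expect_equal(g$n_pairs, 1)
  expect_equal(g$mean_motility, 3)
})

test_that("mean motility dominates the net length change (triangle inequality)", {
  withr::with_seed(5, {
    for (i in 1:25) {
      lens <- runif(sample(3:12, 1), 5, 40)
      g <- glance(motility_trace(lens, frame_interval = 1.5))
      bound <- abs(lens[length(lens)] - lens[1]) / (g$n_pairs * 1.5)
      expect_gte(g$mean_motility + 1e-12, bound)
    }
  })
})

test_that("measured lengths are invariant to translation and frame order", {
  ph <- simulate_process_stack(lengths_um = c(10, 14), nx = 80, ny = 180,
                               amplitude_x = 1, wavelength_y = 30, seed = 6)
  l0 <- tidy(measure_process(ph$stack))$length_um

  shifted <- ph$stack$intensities[, , , c(11:80, 1:10)]  # roll x by 10 px
  l_sh <- tidy(measure_process(zstack_series(shifted)))$length_um
  expect_equal(l_sh, l0, tolerance = 1e-6)

  swapped <- ph$stack$intensities[c(2, 1), , , ]
  l_sw <- tidy(measure_process(zstack_series(swapped)))$length_um
  expect_equal(l_sw, rev(l0), tolerance = 1e-9)
})

test_that("an elongating phantom yields the commanded motility", {
  ph <- simulate_process_stack(lengths_um = seq(12, 24, by = 3), ny = 300,
                               seed = 8)
  g <- glance(measure_process(ph$stack))
  # 3 um per 1.5-min frame = 2 um/min
  expect_equal(g$mean_motility, 2, tolerance = 0.1)
  expect_equal(g$mean_protraction, 2, tolerance = 0.1)
})

test_that("a single detectable frame refuses to produce a trace", {
  ph <- simulate_process_stack(lengths_um = 10, ny = 150, seed = 9)
  expect_error(measure_process(ph$stack),
               class = "phagoquant_undefined_metric")
})

test_that("occupancy equals brute-force pixel counting and is monotone", {
  expect_equal(as.numeric(occupancy_fraction(matrix(0, 10, 10), threshold = 1)), 0)
  half <- matrix(c(rep(0, 50), rep(10, 50)), 10, 10)
  expect_equal(as.numeric(occupancy_fraction(half, threshold = 5)), 50)

  withr::with_seed(13, {
    for (i in 1:10) {
      mask <- array(runif(5 * 20 * 20) > runif(1), dim = c(5, 20, 20))
      got <- as.numeric(occupancy_fraction(mask * 1, threshold = 0.5))
      expect_equal(got, 100 * mean(mask))
    }
    img <- array(runif(3 * 15 * 15), dim = c(3, 15, 15))
    occ <- vapply(seq(0.1, 0.9, 0.2),
                  function(th) as.numeric(occupancy_fraction(img, th)),
                  numeric(1))
    expect_true(all(diff(occ) <= 0))
  })

  expect_error(occupancy_fraction(matrix(1, 2, 2), min_slices = 10),
               class = "phagoquant_validation_error")
})

test_that("auto threshold separates a bimodal image sensibly", {
  withr::with_seed(21, {
    img <- matrix(c(rnorm(300, 10, 1), rnorm(100, 100, 5)), 20, 20)
    occ <- occupancy_fraction(img, threshold = "auto")
    expect_equal(as.numeric(occ), 25, tolerance = 1)
    expect_gt(attr(occ, "threshold"), 15)
    expect_lt(attr(occ, "threshold"), 95)
  })
})
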