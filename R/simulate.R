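# Seed-deterministic synthetic data with ground truth.
#
# Each generator draws from its own RNG sub-stream derived from the master
# seed, so adding or reordering generators never perturbs the others, and
# ground truth is returned alongside the data (never embedded in it) so that
# downstream recovery tests cannot read answers from their inputs.

#' Simulate per-sample phagocytosis censuses
#'
#' Emulates a two-group experiment (baseline vs challenge). Apoptotic counts
#' are Poisson; engulfment is binomial per apoptotic cell; each engulfed cell
#' occupies one pouch assigned to a uniformly chosen microglia, giving the
#' pouch histogram. Under the `"coupled"` scenario the challenge multiplies
#' apoptosis `k`-fold while engulfment probability is unchanged, so microglia
#' absorb the challenge through some mix of more phagocytic cells, more
#' pouches per cell and (optionally, via `microglia_fold`) more cells — and
#' the expected phagocytosis/apoptosis fold change stays at 1. Under
#' `"uncoupled"` the challenge also multiplies apoptosis but the engulfment
#' probability is scaled down by `engulf_drop`, collapsing the phagocytic
#' index and the coupling fold change.
#'
#' Defaults emulate a hippocampal dentate-gyrus census: ~30 apoptotic cells
#' per region at baseline, 90% of them engulfed, ~120 microglia in a 0.2 mm^3
#' septal region. Distances of nonphagocytosed apoptotic cells to the nearest
#' microglial process are lognormal: tight (mean ~1.3 um) at baseline and
#' heavy-tailed (about 25% at 3-10 um and 15% beyond 10 um) in the uncoupled
#' challenge.
#'
#' @param n_per_group Samples per group.
#' @param scenario `"coupled"` or `"uncoupled"`.
#' @param k Fold increase of apoptosis in the challenge group.
#' @param mean_apo Mean apoptotic cells per region at baseline.
#' @param engulf_prob Baseline probability that an apoptotic cell is engulfed.
#' @param engulf_drop Multiplier on `engulf_prob` in the uncoupled challenge.
#' @param mean_microglia Mean microglia per region.
#' @param microglia_fold Challenge-group multiplier on microglial numbers
#'   (one of the three adaptation strategies; default 1).
#' @param region_volume_mm3 Region volume.
#' @param seed Master seed.
#' @return List with tibbles `census`, `pouches`, `distances`, and a `truth`
#'   list of the generating parameters.
#' @export
simulate_census <- function(n_per_group = 10,
                            scenario = c("coupled", "uncoupled"),
                            k = 3, mean_apo = 30, engulf_prob = 0.9,
                            engulf_drop = 0.2, mean_microglia = 120,
                            microglia_fold = 1, region_volume_mm3 = 0.2,
                            seed = 1) {
  scenario <- arg_match(scenario)
  if (engulf_prob <= 0 || engulf_prob > 1 || engulf_drop <= 0 || engulf_drop > 1) {
    abort_validation("Probabilities must be in (0, 1].")
  }
  p_challenge <- if (scenario == "coupled") engulf_prob else engulf_prob * engulf_drop
  withr::with_seed(substream_seed(seed, "census"), {
    groups <- tibble(
      group = rep(c("baseline", "challenge"), each = n_per_group),
      mu_apo = rep(c(mean_apo, mean_apo * k), each = n_per_group),
      p = rep(c(engulf_prob, p_challenge), each = n_per_group),
      mu_mg = rep(c(mean_microglia, mean_microglia * microglia_fold),
                  each = n_per_group)
    )
    census <- groups %>%
      mutate(
        sample_id = sprintf("%s_%02d", .data$group,
                            stats::ave(seq_len(dplyr::n()), .data$group, FUN = seq_along)),
        apo_total = rpois(dplyr::n(), .data$mu_apo),
        apo_phagocytosed = rbinom(dplyr::n(), .data$apo_total, .data$p),
        microglia_total = pmax(1L, rpois(dplyr::n(), .data$mu_mg)),
        region_volume_mm3 = region_volume_mm3
      ) %>%
      select("sample_id", "group", "apo_total", "apo_phagocytosed",
             "microglia_total", "region_volume_mm3")

    pouches <- purrr::pmap(census, function(sample_id, apo_phagocytosed,
                                            microglia_total, ...) {
      if (apo_phagocytosed == 0) return(NULL)
      per_cell <- tabulate(sample.int(microglia_total, apo_phagocytosed,
                                      replace = TRUE),
                           nbins = microglia_total)
      tab <- table(per_cell[per_cell > 0])
      tibble(sample_id = sample_id,
             n_pouches = as.integer(names(tab)),
             count = as.integer(tab))
    }) %>% bind_rows()

    distances <- purrr::pmap(census, function(sample_id, group, apo_total,
                                              apo_phagocytosed, ...) {
      n_free <- apo_total - apo_phagocytosed
      if (n_free == 0) return(NULL)
      if (group == "baseline" || scenario == "coupled") {
        d <- stats::rlnorm(n_free, meanlog = log(1.3) - 0.8^2 / 2, sdlog = 0.8)
      } else {
        # heavy tail: ~60% under 3 um, ~25% in 3-10 um, ~15% over 10 um
        d <- stats::rlnorm(n_free, meanlog = 0.709, sdlog = 1.5375)
      }
      tibble(sample_id = sample_id, distance_um = d)
    }) %>% bind_rows()
  })
  list(
    census = census, pouches = pouches, distances = distances,
    truth = list(scenario = scenario, k = k,
                 engulf_prob = c(baseline = engulf_prob, challenge = p_challenge),
                 expected_ph_a_fold = p_challenge / engulf_prob,
                 mean_apo = c(baseline = mean_apo, challenge = mean_apo * k))
  )
}

#' Simulate a pulse-chase clearance cohort
#'
#' Discrete-event simulation of a labelled cohort: cells enter apoptosis as
#' a homogeneous Poisson process at `production_rate`, and each apoptotic
#' cell is removed after an exponential waiting time with mean
#' `clearance_time`. Tallies of cells present (apoptotic, not yet cleared)
#' and cumulatively cleared are reported at the requested times. At steady
#' state the expected present count is `production_rate * clearance_time`.
#'
#' @param clearance_time Mean clearance time tau in hours.
#' @param production_rate Apoptosis entry rate, cells/h; `NULL` sizes the
#'   rate so `n_cells` enter over the simulated span.
#' @param n_cells Number of cells entering apoptosis over the simulation.
#' @param burn_in Hours simulated before the observation window (defaults to
#'   `10 * clearance_time` so tallies are at steady state).
#' @param delta_t Observation window in hours.
#' @param times Report times in hours; default covers burn-in plus window at
#'   1-h steps.
#' @param seed Master seed.
#' @return Tibble `(time_h, present, cleared_cum)` with the generating
#'   parameters in attribute `truth`.
#' @export
simulate_clearance_cohort <- function(clearance_time = 1.5,
                                      production_rate = NULL,
                                      n_cells = 10000,
                                      burn_in = 10 * clearance_time,
                                      delta_t = 24, times = NULL, seed = 1) {
  if (clearance_time <= 0 || delta_t <= 0) {
    abort_validation("clearance_time and delta_t must be positive.")
  }
  span <- burn_in + delta_t
  if (is.null(production_rate)) production_rate <- n_cells / span
  if (is.null(times)) times <- seq(0, span, by = min(1, delta_t / 4))
  withr::with_seed(substream_seed(seed, "clearance"), {
    n_entries <- rpois(1, production_rate * span)
    entry <- sort(runif(n_entries, 0, span))
    removal <- entry + rexp(n_entries, rate = 1 / clearance_time)
  })
  out <- tibble(
    time_h = times,
    present = vapply(times, function(t) sum(entry <= t & removal > t), numeric(1)),
    cleared_cum = vapply(times, function(t) sum(removal <= t), numeric(1))
  )
  attr(out, "truth") <- list(clearance_time = clearance_time,
                             production_rate = production_rate,
                             burn_in = burn_in, delta_t = delta_t)
  out
}

#' Simulate a tubular process phantom with known centerline
#'
#' Renders a fluorescent tube with Gaussian cross-section along a smooth
#' centerline into a 4-D stack at two-photon voxel geometry, one tube per
#' frame with a commanded arc length. The centerline runs along y with an
#' optional sinusoidal excursion in x; it stays in a plane of constant z by
#' default because the 1-um z-step quantizes the center slice to half-slice
#' precision, which would dominate the length error for steep z-curvature.
#' Per-frame ground-truth arc lengths are computed from the analytic
#' centerline on a fine grid, independently of the measurement algorithm.
#'
#' @param lengths_um Commanded per-frame arc lengths (um); one frame each.
#' @param nx,ny,nz Stack dimensions in pixels/slices.
#' @param voxel_size `(dx, dy, dz)` in um.
#' @param frame_interval Minutes between frames.
#' @param radius_sigma Gaussian cross-section sigma in um (~process radius/2).
#' @param amplitude_x Sinusoidal x-excursion amplitude of the centerline, um.
#' @param wavelength_y Period of the excursion along y, um.
#' @param z_center Center slice of the tube plane (defaults to mid-stack).
#' @param amplitude Peak fluorescence amplitude above background.
#' @param background Constant background intensity.
#' @param snr Signal-to-noise ratio; Gaussian noise with sd `amplitude/snr`
#'   is added (`Inf` = noiseless).
#' @param seed Master seed (used only when `snr` is finite).
#' @return List with `stack` (a [zstack_series()]) and `truth` (tibble
#'   `frame`, `length_um` of analytic arc lengths, plus centerline function).
#' @export
simulate_process_stack <- function(lengths_um = seq(20, 47, by = 3),
                                   nx = 60, ny = 550, nz = 9,
                                   voxel_size = c(0.1, 0.1, 1),
                                   frame_interval = 1.5,
                                   radius_sigma = 0.5,
                                   amplitude_x = 1.5, wavelength_y = 40,
                                   z_center = NULL, amplitude = 100,
                                   background = 5, snr = Inf, seed = 1) {
  dx <- voxel_size[1]; dy <- voxel_size[2]; dz <- voxel_size[3]
  if (is.null(z_center)) z_center <- (nz + 1) / 2 * dz
  x_center <- nx / 2 * dx
  xc_fun <- function(y_um) x_center + amplitude_x * sin(2 * pi * y_um / wavelength_y)
  zc_fun <- function(y_um) rep(z_center, length(y_um))

  # cumulative arc length of the analytic centerline on a fine grid
  y_max_um <- ny * dy
  fine <- seq(0, y_max_um, by = dy / 10)
  seg <- sqrt(diff(fine)^2 + diff(xc_fun(fine))^2 + diff(zc_fun(fine))^2)
  s_cum <- c(0, cumsum(seg))
  total_arc <- max(s_cum)
  if (any(lengths_um > total_arc)) {
    abort_validation("Commanded length exceeds the arc available in the ",
                     "stack (", signif(total_arc, 5), " um); enlarge ny.")
  }
  extent_for <- function(L) fine[which.min(abs(s_cum - L))]
  truth_len <- vapply(lengths_um, function(L) s_cum[which.min(abs(s_cum - L))],
                      numeric(1))

  nf <- length(lengths_um)
  a <- array(background, dim = c(nf, nz, ny, nx))
  x_um <- (seq_len(nx) - 0.5) * dx
  z_um <- (seq_len(nz) - 0.5) * dz
  y_um <- (seq_len(ny) - 0.5) * dy
  for (f in seq_len(nf)) {
    ext <- extent_for(lengths_um[f])
    iy <- which(y_um <= ext)
    xc <- xc_fun(y_um[iy]); zc <- zc_fun(y_um[iy])
    for (j in seq_along(iy)) {
      gx <- exp(-0.5 * ((x_um - xc[j]) / radius_sigma)^2)
      gz <- exp(-0.5 * ((z_um - zc[j]) / radius_sigma)^2)
      a[f, , iy[j], ] <- background + amplitude * outer(gz, gx)
    }
  }
  if (is.finite(snr)) {
    withr::with_seed(substream_seed(seed, "stack"), {
      a <- a + array(rnorm(length(a), sd = amplitude / snr), dim = dim(a))
    })
  }
  list(
    stack = zstack_series(a, voxel_size, frame_interval),
    truth = list(
      lengths = tibble(frame = seq_len(nf), length_um = truth_len),
      centerline = list(xc = xc_fun, zc = zc_fun),
      background = background, amplitude = amplitude, snr = snr
    )
  )
}

#' Simulate a long-format Ct table with known fold changes
#'
#' Ct values are generated from true relative abundances via
#' `Ct = intercept - log(abundance) / log(1 + eff)` plus Gaussian cycle
#' noise; the reference gene has fold change 1 in every group.
#'
#' @param fold_changes Named numeric vector: true fold change of each target
#'   gene in the treatment group relative to control.
#' @param efficiencies Named numeric vector of amplification efficiencies per
#'   gene (including the reference); genes absent default to 1.
#' @param reference_gene Reference gene name.
#' @param n_per_group Biological samples per group.
#' @param replicates Technical replicates per (sample, gene).
#' @param noise_sd Cycle noise SD (cycles).
#' @param ct_intercept Ct of unit abundance.
#' @param seed Master seed.
#' @return List with `ct_table` (tibble `sample_id`, `group`, `gene`, `ct`,
#'   `replicate`) and `truth` (tibble `gene`, `fold_change`).
#' @export
simulate_ct_table <- function(fold_changes = c(il1b = 4, tnfa = 2.5),
                              efficiencies = NULL,
                              reference_gene = "l27a",
                              n_per_group = 4, replicates = 3,
                              noise_sd = 0.2, ct_intercept = 22, seed = 1) {
  eff_of <- function(g) {
    e <- if (!is.null(efficiencies) && g %in% names(efficiencies)) efficiencies[[g]] else 1
    if (e <= 0 || e > 1.2) abort_validation("Efficiencies must be in (0, 1.2].")
    e
  }
  genes <- c(names(fold_changes), reference_gene)
  design <- tidyr::expand_grid(
    group = c("control", "treated"),
    animal = seq_len(n_per_group),
    gene = genes,
    replicate = seq_len(replicates)
  ) %>%
    mutate(sample_id = sprintf("%s_%02d", .data$group, .data$animal))
  withr::with_seed(substream_seed(seed, "qpcr"), {
    ct_table <- design %>%
      mutate(
        abundance = dplyr::if_else(
          .data$group == "treated" & .data$gene != reference_gene,
          unname(fold_changes[.data$gene]), 1
        ),
        ct = ct_intercept -
          log(.data$abundance) / log(1 + vapply(.data$gene, eff_of, numeric(1))) +
          rnorm(dplyr::n(), sd = noise_sd)
      ) %>%
      select("sample_id", "group", "gene", "replicate", "ct")
  })
  list(
    ct_table = ct_table,
    truth = tibble(gene = names(fold_changes),
                   fold_change = unname(fold_changes))
  )
}
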