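# Shared fixture builders and independent reference implementations.

# Random single-sample census built from an explicit per-cell pouch list, so
# tests can compare the histogram formula against direct per-cell averaging.
random_cell_census <- function(n_microglia = sample(20:200, 1),
                               max_pouches = 7) {
  per_cell <- sample(0:max_pouches, n_microglia, replace = TRUE,
                     prob = c(8, 4, 2, 1, 0.5, 0.25, 0.1, 0.05))
  tab <- table(per_cell[per_cell > 0])
  list(
    per_cell = per_cell,
    histogram = tibble::tibble(n_pouches = as.integer(names(tab)),
                               count = as.integer(tab)),
    n_microglia = n_microglia
  )
}

# Naive reference skeleton: per line, per slice, direct half-max border scan
# on the raw (unsmoothed) profile, then the center rule, written without any
# of the package's vectorized plumbing.
naive_skeleton <- function(volume, background) {
  nz <- dim(volume)[1]; ny <- dim(volume)[2]; nx <- dim(volume)[3]
  out <- NULL
  for (y in seq_len(ny)) {
    zs <- c(); xls <- c(); xrs <- c()
    for (z in seq_len(nz)) {
      p <- volume[z, y, ]
      m <- which.max(p)
      if (p[m] <= background) next
      level <- background + 0.5 * (p[m] - background)
      xl <- 1
      for (i in seq(m, 1)) {
        if (p[i] < level) {
          xl <- i + (level - p[i]) / (p[i + 1] - p[i])
          break
        }
      }
      xr <- nx
      for (i in seq(m, nx)) {
        if (p[i] < level) {
          xr <- i - (level - p[i]) / (p[i - 1] - p[i])
          break
        }
      }
      zs <- c(zs, z); xls <- c(xls, xl); xrs <- c(xrs, xr)
    }
    if (length(zs) == 0) next
    zc <- (max(zs) + min(zs)) / 2
    if (zc %% 1 == 0) {
      k <- which(zs == zc)
      if (length(k) != 1) next
      xc <- (xls[k] + xrs[k]) / 2
    } else {
      k1 <- which(zs == zc - 0.5); k2 <- which(zs == zc + 0.5)
      if (length(k1) != 1 || length(k2) != 1) next
      xc <- ((xls[k1] + xls[k2]) / 2 + (xrs[k1] + xrs[k2]) / 2) / 2
    }
    out <- rbind(out, data.frame(y = y, xC = xc, zC = zc))
  }
  out
}

# Small noiseless Gaussian-tube volume (z, y, x) with per-line commanded
# center positions, for border/center checks.
tiny_tube_volume <- function(ny = 20, nx = 31, nz = 5, xc = rep(16, ny),
                             zc = rep(3, ny), sigma_x = 3, sigma_z = 0.6,
                             amplitude = 100, background = 0) {
  a <- array(background, dim = c(nz, ny, nx))
  for (y in seq_len(ny)) {
    gx <- exp(-0.5 * ((seq_len(nx) - xc[y]) / sigma_x)^2)
    gz <- exp(-0.5 * ((seq_len(nz) - zc[y]) / sigma_z)^2)
    a[, y, ] <- background + amplitude * outer(gz, gx)
  }
  a
}
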