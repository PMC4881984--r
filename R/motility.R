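# 3-D process length and motility from two-photon time-lapse z-stacks.
#
# The algorithm works on a pre-registered 4-D stack (frame, slice, line,
# column). A selected process is reoriented so its axis runs along y; then,
# in every frame, the intensity profile of each horizontal line is scanned in
# each z-slice to find the left/right borders of the process, the border
# coordinates give a center point (xC, zC) per line, and the 3-D skeleton
# length is the summed distance between center points of consecutive lines
# (converted to um with the anisotropic voxel sizes). Motility is the
# absolute frame-to-frame length change per minute; protraction and
# retraction average the increases and decreases separately.

#' Construct a 4-D time-lapse z-stack series
#'
#' @param intensities 4-D numeric array ordered (frame, slice z, line y,
#'   column x).
#' @param voxel_size Numeric length-3 `(dx, dy, dz)` in um. The default
#'   0.1 x 0.1 x 1 um matches typical two-photon acquisition with 1-um z-steps.
#' @param frame_interval Minutes between consecutive frames (default 1.5).
#' @return A `zstack_series` object.
#' @export
zstack_series <- function(intensities, voxel_size = c(0.1, 0.1, 1),
                          frame_interval = 1.5) {
  if (length(dim(intensities)) != 4) {
    abort_validation("intensities must be a 4-D array (t, z, y, x).")
  }
  if (length(voxel_size) != 3 || any(voxel_size <= 0)) {
    abort_validation("voxel_size must be three positive numbers (dx, dy, dz).")
  }
  if (frame_interval <= 0) abort_validation("frame_interval must be positive.")
  structure(
    list(intensities = intensities, voxel_size = as.numeric(voxel_size),
         frame_interval = frame_interval),
    class = "zstack_series"
  )
}

#' @export
print.zstack_series <- function(x, ...) {
  d <- dim(x$intensities)
  cat("<zstack_series> ", d[1], " frames x ", d[2], " slices x ",
      d[3], " x ", d[4], " px; voxel ",
      paste(x$voxel_size, collapse = " x "), " um; ",
      x$frame_interval, " min/frame\n", sep = "")
  invisible(x)
}

# In-plane rotation with bilinear resampling -----------------------------

# Rotates a (y, x) matrix by `angle` degrees counterclockwise about its
# center, keeping the output grid identical to the input grid. Written by
# hand because the algorithm needs a center-fixed, same-size resample with a
# controlled fill value.
#' @keywords internal
rotate_bilinear <- function(mat, angle, fill = min(mat)) {
  if (angle %% 360 == 0) return(mat)
  ny <- nrow(mat); nx <- ncol(mat)
  th <- angle * pi / 180
  cy <- (ny + 1) / 2; cx <- (nx + 1) / 2
  # inverse mapping: source = R(-angle) . dest
  gy <- rep(seq_len(ny), times = nx) - cy
  gx <- rep(seq_len(nx), each = ny) - cx
  sx <- cos(th) * gx - sin(th) * gy + cx
  sy <- sin(th) * gx + cos(th) * gy + cy
  x0 <- floor(sx); y0 <- floor(sy)
  fx <- sx - x0; fy <- sy - y0
  out <- rep(fill, ny * nx)
  ok <- x0 >= 1 & x0 + 1 <= nx & y0 >= 1 & y0 + 1 <= ny
  if (any(ok)) {
    i00 <- (x0[ok] - 1) * ny + y0[ok]
    v <- mat[i00] * (1 - fx[ok]) * (1 - fy[ok]) +
      mat[i00 + ny] * fx[ok] * (1 - fy[ok]) +
      mat[i00 + 1] * (1 - fx[ok]) * fy[ok] +
      mat[i00 + ny + 1] * fx[ok] * fy[ok]
    out[ok] <- v
  }
  matrix(out, ny, nx)
}

#' Crop and reorient a process sub-volume
#'
#' Extracts a rectangular region of interest around one process and rotates
#' every xy-plane so that the process axis is vertical (aligned with y).
#' Slices and frames are untouched; resampling is bilinear.
#'
#' @param stack A [zstack_series()].
#' @param roi `c(x_min, x_max, y_min, y_max)` in pixels, or `NULL` for the
#'   whole field.
#' @param angle In-plane rotation in degrees (counterclockwise) that makes
#'   the process vertical.
#' @param fill Value for pixels rotated in from outside the region; defaults
#'   to the region minimum.
#' @return A `zstack_series` holding the rotated sub-volume.
#' @export
reorient_process <- function(stack, roi = NULL, angle = 0, fill = NULL) {
  stopifnot(inherits(stack, "zstack_series"))
  if (!is.finite(angle)) abort_validation("Rotation angle must be finite.")
  a <- stack$intensities
  d <- dim(a)
  if (is.null(roi)) roi <- c(1, d[4], 1, d[3])
  roi <- as.numeric(roi)
  if (length(roi) != 4 || roi[1] < 1 || roi[2] > d[4] || roi[3] < 1 ||
      roi[4] > d[3] || roi[1] > roi[2] || roi[3] > roi[4]) {
    abort_validation("ROI [", paste(roi, collapse = ", "),
                     "] outside stack bounds ", d[3], " x ", d[4], " (y x x).")
  }
  sub <- a[, , roi[3]:roi[4], roi[1]:roi[2], drop = FALSE]
  if (angle %% 360 != 0) {
    if (is.null(fill)) fill <- min(sub)
    for (f in seq_len(dim(sub)[1])) {
      for (z in seq_len(dim(sub)[2])) {
        sub[f, z, , ] <- rotate_bilinear(sub[f, z, , ], angle, fill = fill)
      }
    }
  }
  zstack_series(sub, stack$voxel_size, stack$frame_interval)
}

# Border detection -------------------------------------------------------

#' @keywords internal
smooth_profile <- function(p, sigma_px) {
  if (sigma_px <= 0) return(p)
  half <- max(1L, ceiling(3 * sigma_px))
  k <- exp(-0.5 * ((-half:half) / sigma_px)^2)
  n <- length(p)
  padded <- c(rep(p[1], half), p, rep(p[n], half))
  as.numeric(stats::filter(padded, k / sum(k), sides = 2))[(half + 1):(half + n)]
}

# Gaussian-smooths a stacked profile matrix column-wise in one pass
# (stats::filter runs column-wise on a matrix of series).
#' @keywords internal
filter_columns <- function(profiles, sigma_px) {
  n <- nrow(profiles)
  half <- max(1L, ceiling(3 * sigma_px))
  k <- exp(-0.5 * ((-half:half) / sigma_px)^2)
  padded <- rbind(
    profiles[rep(1L, half), , drop = FALSE],
    profiles,
    profiles[rep(n, half), , drop = FALSE]
  )
  out <- stats::filter(padded, k / sum(k), sides = 2)[(half + 1):(half + n), ,
                                                      drop = FALSE]
  matrix(as.numeric(out), nrow = n)
}

# In-plane (x and y) Gaussian smoothing of a (z, y, x) volume. Smoothing
# along the process axis as well as across it keeps neighbouring-line center
# estimates correlated under noise, so noise cannot inflate the summed
# skeleton length through line-to-line center jitter.
#' @keywords internal
smooth_volume_xy <- function(vol, sigma_px) {
  if (sigma_px <= 0) return(vol)
  d <- dim(vol)
  sm <- matrix(aperm(vol, c(3, 1, 2)), nrow = d[3])        # x-profiles
  sm <- filter_columns(sm, sigma_px)
  vol <- aperm(array(sm, dim = c(d[3], d[1], d[2])), c(2, 3, 1))
  sm <- matrix(aperm(vol, c(2, 1, 3)), nrow = d[2])        # y-profiles
  sm <- filter_columns(sm, sigma_px)
  aperm(array(sm, dim = c(d[2], d[1], d[3])), c(2, 1, 3))
}

# Largest contiguous run of TRUE values; ties broken by `weight`.
#' @keywords internal
largest_run <- function(idx, weight = NULL) {
  if (length(idx) == 0) return(integer())
  runs <- split(idx, cumsum(c(1, diff(idx) != 1)))
  sizes <- lengths(runs)
  best <- which(sizes == max(sizes))
  if (length(best) > 1 && !is.null(weight)) {
    best <- best[which.max(vapply(runs[best],
                                  function(r) max(weight[r]), numeric(1)))]
  }
  runs[[best[1]]]
}

#' Detect process borders on a 1-D intensity profile
#'
#' Finds the left and right borders of a process crossing a horizontal line.
#' The profile is absent (returns `NULL`) when the maximum does not rise
#' above the background by at least `min_prominence`. Otherwise, walking
#' outward from the maximum, the border is the first sub-pixel position where
#' intensity falls to `background + prominence_fraction * (max - background)`
#' (half-maximum by default), optionally refined to the nearest sign change
#' of the discrete second derivative (inflexion point).
#'
#' @param profile Numeric intensity profile (>= 3 samples).
#' @param background Background intensity level.
#' @param prominence_fraction Fraction of the prominence at which the border
#'   is placed (default 0.5, the half-max convention).
#' @param use_inflexion Refine borders to the nearest inflexion point.
#' @param min_prominence Minimum prominence (max - background) for the line
#'   to count as containing the process.
#' @param smooth_sigma Gaussian pre-smoothing of the profile, in pixels
#'   (0 disables).
#' @param edge_margin Treat the process as absent when the profile maximum
#'   lies within this many samples of either end (edge-padded smoothing is
#'   unreliable there).
#' @return `c(xL, xR)` in (sub-)pixel column coordinates, or `NULL` when the
#'   process is absent.
#' @export
detect_borders <- function(profile, background, prominence_fraction = 0.5,
                           use_inflexion = TRUE, min_prominence = 0,
                           smooth_sigma = 0, edge_margin = 0) {
  if (any(!is.finite(profile))) abort_validation("Profile has non-finite intensities.")
  if (length(profile) < 3) abort_validation("Profile must have >= 3 samples.")
  if (prominence_fraction <= 0 || prominence_fraction > 1) {
    abort_validation("prominence_fraction must be in (0, 1].")
  }
  p <- smooth_profile(profile, smooth_sigma)
  m <- which.max(p)
  if (edge_margin > 0 &&
      (m <= edge_margin || m > length(p) - edge_margin)) {
    return(NULL)
  }
  prom <- p[m] - background
  if (prom <= max(0, min_prominence)) return(NULL)
  level <- background + prominence_fraction * prom

  cross_out <- function(dir) {
    # walk outward from the max until intensity first falls below `level`
    idx <- if (dir < 0) seq(m, 1L) else seq(m, length(p))
    below <- which(p[idx] < level)
    if (length(below) == 0) return(if (dir < 0) 1 else length(p))
    i_out <- idx[below[1]]          # first sample below level
    i_in <- i_out - dir             # neighbouring sample still above
    frac <- (level - p[i_in]) / (p[i_out] - p[i_in])
    i_in + dir * frac
  }
  xL <- cross_out(-1L)
  xR <- cross_out(+1L)

  if (use_inflexion && length(p) >= 6) {
    # curvature is estimated at a coarser scale (extra 2-px smoothing,
    # second differences at 2-px spacing) and a refinement is accepted only
    # within 2 px of the half-max crossing: both guards keep noise-induced
    # curvature sign changes from capturing the border
    ps <- smooth_profile(p, 2)
    h <- 2L
    i <- (1 + h):(length(p) - h)
    d2 <- ps[i + h] - 2 * ps[i] + ps[i - h]
    sgn <- d2[-length(d2)] * d2[-1]
    at <- which(sgn < 0)
    if (length(at) > 0) {
      zeros <- i[at] + d2[at] / (d2[at] - d2[at + 1])
      refine <- function(x0, side) {
        cand <- zeros[side(zeros) & abs(zeros - x0) <= 2]
        if (length(cand) > 0) cand[which.min(abs(cand - x0))] else x0
      }
      xL <- refine(xL, function(z) z < m)
      xR <- refine(xR, function(z) z > m)
    }
  }
  c(xL = unname(xL), xR = unname(xR))
}

# Center points and skeleton ---------------------------------------------

#' Center point of a process on one horizontal line
#'
#' Given the detected borders in each z-slice that contains the process at
#' this y-line, the center slice is `zC = (zU + zB) / 2` (upper and bottom
#' slices containing the process). When `zC` is an integer, `xC` is the
#' border midpoint at that slice. When `zC` is virtual (half-integer), the
#' left and right borders are each averaged over the two flanking slices
#' `zC - 0.5` and `zC + 0.5` before taking the midpoint.
#'
#' @param borders Data frame with columns `z`, `xL`, `xR` (one row per slice
#'   containing the process at this line).
#' @return `c(xC, zC)` in (sub-)pixel coordinates.
#' @export
center_point <- function(borders) {
  if (nrow(borders) == 0) abort_validation("No slice contains the process.")
  zB <- min(borders$z); zU <- max(borders$z)
  zC <- (zU + zB) / 2
  pick <- function(z) {
    row <- borders[borders$z == z, , drop = FALSE]
    if (nrow(row) != 1) {
      abort(paste0("Process not detected at slice z = ", z,
                   " required by the center rule (gap in the z-range)."),
            class = "phagoquant_gap")
    }
    row
  }
  if (zC %% 1 == 0) {
    row <- pick(zC)
    xC <- (row$xL + row$xR) / 2
  } else {
    lo <- pick(zC - 0.5); hi <- pick(zC + 0.5)
    xR <- (lo$xR + hi$xR) / 2
    xL <- (lo$xL + hi$xL) / 2
    xC <- (xL + xR) / 2
  }
  c(xC = unname(xC), zC = zC)
}

#' Extract the process skeleton from one frame
#'
#' Runs border detection on every horizontal line of every z-slice of a
#' single-frame volume and assembles the per-line center points. The volume
#' is first smoothed in-plane (x and y) with a Gaussian of `smooth_sigma`
#' pixels — the denoising step a registration/bleach-corrected two-photon
#' pipeline applies before measuring. Because a process is a connected tube,
#' only the largest contiguous run of detected z-slices per line, and of
#' detected lines per frame, is kept. Lines whose maximum never rises above
#' the detection floor contain no process; lines whose z-range has a gap at
#' the slice needed by the center rule are skipped (and counted in the
#' `dropped_lines` attribute).
#'
#' @param volume 3-D array (z, y, x) of one frame.
#' @param background Background intensity.
#' @param prominence_fraction,use_inflexion,smooth_sigma See [detect_borders()].
#' @param floor_fraction Detection floor as a fraction of the frame-wide
#'   prominence `max(volume) - background`; lines/slices below it are treated
#'   as not containing the process.
#' @return Tibble `(y, xC, zC)` with attribute `dropped_lines`.
#' @export
extract_skeleton <- function(volume, background,
                             prominence_fraction = 0.5, use_inflexion = TRUE,
                             smooth_sigma = 2, floor_fraction = 0.3) {
  stopifnot(length(dim(volume)) == 3)
  volume <- smooth_volume_xy(volume, smooth_sigma)
  nz <- dim(volume)[1]; ny <- dim(volume)[2]
  floor_abs <- floor_fraction * (max(volume) - background)
  # lines/slices whose maximum clears the floor are candidates
  line_max <- apply(volume, c(1, 2), max)
  dropped <- integer()
  rows <- vector("list", ny)
  for (y in seq_len(ny)) {
    cand <- which(line_max[, y] > background + floor_abs)
    # a process is a connected tube: keep the largest contiguous z-run
    # (brightest on ties) so stray detections cannot corrupt the z-range
    cand <- largest_run(cand, weight = line_max[, y])
    bz <- vector("list", nz)
    for (z in cand) {
      b <- detect_borders(volume[z, y, ], background,
                          prominence_fraction = prominence_fraction,
                          use_inflexion = use_inflexion,
                          min_prominence = floor_abs,
                          smooth_sigma = 0,
                          edge_margin = ceiling(3 * smooth_sigma))
      if (!is.null(b)) bz[[z]] <- tibble(z = z, xL = b[["xL"]], xR = b[["xR"]])
    }
    bz <- bind_rows(bz)
    if (nrow(bz) == 0) next
    cp <- tryCatch(center_point(bz), phagoquant_gap = function(e) NULL)
    if (is.null(cp)) {
      dropped <- c(dropped, y)
      next
    }
    rows[[y]] <- tibble(y = y, xC = cp[["xC"]], zC = cp[["zC"]])
  }
  out <- bind_rows(rows)
  if (nrow(out) > 0) {
    # same connectivity argument along the process axis
    keep <- largest_run(out$y, weight = apply(line_max, 2, max))
    out <- out[out$y %in% keep, , drop = FALSE]
  }
  if (nrow(out) >= 3) {
    # zC is quantized to half-slices; a running median removes isolated
    # one-line flips that would otherwise add spurious skeleton length
    out$zC <- as.numeric(stats::runmed(out$zC, 3, endrule = "median"))
  }
  attr(out, "dropped_lines") <- dropped
  out
}

#' 3-D skeleton length
#'
#' Summed Euclidean distance between center points on consecutive lines,
#' with each axis difference converted to um via the voxel size before
#' squaring. Anisotropic voxels (e.g. 0.1 x 0.1 x 1 um) make this conversion
#' mandatory for meaningful lengths.
#'
#' @param skeleton Tibble `(y, xC, zC)` in pixel coordinates, ordered by `y`.
#' @param voxel_size `(dx, dy, dz)` in um.
#' @return Length in um.
#' @export
skeleton_length <- function(skeleton, voxel_size = c(0.1, 0.1, 1)) {
  if (nrow(skeleton) < 2) {
    abort_undefined("skeleton_length", "need at least 2 center points")
  }
  skeleton <- arrange(skeleton, .data$y)
  dy <- diff(skeleton$y) * voxel_size[2]
  dx <- diff(skeleton$xC) * voxel_size[1]
  dz <- diff(skeleton$zC) * voxel_size[3]
  sum(sqrt(dy^2 + dx^2 + dz^2))
}

# Motility ----------------------------------------------------------------

#' Motility trace from per-frame lengths
#'
#' Motility between consecutive frames is `|length[f+1] - length[f]| /
#' frame_interval` (um/min). Protraction and retraction average the pairs
#' where length increased or decreased, respectively; pairs with no change
#' contribute zero motility but belong to neither. Frames with `NA` length
#' (process lost) invalidate both adjacent pairs.
#'
#' @param lengths Per-frame process lengths in um (`NA` = frame dropped).
#' @param frame_interval Minutes between frames.
#' @return A `motility_trace` object; see [glance.motility_trace()].
#' @examples
#' glance(motility_trace(c(10, 13, 7), frame_interval = 1.5))
#' @export
motility_trace <- function(lengths, frame_interval = 1.5) {
  if (length(lengths) < 2) {
    abort_undefined("motility_trace", "need lengths for at least 2 frames")
  }
  if (frame_interval <= 0) abort_validation("frame_interval must be positive.")
  dl <- diff(lengths)
  motility <- abs(dl) / frame_interval
  structure(
    list(lengths = lengths, dlength = dl, motility = motility,
         frame_interval = frame_interval),
    class = "motility_trace"
  )
}

#' @export
print.motility_trace <- function(x, ...) {
  g <- generics::glance(x)
  cat("<motility_trace> ", g$n_frames, " frames, mean motility ",
      signif(g$mean_motility, 4), " um/min (protraction ",
      signif(g$mean_protraction, 4), ", retraction ",
      signif(g$mean_retraction, 4), ")\n", sep = "")
  invisible(x)
}

#' Tidy a motility trace
#'
#' @param x A `motility_trace`.
#' @param ... Unused.
#' @return Tibble with one row per frame: `frame`, `length_um`, and the
#'   motility of the pair ending at that frame.
#' @export
tidy.motility_trace <- function(x, ...) {
  tibble(
    frame = seq_along(x$lengths),
    length_um = x$lengths,
    motility_um_min = c(NA_real_, x$motility)
  )
}

#' One-row summary of a motility trace
#'
#' @param x A `motility_trace`.
#' @param ... Unused.
#' @return Tibble with `n_frames`, `n_pairs` (valid frame pairs),
#'   `mean_motility`, `mean_protraction`, `mean_retraction` (um/min; the
#'   latter two are `NA` when no pair moved in that direction).
#' @export
glance.motility_trace <- function(x, ...) {
  ok <- !is.na(x$motility)
  up <- ok & !is.na(x$dlength) & x$dlength > 0
  down <- ok & !is.na(x$dlength) & x$dlength < 0
  mean_or_na <- function(v) if (length(v) == 0) NA_real_ else mean(v)
  tibble(
    n_frames = length(x$lengths),
    n_pairs = sum(ok),
    mean_motility = mean_or_na(x$motility[ok]),
    mean_protraction = mean_or_na(x$motility[up]),
    mean_retraction = mean_or_na(x$motility[down])
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

# Full pipeline for one process ------------------------------------------

#' Measure one process across a time-lapse recording
#'
#' Composition of the full algorithm: crop/reorient the selection, estimate
#' the background (median of the region's xy-boundary pixels unless
#' supplied), extract the per-line center points and skeleton length in each
#' frame, and compute the motility trace. Frames where the process cannot be
#' measured (fewer than 2 center points) are flagged and excluded pairwise.
#'
#' @inheritParams reorient_process
#' @param background Background intensity; `NULL` estimates it per frame as
#'   the median of the boundary pixels of the (rotated) region.
#' @param prominence_fraction,use_inflexion,smooth_sigma,floor_fraction See
#'   [extract_skeleton()].
#' @return A `process_measurement` object with per-frame lengths
#'   (`tidy()`), summary motility (`glance()`), and a `dropped_frames` field.
#' @export
measure_process <- function(stack, roi = NULL, angle = 0, background = NULL,
                            prominence_fraction = 0.5, use_inflexion = TRUE,
                            smooth_sigma = 2, floor_fraction = 0.3) {
  sub <- reorient_process(stack, roi = roi, angle = angle)
  a <- sub$intensities
  nf <- dim(a)[1]
  lengths <- rep(NA_real_, nf)
  n_lines <- integer(nf)
  dropped <- character()
  for (f in seq_len(nf)) {
    vol <- a[f, , , , drop = TRUE]
    if (length(dim(vol)) == 2) dim(vol) <- c(1, dim(vol))
    bg <- if (is.null(background)) boundary_median(vol) else background
    skel <- extract_skeleton(vol, bg,
                             prominence_fraction = prominence_fraction,
                             use_inflexion = use_inflexion,
                             smooth_sigma = smooth_sigma,
                             floor_fraction = floor_fraction)
    n_lines[f] <- nrow(skel)
    if (nrow(skel) < 2) {
      dropped <- c(dropped, paste0("frame ", f, ": process not detected (",
                                   nrow(skel), " line(s) with borders)"))
      next
    }
    lengths[f] <- skeleton_length(skel, sub$voxel_size)
  }
  if (sum(!is.na(lengths)) < 2) {
    abort("Process measurable in fewer than 2 frames; no motility trace.",
          class = "phagoquant_undefined_metric")
  }
  structure(
    list(
      lengths = tibble(frame = seq_len(nf), length_um = lengths,
                       n_lines = n_lines),
      trace = motility_trace(lengths, sub$frame_interval),
      dropped_frames = dropped,
      params = list(angle = angle, prominence_fraction = prominence_fraction,
                    use_inflexion = use_inflexion, smooth_sigma = smooth_sigma,
                    floor_fraction = floor_fraction,
                    background = background %||% "boundary median",
                    resampling = "bilinear")
    ),
    class = "process_measurement"
  )
}

#' @keywords internal
boundary_median <- function(vol) {
  ny <- dim(vol)[2]; nx <- dim(vol)[3]
  median(c(vol[, 1, ], vol[, ny, ], vol[, , 1], vol[, , nx]))
}

#' @export
print.process_measurement <- function(x, ...) {
  g <- generics::glance(x)
  cat("<process_measurement> ", g$n_frames, " frames (",
      length(x$dropped_frames), " dropped), mean length ",
      signif(mean(x$lengths$length_um, na.rm = TRUE), 4),
      " um, mean motility ", signif(g$mean_motility, 4), " um/min\n", sep = "")
  invisible(x)
}

#' @rdname measure_process
#' @param x A `process_measurement`.
#' @param ... Unused.
#' @export
tidy.process_measurement <- function(x, ...) {
  mutate(x$lengths,
         motility_um_min = c(NA_real_, x$trace$motility))
}

#' @rdname measure_process
#' @export
glance.process_measurement <- function(x, ...) {
  generics::glance(x$trace)
}

# Occupancy ---------------------------------------------------------------

#' Area-fraction occupancy
#'
#' Percentage of pixels above threshold, computed per z-slice and averaged
#' over slices — the area-fraction measure of the parenchymal volume occupied
#' by labelled microglia. For quantification the source protocol averages a
#' minimum of ten images per z-stack; `min_slices` enforces a floor when set.
#'
#' @param x A matrix (single image), a 3-D array (z, y, x), or a
#'   [zstack_series()] (its first frame is used).
#' @param threshold Intensity threshold, or `"auto"` for an iterative
#'   intermeans (isodata) threshold computed on the whole volume.
#' @param min_slices Minimum number of slices required (default 1; set to 10
#'   to enforce the acquisition rule).
#' @return Occupancy in percent, with per-slice values as attribute
#'   `per_slice`.
#' @export
occupancy_fraction <- function(x, threshold = "auto", min_slices = 1) {
  if (inherits(x, "zstack_series")) {
    x <- x$intensities[1, , , , drop = TRUE]
    if (length(dim(x)) == 2) dim(x) <- c(1, dim(x))
  }
  if (is.matrix(x)) dim(x) <- c(1, dim(x))
  if (length(dim(x)) != 3 || length(x) == 0) {
    abort_validation("Need a non-empty image, 3-D array, or zstack_series.")
  }
  nz <- dim(x)[1]
  if (nz < min_slices) {
    abort_validation("Only ", nz, " slice(s); min_slices = ", min_slices, ".")
  }
  if (identical(threshold, "auto")) threshold <- isodata_threshold(as.numeric(x))
  per_slice <- vapply(seq_len(nz),
                      function(z) 100 * mean(x[z, , ] > threshold),
                      numeric(1))
  structure(mean(per_slice), per_slice = per_slice, threshold = threshold)
}

# Iterative intermeans (isodata) threshold.
#' @keywords internal
isodata_threshold <- function(v) {
  t0 <- mean(range(v))
  for (i in 1:100) {
    lo <- v[v <= t0]; hi <- v[v > t0]
    if (length(lo) == 0 || length(hi) == 0) break
    t1 <- (mean(lo) + mean(hi)) / 2
    if (abs(t1 - t0) < 1e-10) break
    t0 <- t1
  }
  t0
}
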