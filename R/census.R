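# Count-based phagocytosis metrics computed from per-sample cell censuses.
#
# A census row records, for one animal/region/culture, the total number of
# apoptotic cells (by pyknosis/karyorrhexis and/or activated caspase-3), how
# many of them sit inside a closed microglial pouch, the number of microglia,
# and the histogram of microglia by number of phagocytic pouches. All internal
# values are fractions; percent formatting is left to the reporting layer.

#' Phagocytic index
#'
#' Proportion of apoptotic cells completely engulfed by microglia,
#' `apo_phagocytosed / apo_total`. When no apoptotic cells are present the
#' index is undefined (apoptosis can be undetectable in control tissue); with
#' `strict = TRUE` this raises an error naming the sample, otherwise `NA` is
#' returned.
#'
#' @param apo_phagocytosed Number of apoptotic cells inside microglial pouches.
#' @param apo_total Total number of apoptotic cells.
#' @param sample_id Optional label used in error messages.
#' @param strict Error on an undefined metric (default) or return `NA`.
#' @return A fraction in `[0, 1]`.
#' @examples
#' ph_index(15, 30)
#' @export
ph_index <- function(apo_phagocytosed, apo_total, sample_id = NULL,
                     strict = TRUE) {
  if (apo_phagocytosed < 0 || apo_total < 0) {
    abort_validation("Counts must be non-negative.")
  }
  if (apo_phagocytosed > apo_total) {
    abort_validation(
      "apo_phagocytosed (", apo_phagocytosed, ") exceeds apo_total (",
      apo_total, ")", if (!is.null(sample_id)) paste0(" in sample '", sample_id, "'"), "."
    )
  }
  if (apo_total == 0) {
    if (strict) abort_undefined("ph_index", "no apoptotic cells (apo_total = 0)", sample_id)
    return(NA_real_)
  }
  apo_phagocytosed / apo_total
}

#' Weighted phagocytic capacity
#'
#' Mean number of phagocytic pouches per microglia,
#' `sum(n * count(n)) / total_cells`, where the histogram counts microglia by
#' their number of pouches (n >= 1); cells with zero pouches are implicit.
#' The same formula applies to phagoptosis (engulfment of nonapoptotic cells)
#' when the histogram counts phagoptotic pouches. Units: pouches per cell
#' ("parts per unit", ppu).
#'
#' @param histogram Either a two-column data frame with columns `n_pouches`
#'   and `count`, or a numeric vector of counts named by pouch number.
#'   An empty histogram means no phagocytic cells.
#' @param total_cells Total number of microglia (including non-phagocytic).
#' @param sample_id Optional label used in error messages.
#' @param strict Error on an undefined metric (default) or return `NA`.
#' @return Mean pouches per cell (ppu).
#' @examples
#' weighted_capacity(c(`1` = 15, `2` = 5), 100)
#' @export
weighted_capacity <- function(histogram, total_cells, sample_id = NULL,
                              strict = TRUE) {
  h <- as_pouch_histogram(histogram)
  if (total_cells == 0) {
    if (strict) abort_undefined("weighted_capacity", "no cells (total_cells = 0)", sample_id)
    return(NA_real_)
  }
  if (total_cells < 0) abort_validation("total_cells must be non-negative.")
  if (sum(h$count) > total_cells) {
    abort_validation(
      "Pouch histogram counts (", sum(h$count), ") exceed total_cells (",
      total_cells, ")", if (!is.null(sample_id)) paste0(" in sample '", sample_id, "'"), "."
    )
  }
  sum(h$n_pouches * h$count) / total_cells
}

# Normalise the two accepted histogram representations.
#' @keywords internal
as_pouch_histogram <- function(histogram) {
  if (is.data.frame(histogram)) {
    if (!all(c("n_pouches", "count") %in% names(histogram))) {
      abort_validation("Histogram data frame needs columns 'n_pouches' and 'count'.")
    }
    h <- tibble(n_pouches = as.numeric(histogram$n_pouches),
                count = as.numeric(histogram$count))
  } else if (is.numeric(histogram)) {
    if (length(histogram) > 0 && is.null(names(histogram))) {
      abort_validation("A numeric histogram must be named by pouch number.")
    }
    h <- tibble(n_pouches = as.numeric(names(histogram)),
                count = as.numeric(histogram))
  } else {
    abort_validation("Unsupported histogram representation.")
  }
  if (any(h$count < 0)) abort_validation("Histogram counts must be non-negative.")
  if (any(h$n_pouches < 1)) {
    abort_validation("Histogram keys must be >= 1; cells with 0 pouches are implicit.")
  }
  h
}

#' Net phagocytosis
#'
#' Number of microglia multiplied by their weighted phagocytic capacity:
#' the expected number of cells currently being engulfed.
#'
#' @inheritParams weighted_capacity
#' @param microglia_total Number of microglia.
#' @return Cells being engulfed.
#' @export
net_phagocytosis <- function(histogram, microglia_total, sample_id = NULL) {
  if (microglia_total < 0) abort_validation("microglia_total must be non-negative.")
  if (microglia_total == 0) return(0)
  microglia_total * weighted_capacity(histogram, microglia_total, sample_id)
}

#' Phagocytosis/apoptosis coupling ratio
#'
#' Net phagocytosis divided by the total number of apoptotic cells:
#' `(capacity * microglia_total) / apo_total`. A value of 1 means phagocytosis
#' matches apoptosis. Figures usually report it as a fold change over the mean
#' raw ratio of a baseline (control) group; see [phagocytosis_summary()].
#'
#' @param capacity Weighted phagocytic capacity (ppu).
#' @param microglia_total Number of microglia.
#' @param apo_total Total number of apoptotic cells.
#' @inheritParams ph_index
#' @return Raw coupling ratio (dimensionless).
#' @export
ph_a_coupling <- function(capacity, microglia_total, apo_total,
                          sample_id = NULL, strict = TRUE) {
  if (apo_total == 0) {
    if (strict) abort_undefined("ph_a_coupling", "no apoptotic cells (apo_total = 0)", sample_id)
    return(NA_real_)
  }
  capacity * microglia_total / apo_total
}

#' Cell density
#'
#' Cells per cubic millimetre. Inverse of the stereological step that converts
#' densities to absolute numbers via the region volume.
#'
#' @param count Cell count.
#' @param volume_mm3 Region volume in mm^3.
#' @return Density in cells/mm^3.
#' @export
cell_density <- function(count, volume_mm3) {
  if (any(volume_mm3 <= 0)) abort_validation("volume_mm3 must be positive.")
  count / volume_mm3
}

#' Distance-to-process histogram
#'
#' Bins the distances of (typically nonphagocytosed) apoptotic cells to the
#' nearest microglial process and returns per-bin proportions. Bins are
#' half-open `[lo, hi)`; the final bin is open-ended. Default edges 0, 0.5, 3
#' and 10 um follow the thresholds used to describe apposed versus far-off
#' apoptotic cells.
#'
#' @param distances Distances in um, non-negative.
#' @param bin_edges Strictly increasing finite lower edges; the last bin is
#'   `[max(bin_edges), Inf)`.
#' @return Tibble with `lower`, `upper`, `label`, `n`, `prop`.
#' @export
distance_histogram <- function(distances, bin_edges = c(0, 0.5, 3, 10)) {
  if (length(distances) == 0) {
    abort_undefined("distance_histogram", "no distances supplied")
  }
  if (any(distances < 0)) abort_validation("Distances must be non-negative.")
  edges <- unique(c(bin_edges[is.finite(bin_edges)]))
  if (is.unsorted(edges, strictly = TRUE)) {
    abort_validation("bin_edges must be strictly increasing.")
  }
  breaks <- c(edges, Inf)
  idx <- cut(distances, breaks = breaks, right = FALSE, labels = FALSE)
  if (anyNA(idx)) abort_validation("Distances below the first bin edge.")
  counts <- tabulate(idx, nbins = length(breaks) - 1)
  tibble(
    lower = breaks[-length(breaks)],
    upper = breaks[-1],
    label = paste0("[", lower, ", ", ifelse(is.finite(upper), upper, "Inf"), ")"),
    n = counts,
    prop = counts / sum(counts)
  )
}

#' Coefficient of determination of a simple linear regression
#'
#' Ordinary least-squares R^2 of `y` on `x`, e.g. for relating the phagocytic
#' index to the number of apoptotic cells across animals.
#'
#' @param x,y Paired numeric vectors, at least 3 complete pairs; `x` must not
#'   be constant.
#' @return R^2 in `[0, 1]`.
#' @export
linear_r2 <- function(x, y) {
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) abort_validation("Need at least 3 paired points.")
  if (sd(x) == 0) abort_undefined("linear_r2", "x is constant")
  suppressWarnings(summary(lm(y ~ x))$r.squared)
}

# Per-sample summary -----------------------------------------------------

#' Summarise phagocytosis metrics for a census table
#'
#' Computes, per sample, the phagocytic index, weighted phagocytic (and
#' optionally phagoptotic) capacity, net phagocytosis, raw
#' phagocytosis/apoptosis coupling and its fold change over the mean raw
#' coupling of a named baseline group, plus apoptotic-cell and microglial
#' densities. Undefined metrics (zero denominators) become `NA` with a reason
#' recorded in the `notes` column rather than being forced to zero.
#'
#' @param census Data frame, one row per sample, with columns `sample_id`,
#'   `group`, `apo_total`, `apo_phagocytosed`, `microglia_total` and
#'   optionally `region_volume_mm3`.
#' @param pouches Optional long table `(sample_id, n_pouches, count)` of
#'   microglia counted by number of phagocytic pouches; samples absent from it
#'   have no phagocytic microglia.
#' @param phagoptosis Optional long table in the same layout counting
#'   phagoptotic pouches (engulfed nonapoptotic cells).
#' @param baseline Name of the baseline group for the coupling fold change;
#'   `NULL` skips fold changes.
#' @return Tibble with one row per sample.
#' @examples
#' census <- tibble::tibble(
#'   sample_id = c("a", "b"), group = c("control", "challenge"),
#'   apo_total = c(20, 60), apo_phagocytosed = c(18, 54),
#'   microglia_total = c(100, 100), region_volume_mm3 = 0.2
#' )
#' pouches <- tibble::tibble(
#'   sample_id = c("a", "b", "b"), n_pouches = c(1, 1, 2),
#'   count = c(18, 40, 7)
#' )
#' phagocytosis_summary(census, pouches, baseline = "control")
#' @export
phagocytosis_summary <- function(census, pouches = NULL, phagoptosis = NULL,
                                 baseline = NULL) {
  census <- validate_census(census, pouches)
  rows <- purrr::pmap(census, function(sample_id, group, apo_total,
                                       apo_phagocytosed, microglia_total,
                                       region_volume_mm3, ...) {
    notes <- character()
    hist_ph <- census_histogram(pouches, sample_id)
    hist_php <- census_histogram(phagoptosis, sample_id)

    idx <- ph_index(apo_phagocytosed, apo_total, sample_id, strict = FALSE)
    if (is.na(idx)) notes <- c(notes, "ph_index undefined: apo_total = 0")

    capacity <- weighted_capacity(hist_ph, microglia_total, sample_id, strict = FALSE)
    if (is.na(capacity)) notes <- c(notes, "ph_capacity undefined: microglia_total = 0")

    php <- if (is.null(phagoptosis)) NA_real_ else {
      weighted_capacity(hist_php, microglia_total, sample_id, strict = FALSE)
    }

    net <- if (is.na(capacity)) NA_real_ else microglia_total * capacity
    raw <- if (is.na(capacity)) NA_real_ else {
      ph_a_coupling(capacity, microglia_total, apo_total, sample_id, strict = FALSE)
    }
    if (!is.na(capacity) && is.na(raw)) {
      notes <- c(notes, "ph_a_coupling undefined: apo_total = 0")
    }

    vol <- region_volume_mm3
    tibble(
      sample_id = sample_id, group = group,
      ph_index = idx, ph_capacity = capacity, php_capacity = php,
      net_phagocytosis = net, ph_a_raw = raw,
      apo_density = if (is.na(vol)) NA_real_ else cell_density(apo_total, vol),
      microglia_density = if (is.na(vol)) NA_real_ else cell_density(microglia_total, vol),
      notes = paste(notes, collapse = "; ")
    )
  })
  out <- bind_rows(rows)
  if (!is.null(baseline)) {
    if (!baseline %in% out$group) {
      abort_validation("Baseline group '", baseline, "' not present in census.")
    }
    base_mean <- mean(out$ph_a_raw[out$group == baseline], na.rm = TRUE)
    if (!is.finite(base_mean) || base_mean <= 0) {
      abort_undefined("ph_a_fold_change", "baseline mean raw coupling is not positive")
    }
    out <- mutate(out, ph_a_fold = .data$ph_a_raw / base_mean)
  }
  out
}

#' Per-group means of a phagocytosis summary
#'
#' @param summary Output of [phagocytosis_summary()].
#' @return Tibble of group means (NA-removed) for each metric.
#' @export
phagocytosis_group_summary <- function(summary) {
  summary %>%
    group_by(.data$group) %>%
    summarise(
      dplyr::across(
        dplyr::where(is.numeric),
        ~ mean(.x, na.rm = TRUE)
      ),
      n_samples = dplyr::n(),
      .groups = "drop"
    )
}

#' @keywords internal
census_histogram <- function(pouches, id) {
  if (is.null(pouches)) {
    return(tibble(n_pouches = numeric(), count = numeric()))
  }
  h <- pouches[pouches$sample_id == id, c("n_pouches", "count"), drop = FALSE]
  as_pouch_histogram(as_tibble(h))
}

#' Validate a census table
#'
#' Checks the census schema and its invariants (non-negative counts,
#' engulfed <= total, histogram counts <= microglia, positive volumes) and
#' reports offending rows by number.
#'
#' @inheritParams phagocytosis_summary
#' @return The census as a tibble with a `region_volume_mm3` column (NA when
#'   not supplied).
#' @export
validate_census <- function(census, pouches = NULL) {
  required <- c("sample_id", "group", "apo_total", "apo_phagocytosed",
                "microglia_total")
  missing_cols <- setdiff(required, names(census))
  if (length(missing_cols) > 0) {
    abort_validation("Census is missing column(s): ",
                     paste(missing_cols, collapse = ", "), ".")
  }
  census <- as_tibble(census)
  if (!"region_volume_mm3" %in% names(census)) census$region_volume_mm3 <- NA_real_
  bad <- function(cond, what) {
    rows <- which(cond)
    if (length(rows) > 0) {
      abort_validation(what, " in census row(s) ", paste(rows, collapse = ", "), ".")
    }
  }
  bad(census$apo_total < 0 | census$apo_phagocytosed < 0 |
        census$microglia_total < 0, "Negative counts")
  bad(census$apo_phagocytosed > census$apo_total,
      "apo_phagocytosed exceeds apo_total")
  bad(!is.na(census$region_volume_mm3) & census$region_volume_mm3 <= 0,
      "Non-positive region volume")
  if (anyDuplicated(census$sample_id)) {
    abort_validation("Duplicated sample_id values in census.")
  }
  if (!is.null(pouches)) {
    tot <- pouches %>%
      group_by(.data$sample_id) %>%
      summarise(pouch_cells = sum(.data$count), .groups = "drop") %>%
      left_join(select(census, "sample_id", "microglia_total"), by = "sample_id")
    over <- tot$pouch_cells > tot$microglia_total
    if (any(over, na.rm = TRUE)) {
      abort_validation("Pouch histogram counts exceed microglia_total for sample(s): ",
                       paste(tot$sample_id[which(over)], collapse = ", "), ".")
    }
    orphan <- setdiff(unique(pouches$sample_id), census$sample_id)
    if (length(orphan) > 0) {
      abort_validation("Pouch table references unknown sample(s): ",
                       paste(orphan, collapse = ", "), ".")
    }
  }
  census
}
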