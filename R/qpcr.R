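# Efficiency-corrected relative expression for qPCR.
#
# Amplification efficiency is estimated per primer pair from a standard curve
# of serial dilutions (Ct against log10 relative concentration); relative
# expression corrects the classic ddCt fold change for the measured
# efficiencies of target and reference genes:
#
#   fold = (1 + eff_target)^dCt_target / (1 + eff_ref)^dCt_ref
#
# The source formula prints (Ct_sample - Ct_control) in BOTH exponents; taken
# literally, higher expression in the sample yields a fold below 1. The
# default convention here is the conventional direction
# dCt = Ct_control - Ct_sample (fold > 1 means higher expression in the
# sample); `convention = "as_printed"` reproduces the literal form. Both are
# recorded on the result.

#' Amplification efficiency from a dilution standard curve
#'
#' Least-squares fit of `Ct ~ log10(concentration)`; the efficiency is
#' `10^(-1/slope) - 1` (1.0 = perfect doubling each cycle, slope -3.32).
#'
#' @param ct Observed Ct values (cycles).
#' @param concentration Relative template concentrations, strictly decreasing
#'   (e.g. `1, 0.5, 0.25, ...` for 1:2 serial dilutions).
#' @param gene Optional gene label stored on the model.
#' @return A `qpcr_efficiency` object with fields `gene`, `efficiency`,
#'   `slope`, `intercept`, `r_squared`; see [tidy.qpcr_efficiency()].
#' @examples
#' efficiency_from_dilutions(c(20, 21, 22), c(1, 0.5, 0.25))
#' @export
efficiency_from_dilutions <- function(ct, concentration, gene = NA_character_) {
  if (length(ct) != length(concentration)) {
    abort_validation("ct and concentration must have the same length.")
  }
  if (length(ct) < 3) abort_validation("Need at least 3 dilution points.")
  if (any(concentration <= 0)) abort_validation("Concentrations must be positive.")
  if (is.unsorted(rev(concentration), strictly = TRUE)) {
    abort_validation("Concentrations must be strictly decreasing.")
  }
  fit <- lm(ct ~ log10(concentration))
  slope <- unname(coef(fit)[2])
  # summary.lm warns on exact fits, which are routine for validation curves
  r2 <- suppressWarnings(summary(fit)$r.squared)
  if (is.unsorted(ct)) {
    warn(paste0("Ct values are not monotone increasing along the dilution ",
                "series (r^2 = ", signif(r2, 4), "); check the standard curve."))
  }
  if (!is.finite(slope) || slope >= 0) {
    abort_validation("Standard-curve slope must be negative; got ", signif(slope, 4), ".")
  }
  structure(
    list(gene = gene, efficiency = 10^(-1 / slope) - 1, slope = slope,
         intercept = unname(coef(fit)[1]), r_squared = r2),
    class = "qpcr_efficiency"
  )
}

#' @export
print.qpcr_efficiency <- function(x, ...) {
  cat("<qpcr_efficiency>", if (!is.na(x$gene)) paste0(" ", x$gene), ": eff = ",
      signif(x$efficiency, 4), " (slope ", signif(x$slope, 4),
      ", r^2 ", signif(x$r_squared, 4), ")\n", sep = "")
  invisible(x)
}

#' Tidy a qPCR efficiency model
#'
#' @param x A `qpcr_efficiency`.
#' @param ... Unused.
#' @return Tibble of standard-curve coefficients.
#' @export
tidy.qpcr_efficiency <- function(x, ...) {
  tibble(term = c("intercept", "slope"),
         estimate = c(x$intercept, x$slope))
}

#' @rdname tidy.qpcr_efficiency
#' @return `glance()`: one-row tibble with `gene`, `efficiency`, `slope`,
#'   `r_squared`.
#' @export
glance.qpcr_efficiency <- function(x, ...) {
  tibble(gene = x$gene, efficiency = x$efficiency, slope = x$slope,
         r_squared = x$r_squared)
}

#' Efficiency-corrected relative amount
#'
#' @param ct_target_sample,ct_target_control Mean target-gene Ct in the
#'   sample and control conditions.
#' @param ct_ref_sample,ct_ref_control Mean reference-gene Ct in the sample
#'   and control conditions.
#' @param eff_target,eff_ref Amplification efficiencies in (0, 1.2]
#'   (1 = perfect doubling).
#' @param convention `"conventional"` (default): `dCt = Ct_control -
#'   Ct_sample`, so fold > 1 means higher expression in the sample;
#'   `"as_printed"`: `dCt = Ct_sample - Ct_control`, the literal published
#'   form (inverts the result).
#' @return Fold change (dimensionless).
#' @examples
#' # with perfect efficiencies this is the classic 2^-ddCt
#' relative_amount(17, 20, 19, 20, 1, 1)
#' @export
relative_amount <- function(ct_target_sample, ct_target_control,
                            ct_ref_sample, ct_ref_control,
                            eff_target = 1, eff_ref = 1,
                            convention = c("conventional", "as_printed")) {
  convention <- arg_match(convention)
  if (any(c(eff_target, eff_ref) <= 0) || any(c(eff_target, eff_ref) > 1.2)) {
    abort_validation("Efficiencies must be in (0, 1.2].")
  }
  sign <- if (convention == "conventional") 1 else -1
  d_target <- sign * (ct_target_control - ct_target_sample)
  d_ref <- sign * (ct_ref_control - ct_ref_sample)
  (1 + eff_target)^d_target / (1 + eff_ref)^d_ref
}

#' Pick the reference gene with lower within-group variability
#'
#' Given a long Ct table and candidate reference genes, returns the candidate
#' whose Ct values have the smallest mean within-group variance (the rule
#' used to choose between alternative reference genes).
#'
#' @param ct_table Long table with columns `group`, `gene`, `ct`.
#' @param candidates Character vector of candidate reference genes.
#' @return The selected gene name.
#' @export
choose_reference_gene <- function(ct_table, candidates) {
  missing <- setdiff(candidates, unique(ct_table$gene))
  if (length(missing) > 0) {
    abort_validation("Candidate gene(s) absent from table: ",
                     paste(missing, collapse = ", "), ".")
  }
  scores <- ct_table %>%
    filter(.data$gene %in% candidates) %>%
    group_by(.data$gene, .data$group) %>%
    summarise(v = var(.data$ct), .groups = "drop_last") %>%
    summarise(score = mean(.data$v, na.rm = TRUE), .groups = "drop")
  scores$gene[which.min(scores$score)]
}

#' Relative expression for a long Ct table
#'
#' Averages replicate Cts per (sample, gene), averages sample Cts per group,
#' and computes the efficiency-corrected fold change of every target gene in
#' every group relative to the control group.
#'
#' @param ct_table Long table with columns `sample_id`, `group`, `gene`,
#'   `ct` (one row per replicate well).
#' @param efficiencies Named numeric vector of amplification efficiencies per
#'   gene (genes absent default to 1, perfect doubling).
#' @param reference_gene Reference (housekeeping) gene name.
#' @param control_group Name of the baseline group.
#' @param convention See [relative_amount()].
#' @return Tibble `(group, gene, fold_change)` for target genes; the control
#'   group's fold change is 1 by construction.
#' @export
relative_expression <- function(ct_table, efficiencies = NULL,
                                reference_gene, control_group,
                                convention = c("conventional", "as_printed")) {
  convention <- arg_match(convention)
  needed <- c("sample_id", "group", "gene", "ct")
  if (!all(needed %in% names(ct_table))) {
    abort_validation("ct_table needs columns: ", paste(needed, collapse = ", "), ".")
  }
  if (!reference_gene %in% ct_table$gene) {
    abort_validation("Reference gene '", reference_gene, "' absent from table.")
  }
  if (!control_group %in% ct_table$group) {
    abort_validation("Control group '", control_group, "' absent from table.")
  }
  eff_of <- function(g) {
    if (!is.null(efficiencies) && g %in% names(efficiencies)) efficiencies[[g]] else 1
  }
  means <- ct_table %>%
    group_by(.data$group, .data$gene) %>%
    summarise(ct = mean(.data$ct), .groups = "drop")
  ref <- filter(means, .data$gene == reference_gene)
  ref_control <- ref$ct[ref$group == control_group]
  targets <- filter(means, .data$gene != reference_gene)
  control_ct <- targets %>%
    filter(.data$group == control_group) %>%
    select("gene", ct_control = "ct")
  targets %>%
    left_join(control_ct, by = "gene") %>%
    left_join(select(ref, "group", ct_ref = "ct"), by = "group") %>%
    mutate(fold_change = purrr::pmap_dbl(
      list(.data$ct, .data$ct_control, .data$ct_ref, .data$gene),
      function(ct_s, ct_c, ct_r, g) {
        relative_amount(ct_s, ct_c, ct_r, ref_control,
                        eff_target = eff_of(g), eff_ref = eff_of(reference_gene),
                        convention = convention)
      }
    )) %>%
    select("group", "gene", "fold_change") %>%
    arrange(.data$gene, .data$group)
}
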