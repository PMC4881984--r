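# Apoptotic-cell clearance time.
#
# Under steady state, a cohort of labelled cells undergoing apoptosis is
# cleared by phagocytes at flux (cells present)/tau, so over an observation
# window Dt the number cleared is present * Dt / tau, and conversely
# tau = present * Dt / cleared. The multi-step inference compares a reference
# condition with known tau against a test condition in which the same total
# cohort (present + cleared) must hold, and back-computes the test condition's
# clearance time from its excess of still-present apoptotic cells.

#' Cells cleared over an observation window
#'
#' Steady-state flux of apoptotic-cell removal: `apo_present * delta_t / tau`.
#'
#' @param apo_present Labelled apoptotic cells present in the tissue (cells).
#' @param tau Clearance time in hours.
#' @param delta_t Observation window in hours.
#' @return Cells cleared over the window.
#' @examples
#' cleared_count(10, tau = 1.5, delta_t = 24)
#' @export
cleared_count <- function(apo_present, tau, delta_t) {
  if (any(tau <= 0)) abort_validation("tau must be positive.")
  if (any(delta_t <= 0)) abort_validation("delta_t must be positive.")
  if (any(apo_present < 0)) abort_validation("apo_present must be non-negative.")
  apo_present * delta_t / tau
}

#' Infer the clearance time of a test condition
#'
#' Given the count of labelled apoptotic cells present in a reference
#' condition with known clearance time `tau_ref`, the total cohort is
#' `apo_present_ref + cleared_count(apo_present_ref, tau_ref, delta_t)`.
#' Assuming the test condition shares that total (equal survival of the
#' labelled cohort), its cleared count is `total - apo_present_test`, and its
#' clearance time is `apo_present_test * delta_t / cleared_test`.
#'
#' The equal-total assumption is a hard precondition: when
#' `apo_present_test >= total` the inference is infeasible and an error is
#' raised.
#'
#' @param apo_present_ref Labelled apoptotic cells present, reference group.
#' @param apo_present_test Labelled apoptotic cells present, test group.
#' @param tau_ref Reference clearance time in hours. Defaults to 1.5 h, the
#'   physiological clearance time in the adult neurogenic niche; always
#'   override when another baseline applies.
#' @param delta_t Observation window in hours; the time between the insult
#'   and sacrifice. Defaults to 24 h.
#' @param details Return the intermediate quantities as a one-row tibble
#'   instead of the scalar.
#' @return Test-condition clearance time in hours, or a one-row tibble with
#'   `total_cohort`, `cleared_ref`, `cleared_test`, `tau_test` when
#'   `details = TRUE`.
#' @examples
#' infer_clearance_time(10, 35.3, tau_ref = 1.5, delta_t = 24)
#' @export
infer_clearance_time <- function(apo_present_ref, apo_present_test,
                                 tau_ref = 1.5, delta_t = 24,
                                 details = FALSE) {
  if (apo_present_test < 0) abort_validation("apo_present_test must be non-negative.")
  cleared_ref <- cleared_count(apo_present_ref, tau_ref, delta_t)
  total <- apo_present_ref + cleared_ref
  cleared_test <- total - apo_present_test
  if (cleared_test <= 0) {
    abort(
      paste0(
        "Clearance-time inference infeasible: test group has ",
        apo_present_test, " labelled apoptotic cells present but the ",
        "inferred total cohort is only ", signif(total, 6),
        ". The equal-total assumption (same cohort size in reference and ",
        "test conditions) is violated."
      ),
      class = "phagoquant_infeasible"
    )
  }
  tau_test <- apo_present_test * delta_t / cleared_test
  if (!details) return(tau_test)
  tibble(
    total_cohort = total, cleared_ref = cleared_ref,
    cleared_test = cleared_test, tau_test = tau_test
  )
}

#' Recover the clearance time from a simulated cohort series
#'
#' Applies `tau = present(t2) * (t2 - t1) / (cleared(t2) - cleared(t1))` to a
#' time-stamped tally of present and cumulatively cleared labelled apoptotic
#' cells, e.g. the output of [simulate_clearance_cohort()]. Used to check
#' that the steady-state formula recovers the clearance time that generated
#' the data.
#'
#' @param cohort Data frame with columns `time_h`, `present`, `cleared_cum`.
#' @param t1,t2 Window endpoints in hours; values are taken at the nearest
#'   tabulated times. Defaults to the last window spanning `delta_t`.
#' @param delta_t Window width used when `t1`/`t2` are not given.
#' @return Estimated clearance time in hours.
#' @export
recover_clearance_time <- function(cohort, t1 = NULL, t2 = NULL, delta_t = 24) {
  stopifnot(all(c("time_h", "present", "cleared_cum") %in% names(cohort)))
  if (is.null(t2)) t2 <- max(cohort$time_h)
  if (is.null(t1)) t1 <- t2 - delta_t
  if (t1 < min(cohort$time_h) || t2 > max(cohort$time_h) || t1 >= t2) {
    abort_validation("Window [", t1, ", ", t2, "] h not covered by the series.")
  }
  at <- function(t, col) cohort[[col]][which.min(abs(cohort$time_h - t))]
  dclear <- at(t2, "cleared_cum") - at(t1, "cleared_cum")
  if (dclear <= 0) {
    abort(
      "No cells were cleared over the window; clearance time is undefined.",
      class = "phagoquant_infeasible"
    )
  }
  at(t2, "present") * (t2 - t1) / dclear
}
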