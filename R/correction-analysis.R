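#' Telophase correction outcome for one or more divisions
#'
#' Computes the signed correction `delta = theta - phi` (division angle one
#' hour after anaphase onset minus the angle at onset) and classifies the
#' outcome from the entry/exit orientation bins:
#'
#' * entry planar/perpendicular, exit in the same bin -> `stable_planar` /
#'   `stable_perpendicular`
#' * entry oblique, exit planar -> `corrected_planar`
#' * entry oblique, exit perpendicular -> `corrected_perpendicular`
#' * entry oblique, exit oblique -> `uncorrected_oblique`
#' * entry planar/perpendicular, exit in a different bin -> `destabilized`
#'
#' "Correction" is a bin change, not a magnitude threshold. The sign
#' convention is fixed as theta minus phi (negative = toward planar).
#'
#' @param phi numeric vector of anaphase-onset angles in `[0, 90]`.
#' @param theta numeric vector of +1 h angles in `[0, 90]`.
#' @return data.frame with columns `phi`, `theta`, `delta`, `entry_class`,
#'   `exit_class`, `outcome`.
#' @examples
#' correction_outcome(50, 12)  # corrected_planar, delta -38
#' @export
correction_outcome <- function(phi, theta) {
  entry <- classify_orientation(phi)
  exit <- classify_orientation(theta)
  outcome <- character(length(entry))
  obl <- entry == "oblique"
  outcome[obl & exit == "planar"] <- "corrected_planar"
  outcome[obl & exit == "perpendicular"] <- "corrected_perpendicular"
  outcome[obl & exit == "oblique"] <- "uncorrected_oblique"
  same <- !obl & (entry == exit)
  outcome[same & entry == "planar"] <- "stable_planar"
  outcome[same & entry == "perpendicular"] <- "stable_perpendicular"
  outcome[!obl & entry != exit] <- "destabilized"
  data.frame(phi = phi, theta = theta, delta = theta - phi,
             entry_class = entry, exit_class = exit,
             outcome = factor(outcome, levels = correction_outcome_levels()))
}

#' @rdname correction_outcome
#' @export
correction_outcome_levels <- function() {
  c("stable_planar", "stable_perpendicular", "corrected_planar",
    "corrected_perpendicular", "uncorrected_oblique", "destabilized")
}

division_table <- function(records) {
  if (inherits(records, "division_cohort")) records$divisions else records
}

#' Correction outcomes conditioned on basal contact, oblique entries only
#'
#' For divisions that enter anaphase obliquely, tabulates the proportion of
#' each correction outcome separately for apical daughters that retain vs
#' lose basement-membrane contact at anaphase onset. Proportions within each
#' contact condition sum to 1; a condition with no records is reported as
#' `NA`, not 0.
#'
#' @param records a `division_cohort` or a data.frame with columns `phi`,
#'   `theta`, `contact_onset`.
#' @return data.frame with one row per (contact condition, outcome) cell:
#'   columns `contact_onset`, `outcome`, `count`, `proportion`.
#' @export
contact_conditioned_summary <- function(records) {
  df <- division_table(records)
  oc <- correction_outcome(df$phi, df$theta)
  keep <- oc$entry_class == "oblique"
  if (!any(keep)) {
    stop("contact_conditioned_summary: no oblique-entry records",
         call. = FALSE)
  }
  oc <- oc[keep, , drop = FALSE]
  contact <- df$contact_onset[keep]
  out <- expand.grid(contact_onset = c(TRUE, FALSE),
                     outcome = correction_outcome_levels(),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$count <- mapply(function(ct, o) {
    sum(contact == ct & oc$outcome == o)
  }, out$contact_onset, out$outcome)
  totals <- vapply(out$contact_onset, function(ct) sum(contact == ct),
                   numeric(1))
  out$proportion <- ifelse(totals > 0, out$count / totals, NA_real_)
  out
}

#' Settling time of a division-orientation trajectory
#'
#' The earliest time point from which the trajectory stays within
#' `tolerance` degrees of its final angle, i.e. the time at which telophase
#' reorientation is complete at the sampling resolution. A trajectory that
#' never leaves the tolerance band of its final angle settles at 0.
#'
#' @param times numeric vector of frame times in minutes (increasing).
#' @param angles numeric vector of unsigned angles, same length as `times`.
#' @param tolerance settling tolerance in degrees (default 5).
#' @return settling time in minutes.
#' @export
settling_time <- function(times, angles, tolerance = 5) {
  if (length(times) != length(angles) || length(times) < 2L) {
    stop("settling_time: malformed trajectory", call. = FALSE)
  }
  if (is.unsorted(times, strictly = TRUE)) {
    stop("settling_time: times must be strictly increasing", call. = FALSE)
  }
  final <- angles[length(angles)]
  bad <- which(abs(angles - final) > tolerance)
  if (!length(bad)) return(0)
  times[max(bad) + 1L]
}

#' Per-division settling times for a simulated or measured cohort
#'
#' @param cohort a `division_cohort` (see [simulate_cohort()]) or a long
#'   trajectory data.frame with columns `division_id`, `t_min`, `angle_deg`.
#' @param tolerance settling tolerance in degrees.
#' @return data.frame with columns `division_id`, `settling_min`.
#' @export
settling_times <- function(cohort, tolerance = 5) {
  traj <- if (inherits(cohort, "division_cohort")) cohort$trajectories else cohort
  sp <- split(traj, traj$division_id)
  data.frame(division_id = names(sp),
             settling_min = vapply(sp, function(d) {
               d <- d[order(d$t_min), ]
               settling_time(d$t_min, d$angle_deg, tolerance)
             }, numeric(1)),
             row.names = NULL)
}

#' Accuracy of basal contact as a predictor of correction direction
#'
#' Among oblique-entry divisions, the fraction whose outcome matches the
#' contact rule: contact retained at anaphase onset and corrected to planar,
#' or contact lost and corrected to perpendicular.
#'
#' @param records a `division_cohort` or data.frame with columns `phi`,
#'   `theta`, `contact_onset`.
#' @return fraction in `[0, 1]`.
#' @export
contact_prediction_accuracy <- function(records) {
  df <- division_table(records)
  oc <- correction_outcome(df$phi, df$theta)
  keep <- oc$entry_class == "oblique" & !is.na(df$contact_onset)
  if (!any(keep)) {
    stop("contact_prediction_accuracy: no oblique-entry records with contact",
         call. = FALSE)
  }
  concordant <- (df$contact_onset[keep] &
                   oc$outcome[keep] == "corrected_planar") |
                (!df$contact_onset[keep] &
                   oc$outcome[keep] == "corrected_perpendicular")
  mean(concordant)
}
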