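#' Genotype configuration for the two-step division-orientation model
#'
#' Parameter set for the stochastic simulator: step 1 draws the
#' anaphase-onset angle phi (LGN-biased entry), step 2 relaxes oblique
#' entries toward a planar or perpendicular target depending on whether the
#' apical daughter retains basement-membrane contact.
#'
#' @param name preset/genotype label.
#' @param p_lgn_apical probability that LGN is recruited to the apical
#'   cortex in a given mitosis (forced `TRUE` for perpendicular entries).
#' @param entry_mode `"uniform"` (phi ~ Uniform\[0, 90\]) or `"mixture"`
#'   (orientation bin drawn from `entry_mixture`, phi uniform within bin).
#' @param entry_mixture length-3 proportions over planar/oblique/
#'   perpendicular entry bins (must sum to 1; used when
#'   `entry_mode = "mixture"`).
#' @param planar_correction_enabled,perpendicular_correction_enabled logical
#'   switches for contact-retained (planar-directed) and contact-lost
#'   (perpendicular-directed) correction of oblique entries.
#' @param random_correction_on_contact_loss logical; when `TRUE`,
#'   contact-lost oblique entries relax toward a uniformly random target in
#'   `[0, 90]` instead of the perpendicular target (the early-stratification
#'   behaviour, where perpendicular correction is unavailable).
#' @param p_contact_retained probability that an oblique entry's apical
#'   daughter retains basal contact at anaphase onset (planar entries always
#'   retain contact; perpendicular entries are recorded as contact lost).
#' @param p_contact_lost_during_telophase probability that a
#'   contact-retaining oblique daughter subsequently loses contact during
#'   telophase (recorded in `contact_end`; conditioning of the correction
#'   direction uses `contact_onset`).
#' @param tau_correction relaxation time constant in minutes.
#' @param angle_noise_sigma per-frame folded Gaussian angular noise, degrees.
#' @param target_planar,target_perpendicular relaxation targets in degrees;
#'   must lie in the planar and perpendicular bins respectively.
#' @return validated list of class `genotype_config`.
#' @seealso [genotype_preset()] for the shipped presets.
#' @export
genotype_config <- function(name = "custom",
                            p_lgn_apical = 0.5,
                            entry_mode = c("uniform", "mixture"),
                            entry_mixture = c(planar = 1 / 3, oblique = 1 / 3,
                                              perpendicular = 1 / 3),
                            planar_correction_enabled = TRUE,
                            perpendicular_correction_enabled = TRUE,
                            random_correction_on_contact_loss = FALSE,
                            p_contact_retained = 0.6,
                            p_contact_lost_during_telophase = 0,
                            tau_correction = 10,
                            angle_noise_sigma = 1.5,
                            target_planar = 10,
                            target_perpendicular = 80) {
  entry_mode <- match.arg(entry_mode)
  probs <- c(p_lgn_apical, p_contact_retained, p_contact_lost_during_telophase)
  if (any(!is.finite(probs)) || any(probs < 0 | probs > 1)) {
    stop("genotype_config: probabilities must be in [0, 1]", call. = FALSE)
  }
  if (length(entry_mixture) != 3L || any(entry_mixture < 0) ||
      abs(sum(entry_mixture) - 1) > 1e-8) {
    stop("genotype_config: entry_mixture must be 3 proportions summing to 1",
         call. = FALSE)
  }
  if (!is.finite(tau_correction) || tau_correction <= 0) {
    stop("genotype_config: tau_correction must be > 0", call. = FALSE)
  }
  if (angle_noise_sigma < 0) {
    stop("genotype_config: angle_noise_sigma must be >= 0", call. = FALSE)
  }
  if (!(target_planar >= 0 && target_planar < 30)) {
    stop("genotype_config: target_planar must lie in [0, 30)", call. = FALSE)
  }
  if (!(target_perpendicular >= 60 && target_perpendicular <= 90)) {
    stop("genotype_config: target_perpendicular must lie in [60, 90]",
         call. = FALSE)
  }
  structure(list(name = name, p_lgn_apical = p_lgn_apical,
                 entry_mode = entry_mode,
                 entry_mixture = stats::setNames(as.numeric(entry_mixture),
                                                 orientation_levels()),
                 planar_correction_enabled = planar_correction_enabled,
                 perpendicular_correction_enabled = perpendicular_correction_enabled,
                 random_correction_on_contact_loss = random_correction_on_contact_loss,
                 p_contact_retained = p_contact_retained,
                 p_contact_lost_during_telophase = p_contact_lost_during_telophase,
                 tau_correction = tau_correction,
                 angle_noise_sigma = angle_noise_sigma,
                 target_planar = target_planar,
                 target_perpendicular = target_perpendicular),
            class = "genotype_config")
}

#' @export
print.genotype_config <- function(x, ...) {
  cat(sprintf(
    "genotype_config '%s': entry %s, planar corr %s, perp corr %s, p(contact) %.2f, tau %.0f min\n",
    x$name, x$entry_mode,
    if (x$planar_correction_enabled) "on" else "off",
    if (x$perpendicular_correction_enabled) "on" else "off",
    x$p_contact_retained, x$tau_correction))
  invisible(x)
}

#' Shipped genotype presets for the two-step model
#'
#' Presets encode the study conditions for each genotype/stage:
#'
#' * `WT_E16.5` — uniform anaphase entry; both corrections enabled; 60% of
#'   oblique entries retain basal contact (and so correct to planar).
#' * `WT_E14.5` — 47% oblique entry, few perpendicular entries; 72% contact
#'   retention; contact-lost obliques correct randomly (no perpendicular
#'   correction at this stage).
#' * `Gpsm2_KD` — LGN knockdown: planar-skewed entry (75/23/2), apical LGN
#'   absent, perpendicular correction disabled; oblique entries invariably
#'   correct to planar (contact retention 1).
#' * `AJ_mutant` — alpha-E-catenin/vinculin-type adherens-junction loss:
#'   uniform entry, both corrections disabled.
#' * `Afdn_KD` — afadin knockdown: as `AJ_mutant`, plus 73% of
#'   contact-retaining oblique daughters lose contact during telophase.
#' * `Gpsm2_Afdn` — double mutant: perpendicular entries absent and both
#'   corrections disabled.
#'
#' @param name preset name (see above).
#' @return a [genotype_config()].
#' @export
genotype_preset <- function(name) {
  switch(name,
    "WT_E16.5" = genotype_config("WT_E16.5"),
    "WT_E14.5" = genotype_config("WT_E14.5",
      p_lgn_apical = 0.05, entry_mode = "mixture",
      entry_mixture = c(0.48, 0.47, 0.05),
      perpendicular_correction_enabled = FALSE,
      random_correction_on_contact_loss = TRUE,
      p_contact_retained = 0.72),
    "Gpsm2_KD" = genotype_config("Gpsm2_KD",
      p_lgn_apical = 0, entry_mode = "mixture",
      entry_mixture = c(0.75, 0.23, 0.02),
      perpendicular_correction_enabled = FALSE,
      p_contact_retained = 1),
    "AJ_mutant" = genotype_config("AJ_mutant",
      planar_correction_enabled = FALSE,
      perpendicular_correction_enabled = FALSE),
    "Afdn_KD" = genotype_config("Afdn_KD",
      planar_correction_enabled = FALSE,
      perpendicular_correction_enabled = FALSE,
      p_contact_lost_during_telophase = 0.73),
    "Gpsm2_Afdn" = genotype_config("Gpsm2_Afdn",
      p_lgn_apical = 0, entry_mode = "mixture",
      entry_mixture = c(0.765, 0.235, 0),
      planar_correction_enabled = FALSE,
      perpendicular_correction_enabled = FALSE,
      p_contact_retained = 1),
    stop("genotype_preset: unknown preset '", name, "'", call. = FALSE))
}

#' @rdname genotype_preset
#' @export
list_presets <- function() {
  c("WT_E16.5", "WT_E14.5", "Gpsm2_KD", "AJ_mutant", "Afdn_KD", "Gpsm2_Afdn")
}

#' Draw anaphase-onset angles (step 1 of the model)
#'
#' Uniform mode draws phi ~ Uniform\[0, 90\]; mixture mode first draws the
#' orientation bin from `entry_mixture`, then phi uniformly within the bin.
#' Apical LGN recruitment is drawn with `p_lgn_apical` and forced `TRUE` for
#' perpendicular entries. Uses the current RNG state; seed externally (or
#' via `seed`) for reproducibility.
#'
#' @param cfg a [genotype_config()].
#' @param n number of draws.
#' @param seed optional integer seed set before drawing.
#' @return data.frame with columns `phi`, `lgn_apical`.
#' @export
sample_anaphase_angles <- function(cfg, n, seed = NULL) {
  stopifnot(inherits(cfg, "genotype_config"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (cfg$entry_mode == "uniform") {
    phi <- stats::runif(n, 0, 90)
  } else {
    bin <- sample.int(3L, n, replace = TRUE, prob = cfg$entry_mixture)
    lo <- c(0, 30, 60)[bin]
    phi <- lo + stats::runif(n, 0, 30)
    # keep within [0,90]; perpendicular bin closed at 90
    phi <- pmin(phi, 90)
  }
  lgn <- stats::runif(n) < cfg$p_lgn_apical
  lgn[phi >= 60] <- TRUE
  data.frame(phi = phi, lgn_apical = lgn)
}

#' Simulate a cohort of divisions under the two-step model
#'
#' For each division: phi is drawn from the entry distribution; basal
#' contact at anaphase onset is assigned (always retained for planar
#' entries, lost for perpendicular entries, Bernoulli(`p_contact_retained`)
#' for oblique entries); a 5-minute-resolution trajectory over 0-60 min is
#' generated by exponential relaxation toward the applicable target,
#' `angle(t) = target + (phi - target) * exp(-t / tau)`, with independent
#' per-frame Gaussian noise folded back into `[0, 90]` (no noise at t = 0);
#' theta is the final trajectory angle. Oblique entries relax toward the
#' planar target when contact is retained and planar correction is enabled,
#' toward the perpendicular target when contact is lost and perpendicular
#' correction is enabled (or a random target under
#' `random_correction_on_contact_loss`); otherwise, and for all planar and
#' perpendicular entries, the target is phi itself (stable up to noise).
#'
#' Reproducible bit-for-bit given `(cfg, n, seed)`: a single seed drives all
#' draws in a fixed order (entry angles, LGN, contact at onset, telophase
#' contact loss, random targets, noise).
#'
#' @param cfg a [genotype_config()] or preset name.
#' @param n number of divisions.
#' @param seed integer seed.
#' @param age,reporter annotation fields copied into the records.
#' @return object of class `division_cohort`: list with `divisions` (one row
#'   per division: `division_id`, `genotype`, `age`, `reporter`, `phi`,
#'   `theta`, `lgn_apical`, `contact_onset`, `contact_end`), `trajectories`
#'   (long data.frame `division_id`, `t_min`, `angle_deg`), `config`, `seed`.
#' @export
simulate_cohort <- function(cfg, n, seed = 1, age = "E16.5",
                            reporter = "WT") {
  if (is.character(cfg)) cfg <- genotype_preset(cfg)
  stopifnot(inherits(cfg, "genotype_config"), n >= 1)
  set.seed(seed)
  entry <- sample_anaphase_angles(cfg, n)
  phi <- entry$phi
  bin <- classify_orientation(phi)

  contact_onset <- rep(TRUE, n)
  contact_onset[bin == "perpendicular"] <- FALSE
  obl <- bin == "oblique"
  contact_onset[obl] <- stats::runif(sum(obl)) < cfg$p_contact_retained

  lost_telo <- contact_onset &
    stats::runif(n) < cfg$p_contact_lost_during_telophase
  contact_end <- contact_onset & !lost_telo

  random_target <- stats::runif(n, 0, 90)  # used only when configured

  target <- phi
  plan_corr <- obl & contact_onset & cfg$planar_correction_enabled
  target[plan_corr] <- cfg$target_planar
  perp_corr <- obl & !contact_onset & cfg$perpendicular_correction_enabled
  target[perp_corr] <- cfg$target_perpendicular
  rand_corr <- obl & !contact_onset & !cfg$perpendicular_correction_enabled &
    cfg$random_correction_on_contact_loss
  target[rand_corr] <- random_target[rand_corr]

  t_grid <- seq(0, 60, by = 5)
  det <- outer(phi - target, exp(-t_grid / cfg$tau_correction)) + target
  noise <- matrix(stats::rnorm(n * (length(t_grid) - 1L),
                               sd = cfg$angle_noise_sigma),
                  nrow = n)
  traj <- det
  traj[, -1L] <- fold_angle(det[, -1L] + noise)
  theta <- traj[, length(t_grid)]

  ids <- sprintf("div%05d", seq_len(n))
  divisions <- data.frame(division_id = ids, genotype = cfg$name,
                          age = age, reporter = reporter,
                          phi = phi, theta = theta,
                          lgn_apical = entry$lgn_apical,
                          contact_onset = contact_onset,
                          contact_end = contact_end,
                          stringsAsFactors = FALSE)
  trajectories <- data.frame(
    division_id = rep(ids, each = length(t_grid)),
    t_min = rep(t_grid, times = n),
    angle_deg = as.numeric(t(traj)),
    stringsAsFactors = FALSE)
  structure(list(divisions = divisions, trajectories = trajectories,
                 config = cfg, seed = seed),
            class = "division_cohort")
}

#' @export
print.division_cohort <- function(x, ...) {
  cat(sprintf("division_cohort '%s': n = %d divisions (seed %d)\n",
              x$config$name, nrow(x$divisions), x$seed))
  invisible(x)
}

#' Extract the anaphase-onset (phi) or +1 h (theta) angle pool of a cohort
#'
#' @param cohort a `division_cohort`.
#' @return an [angle_sample()].
#' @export
phi_sample <- function(cohort) {
  angle_sample(cohort$divisions$phi, paste0(cohort$config$name, "_phi"))
}

#' @rdname phi_sample
#' @export
theta_sample <- function(cohort) {
  angle_sample(cohort$divisions$theta, paste0(cohort$config$name, "_theta"))
}

#' Simulate a fixed-tissue snapshot of mitotic stages and angles
#'
#' Emulates scoring mitoses in fixed sections: each cell is assigned a stage
#' with probability proportional to the configured stage duration (anaphase
#' is short, so anaphase cells are rare relative to telophase). Metaphase
#' and anaphase angles are drawn from the entry distribution; telophase
#' angles are theta values from a simulated cohort.
#'
#' @param cfg a [genotype_config()] or preset name.
#' @param stage_durations named numeric vector of stage durations in minutes
#'   (`metaphase`, `anaphase`, `telophase`); default 10/10/50 reproduces the
#'   roughly 1:1:5 observed stage frequencies.
#' @param n number of cells.
#' @param seed integer seed.
#' @return data.frame with columns `stage` (factor) and `angle_deg`.
#' @export
simulate_snapshot <- function(cfg,
                              stage_durations = c(metaphase = 10,
                                                  anaphase = 10,
                                                  telophase = 50),
                              n = 1000, seed = 1) {
  if (is.character(cfg)) cfg <- genotype_preset(cfg)
  if (length(stage_durations) != 3L || any(stage_durations <= 0)) {
    stop("simulate_snapshot: stage durations must be 3 positive values",
         call. = FALSE)
  }
  stages <- c("metaphase", "anaphase", "telophase")
  set.seed(seed)
  stage <- sample(stages, n, replace = TRUE,
                  prob = stage_durations / sum(stage_durations))
  n_telo <- sum(stage == "telophase")
  angle <- numeric(n)
  early <- stage != "telophase"
  if (any(early)) {
    angle[early] <- sample_anaphase_angles(cfg, sum(early))$phi
  }
  if (n_telo > 0) {
    coh <- simulate_cohort(cfg, n_telo, seed = seed + 1L)
    angle[stage == "telophase"] <- coh$divisions$theta
  }
  data.frame(stage = factor(stage, levels = stages), angle_deg = angle)
}

#' Write / read a simulated cohort as plain CSV files
#'
#' Writes `divisions.csv` (per-division records) and `trajectories.csv`
#' (long format `division_id`, `t_min`, `angle_deg`) into `dir`.
#'
#' @param cohort a `division_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort_csv <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort$divisions, file.path(dir, "divisions.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$trajectories, file.path(dir, "trajectories.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' @rdname write_cohort_csv
#' @param divisions_csv,trajectories_csv file paths; `trajectories_csv` may
#'   be `NULL` if only per-division records are available.
#' @export
read_cohort_csv <- function(divisions_csv, trajectories_csv = NULL) {
  div <- utils::read.csv(divisions_csv, stringsAsFactors = FALSE)
  need <- c("division_id", "phi", "theta")
  missing <- setdiff(need, names(div))
  if (length(missing)) {
    stop("read_cohort_csv: divisions table missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  traj <- if (!is.null(trajectories_csv)) {
    utils::read.csv(trajectories_csv, stringsAsFactors = FALSE)
  }
  structure(list(divisions = div, trajectories = traj,
                 config = NULL, seed = NA_integer_),
            class = "division_cohort")
}
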