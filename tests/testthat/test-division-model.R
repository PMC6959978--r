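test_that("genotype_config validates probabilities, mixture and targets", {
  expect_error(genotype_config(p_lgn_apical = 1.2), "probabilities")
  expect_error(genotype_config(entry_mode = "mixture",
                               entry_mixture = c(0.5, 0.6, 0.1)), "sum")
  expect_error(genotype_config(tau_correction = 0), "tau")
  expect_error(genotype_config(target_planar = 40), "target_planar")
  expect_error(genotype_config(target_perpendicular = 40),
               "target_perpendicular")
  expect_error(genotype_preset("WTX"), "unknown preset")
  for (p in list_presets()) {
    expect_s3_class(genotype_preset(p), "genotype_config")
  }
})

test_that("anaphase entry sampling matches the configured distribution", {
  set.seed(41)
  wt <- sample_anaphase_angles(genotype_preset("WT_E16.5"), 1e5)
  expect_true(all(wt$phi >= 0 & wt$phi <= 90))
  expect_equal(mean(classify_orientation(wt$phi) == "oblique"), 1 / 3,
               tolerance = 0.03)
  g <- sample_anaphase_angles(genotype_preset("Gpsm2_KD"), 1e5)
  fr <- as.numeric(table(classify_orientation(g$phi)) / 1e5)
  expect_equal(fr, c(0.75, 0.23, 0.02), tolerance = 0.05)
  allp <- sample_anaphase_angles(
    genotype_config(entry_mode = "mixture", entry_mixture = c(1, 0, 0)), 1000)
  expect_true(all(allp$phi < 30))
  # LGN forced apical for perpendicular entries
  noLGN <- sample_anaphase_angles(
    genotype_config(p_lgn_apical = 0), 1000)
  expect_true(all(noLGN$lgn_apical[noLGN$phi >= 60]))
  expect_false(any(noLGN$lgn_apical[noLGN$phi < 60]))
})

test_that("simulated trajectories start at phi, end at theta, stay in range", {
  co <- simulate_cohort("WT_E16.5", 200, seed = 42)
  traj <- co$trajectories
  expect_true(all(traj$angle_deg >= 0 & traj$angle_deg <= 90))
  first <- traj[traj$t_min == 0, ]
  last <- traj[traj$t_min == 60, ]
  expect_equal(first$angle_deg[match(co$divisions$division_id,
                                     first$division_id)],
               co$divisions$phi)
  expect_equal(last$angle_deg[match(co$divisions$division_id,
                                    last$division_id)],
               co$divisions$theta)
  expect_equal(sort(unique(traj$t_min)), seq(0, 60, by = 5))
})

test_that("closed-form limits: zero noise/fast relaxation hit the target", {
  # corrections disabled, no noise: theta equals phi exactly
  frozen <- genotype_config("frozen", planar_correction_enabled = FALSE,
                            perpendicular_correction_enabled = FALSE,
                            angle_noise_sigma = 0)
  co <- simulate_cohort(frozen, 300, seed = 43)
  expect_equal(co$divisions$theta, co$divisions$phi)
  # tau -> 0, no noise: oblique corrected entries land on the target exactly
  fast <- genotype_config("fast", tau_correction = 1e-9,
                          angle_noise_sigma = 0, p_contact_retained = 1)
  co2 <- simulate_cohort(fast, 300, seed = 44)
  obl <- classify_orientation(co2$divisions$phi) == "oblique"
  expect_true(any(obl))
  expect_equal(co2$divisions$theta[obl],
               rep(fast$target_planar, sum(obl)))
  # relaxation closed form: phi=45, contact retained, default WT parameters
  wt <- genotype_preset("WT_E16.5")
  expected_end <- wt$target_planar +
    (45 - wt$target_planar) * exp(-60 / wt$tau_correction)
  expect_lt(expected_end, 30)  # 10.09: corrected well into the planar bin
})

test_that("cohorts are reproducible bit-for-bit given the seed", {
  a <- simulate_cohort("WT_E16.5", 500, seed = 45)
  b <- simulate_cohort("WT_E16.5", 500, seed = 45)
  expect_identical(a$divisions, b$divisions)
  expect_identical(a$trajectories, b$trajectories)
  c2 <- simulate_cohort("WT_E16.5", 500, seed = 46)
  expect_false(identical(a$divisions$phi, c2$divisions$phi))
})

test_that("parameter recovery: contact retention from outcome frequencies", {
  co <- simulate_cohort("WT_E16.5", 10000, seed = 47)
  oc <- correction_outcome(co$divisions$phi, co$divisions$theta)
  obl <- oc$entry_class == "oblique"
  p_hat <- mean(oc$outcome[obl] == "corrected_planar")
  expect_equal(p_hat, co$config$p_contact_retained, tolerance = 0.03)
})

test_that("WT E16.5 reproduces random-entry to bimodal-exit signature", {
  co <- simulate_cohort("WT_E16.5", 10000, seed = 48)
  expect_gt(ks_uniform(phi_sample(co))$p_value, 0.05)
  expect_lt(ks_uniform(theta_sample(co))$p_value, 1e-6)
  oc_frac <- mean(classify_orientation(co$divisions$theta) == "oblique")
  expect_lt(oc_frac, 0.10)  # oblique theta nearly eliminated at 1 h
  expect_gt(mean(classify_orientation(co$divisions$phi) == "oblique"), 0.25)
})

test_that("mutant presets reproduce their distribution signatures", {
  aj <- simulate_cohort("AJ_mutant", 10000, seed = 49)
  expect_gt(ks_uniform(theta_sample(aj))$p_value, 0.05)
  e14 <- simulate_cohort("WT_E14.5", 10000, seed = 50)
  expect_gt(mean(classify_orientation(e14$divisions$theta) == "planar"), 0.7)
  dbl <- simulate_cohort("Gpsm2_Afdn", 10000, seed = 51)
  expect_lt(mean(classify_orientation(dbl$divisions$theta) ==
                   "perpendicular"), 0.05)
})

test_that("snapshot stages follow durations and stage-specific pools", {
  snap <- simulate_snapshot("WT_E16.5", c(metaphase = 10, anaphase = 10,
                                          telophase = 50),
                            n = 10000, seed = 52)
  frac <- table(snap$stage) / nrow(snap)
  expect_equal(as.numeric(frac["anaphase"]), 10 / 70, tolerance = 0.02)
  expect_equal(sum(snap$stage == "telophase") / sum(snap$stage == "anaphase"),
               5, tolerance = 0.5)
  ana <- classify_distribution(
    angle_sample(snap$angle_deg[snap$stage == "anaphase"]))
  telo <- classify_distribution(
    angle_sample(snap$angle_deg[snap$stage == "telophase"]))
  expect_equal(ana$call, "random")
  expect_equal(telo$call, "bimodal")
  expect_error(simulate_snapshot("WT_E16.5", c(0, 10, 50), 10, 1),
               "positive")
})

test_that("cohort CSVs round-trip through the package readers", {
  dir <- tempfile()
  on.exit(unlink(dir, recursive = TRUE))
  co <- simulate_cohort("WT_E16.5", 50, seed = 53)
  write_cohort_csv(co, dir)
  back <- read_cohort_csv(file.path(dir, "divisions.csv"),
                          file.path(dir, "trajectories.csv"))
  expect_equal(back$divisions$phi, co$divisions$phi)
  expect_equal(back$divisions$contact_onset, co$divisions$contact_onset)
  expect_equal(back$trajectories$angle_deg, co$trajectories$angle_deg)
})
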