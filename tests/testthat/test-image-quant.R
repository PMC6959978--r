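test_that("orthogonal linescans run perpendicular and re-anchor on the peak", {
  img <- make_junction_image("linear", noise_sigma = 0, seed = 1)
  scans <- orthogonal_linescans(img, "ecad")
  expect_length(scans, 3)
  for (s in scans) {
    # horizontal ridge -> vertical scans
    expect_lt(diff(range(s$positions$x)), 1e-9)
    expect_equal(s$center_index, (21 + 1) / 2)
    expect_equal(max(s$intensities),
                 img$params$offset + img$params$amplitude, tolerance = 1)
  }
  expect_error(orthogonal_linescans(img, "nope"), "unknown channel")
})

test_that("scans re-center when the anchor peak is offset from the path", {
  img <- make_junction_image("linear", noise_sigma = 0, seed = 1)
  img$path$y <- img$path$y + 2  # annotated path 2 px off the true ridge
  s <- orthogonal_linescans(img, "ecad")[[2]]
  expect_equal(s$positions$y[s$center_index],
               make_junction_image("linear", noise_sigma = 0,
                                   seed = 1)$path$y[1],
               tolerance = 0.6)
})

test_that("scans at zipper gaps shift to the nearest punctum", {
  img <- make_junction_image("zipper", duty_cycle = 0.3, period = 40,
                             noise_sigma = 0, seed = 1)
  scans <- orthogonal_linescans(img, "ecad")
  for (s in scans) {
    peak <- s$intensities[s$center_index]
    expect_gt(peak, img$params$offset + 0.9 * img$params$amplitude)
  }
})

test_that("center intensity is the geometric mean of the 3 central samples", {
  scan <- structure(list(positions = NULL,
                         intensities = c(1, 80, 100, 125, 1),
                         center_index = 3, path_fraction = 0.5),
                    class = "linescan")
  expect_equal(as.numeric(center_intensity(scan)), 100)
  const <- structure(list(positions = NULL, intensities = rep(7, 21),
                          center_index = 11, path_fraction = 0.5),
                     class = "linescan")
  expect_equal(as.numeric(center_intensity(const)), 7)
  degen <- structure(list(positions = NULL, intensities = c(0, 100, 100),
                          center_index = 2, path_fraction = 0.5),
                     class = "linescan")
  expect_equal(as.numeric(center_intensity(degen)), 0)
  expect_true(attr(center_intensity(degen), "degenerate"))
})

test_that("channel ratio subtracts backgrounds and is gain/offset invariant", {
  expect_equal(channel_ratio(100, 20, 180, 20)$ratio, 0.5)
  expect_equal(channel_ratio(50, 10, 50, 10)$ratio, 1.0)
  r0 <- channel_ratio(100, 20, 180, 20)$ratio
  g <- 3.7; c0 <- 11
  expect_equal(channel_ratio(g * 100 + c0, g * 20 + c0,
                             g * 180 + c0, g * 20 + c0)$ratio, r0)
  expect_error(channel_ratio(100, 20, 30, 40), "denominator")
})

test_that("junction continuity: perfect ridge scores 100, zipper the duty", {
  lin0 <- make_junction_image("linear", noise_sigma = 0, seed = 1)
  expect_equal(as.numeric(junction_continuity(lin0)), 100)
  lin <- make_junction_image("linear", amplitude = 200, noise_sigma = 5,
                             seed = 1)
  expect_gte(as.numeric(junction_continuity(lin)), 90)
  zip <- make_junction_image("zipper", duty_cycle = 0.5, seed = 1)
  expect_equal(as.numeric(junction_continuity(zip)), 50, tolerance = 10 / 50)
  short <- lin
  short$path <- short$path[1:5, ]
  expect_error(junction_continuity(short), "path too short")
})

test_that("continuity is invariant to a global intensity gain", {
  img <- make_junction_image("zipper", duty_cycle = 0.4, seed = 2)
  base <- as.numeric(junction_continuity(img))
  img$channels <- lapply(img$channels, function(m) m * 4.2)
  expect_equal(as.numeric(junction_continuity(img)), base)
})

test_that("continuity recovers zipper duty cycle within 10 points, seeds 1-20", {
  for (duty in c(0.3, 0.5, 0.7)) {
    est <- vapply(1:20, function(s) {
      as.numeric(junction_continuity(
        make_junction_image("zipper", duty_cycle = duty, seed = s)))
    }, numeric(1))
    expect_true(all(abs(est - 100 * duty) <= 10),
                info = sprintf("duty %.1f: range %.1f-%.1f", duty,
                               min(est), max(est)))
  }
})

test_that("radial fraction localizes intensity along the cortical path", {
  prof <- rep(0, 100); prof[40:60] <- 50
  expect_equal(radial_intensity_fraction(prof), 1.0)
  expect_equal(radial_intensity_fraction(rep(3, 100)), 0.5)
  basal <- rep(0, 100); basal[1:25] <- 50
  expect_equal(radial_intensity_fraction(basal), 0.0)
  expect_true(is.na(radial_intensity_fraction(rep(0, 8))))
  expect_error(radial_intensity_fraction(c(1, 2)), ">= 4")
  cres <- make_radial_profile("apical_crescent", background = 10,
                              noise_sigma = 2, seed = 3)
  expect_gte(radial_intensity_fraction(cres, bg = 10), 0.9)
})

test_that("LGN recruitment classes recover generator labels", {
  expect_equal(lgn_recruitment_class(
    make_radial_profile("apical_crescent", noise_sigma = 0)), "apical")
  expect_equal(lgn_recruitment_class(
    make_radial_profile("absent", noise_sigma = 0)), "absent")
  basal_bump <- make_radial_profile("apical_crescent", center_frac = 0.12,
                                    noise_sigma = 0)
  expect_equal(lgn_recruitment_class(basal_bump), "other")
})

test_that("recruitment calls are >= 95% accurate on a noisy 300-profile panel", {
  patterns <- rep(c("apical_crescent", "absent", "uniform"), each = 100)
  calls <- vapply(seq_along(patterns), function(i) {
    lgn_recruitment_class(make_radial_profile(patterns[i], noise_sigma = 3,
                                              seed = i))
  }, character(1))
  truth <- c(apical_crescent = "apical", absent = "absent",
             uniform = "absent")[patterns]
  expect_gte(mean(calls == truth), 0.95)
})

test_that("endfoot anisotropy is the paired background-subtracted ratio", {
  expect_equal(endfoot_anisotropy(150, 100, 50), 2.0)
  expect_equal(endfoot_anisotropy(100, 100, 0), 1.0)
  expect_error(endfoot_anisotropy(100, 50, 50), "apical")
  # power check: 20 pairs at 1.5x enrichment detected by paired Wilcoxon
  set.seed(61)
  apical <- rnorm(20, 100, 10)
  endfoot <- 1.5 * apical + rnorm(20, 0, 10)
  ratio <- endfoot_anisotropy(endfoot, apical, 0)
  p <- compare_groups(endfoot, apical, "wilcoxon_paired",
                      alternative = "greater")$p_value
  expect_lt(p, 0.05)
  expect_gt(mean(ratio), 1)
})

test_that("tissue metrics follow their defining ratios", {
  sec <- make_section_image(seed = 5)
  m <- tissue_metrics(sec)
  expect_equal(m$k10_thickness_um,
               sum(sec$k10_mask) * sec$pixel_size^2 / sec$bm_length_um)
  expect_equal(m$basal_density,
               sum(sec$nuclei$compartment == "basal") / sec$bm_length_um)
  expect_equal(local_density(5, 250), 0.02)
  expect_error(local_density(5, 0), "> 0")
})
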