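#' Generate a synthetic annotated cell-cell junction image
#'
#' Builds ground-truth-annotated two-channel junction micrographs for
#' testing the intensity metrics. The junction is a horizontal path across
#' the image with a Gaussian cross-section ridge. `morphology = "linear"`
#' gives a continuous ridge (mature junction); `"zipper"` modulates the
#' ridge with a square wave of given period and duty cycle (immature spot
#' junctions separated by gaps). A constant camera offset and Gaussian read
#' noise are added and intensities clamped at 0. Dark elliptical "nucleus"
#' background regions are placed away from the junction for background
#' estimation.
#'
#' Pixel coordinates are 1-based (R matrix convention): `x` is the column,
#' `y` the row, `y` increasing apically.
#'
#' @param morphology `"linear"` or `"zipper"`.
#' @param width,height image size in pixels.
#' @param amplitude peak ridge intensity above offset (arbitrary units).
#' @param ridge_sigma Gaussian cross-section width of the ridge, pixels.
#' @param period zipper punctum period along the path, pixels.
#' @param duty_cycle zipper fraction of the period occupied by puncta,
#'   in (0, 1); this is the ground truth recovered by junction continuity.
#' @param offset constant background offset.
#' @param noise_sigma Gaussian noise standard deviation.
#' @param channels channel names; the first is the junction/anchor channel
#'   (e.g. E-cadherin), additional channels get the same ridge scaled by
#'   `channel_gains`.
#' @param channel_gains numeric gains, one per channel.
#' @param seed integer seed; generation is deterministic given the seed.
#' @return object of class `junction_image`: list with `channels` (named
#'   list of height x width matrices), `path` (data.frame `x`, `y` at 1-px
#'   steps), `morphology`, `params` (ground truth incl. `duty_cycle`),
#'   `background_regions` (list of logical masks), `seed`.
#' @export
make_junction_image <- function(morphology = c("linear", "zipper"),
                                width = 240, height = 120,
                                amplitude = 200, ridge_sigma = 2,
                                period = 20, duty_cycle = 0.5,
                                offset = 20, noise_sigma = 5,
                                channels = c("ecad", "actin"),
                                channel_gains = rep(1, length(channels)),
                                seed = 1) {
  morphology <- match.arg(morphology)
  if (amplitude <= 0 || ridge_sigma <= 0 || period < 2 ||
      duty_cycle <= 0 || duty_cycle >= 1 || noise_sigma < 0) {
    stop("make_junction_image: invalid parameters", call. = FALSE)
  }
  set.seed(seed)
  y0 <- height / 2
  xs <- seq_len(width)
  path <- data.frame(x = xs, y = rep(y0, width))

  # along-path modulation: 1 on puncta, 0 in gaps
  mod <- if (morphology == "linear") {
    rep(1, width)
  } else {
    as.numeric((xs %% period) < duty_cycle * period)
  }
  rows <- seq_len(height)
  cross <- exp(-((rows - y0)^2) / (2 * ridge_sigma^2))  # height vector
  ridge <- outer(cross, mod)  # height x width

  # nucleus background regions: two ellipses clear of the junction
  grid_x <- matrix(xs, nrow = height, ncol = width, byrow = TRUE)
  grid_y <- matrix(rows, nrow = height, ncol = width)
  ellipse <- function(cx, cy, rx, ry) {
    ((grid_x - cx) / rx)^2 + ((grid_y - cy) / ry)^2 <= 1
  }
  background_regions <- list(
    nucleus1 = ellipse(width * 0.25, height * 0.2, width * 0.08, height * 0.1),
    nucleus2 = ellipse(width * 0.75, height * 0.8, width * 0.08, height * 0.1))

  chans <- lapply(seq_along(channels), function(i) {
    img <- offset + channel_gains[i] * amplitude * ridge +
      matrix(stats::rnorm(height * width, sd = noise_sigma), height, width)
    pmax(img, 0)
  })
  names(chans) <- channels

  structure(list(channels = chans, path = path, morphology = morphology,
                 params = list(amplitude = amplitude,
                               ridge_sigma = ridge_sigma, period = period,
                               duty_cycle = if (morphology == "zipper")
                                 duty_cycle else 1,
                               offset = offset, noise_sigma = noise_sigma,
                               channel_gains = channel_gains),
                 background_regions = background_regions, seed = seed),
            class = "junction_image")
}

#' Generate a synthetic radial cortical intensity profile
#'
#' Emulates a linescan that starts at the basement-membrane contact point
#' and traces the cell cortex; by convention the central 50% of the path is
#' the apical surface. Patterns: `"apical_crescent"` — Gaussian bump
#' centered at 50% of the path (an apical LGN crescent); `"uniform"` —
#' constant cortical signal; `"absent"` — background only. A basal bump
#' (for "other" classification tests) can be produced via `center_frac`.
#'
#' @param pattern `"apical_crescent"`, `"uniform"` or `"absent"`.
#' @param length number of samples along the cortex (>= 4).
#' @param peak bump (or uniform plateau) intensity above background.
#' @param bump_sd_frac crescent width as a fraction of the path length.
#' @param center_frac bump center as a fraction of the path (default 0.5 =
#'   apical pole).
#' @param background constant background level.
#' @param noise_sigma Gaussian noise standard deviation.
#' @param seed integer seed.
#' @return numeric intensity vector of the requested length, with the
#'   generating pattern in attribute `"pattern"`.
#' @export
make_radial_profile <- function(pattern = c("apical_crescent", "uniform",
                                            "absent"),
                                length = 100, peak = 100,
                                bump_sd_frac = 0.06, center_frac = 0.5,
                                background = 10, noise_sigma = 0, seed = 1) {
  pattern <- match.arg(pattern)
  if (length < 4) stop("make_radial_profile: length must be >= 4",
                       call. = FALSE)
  set.seed(seed)
  pos <- (seq_len(length) - 0.5) / length
  base <- switch(pattern,
    apical_crescent = background +
      peak * exp(-((pos - center_frac)^2) / (2 * bump_sd_frac^2)),
    uniform = rep(background + peak, length),
    absent = rep(background, length))
  out <- pmax(base + stats::rnorm(length, sd = noise_sigma), 0)
  attr(out, "pattern") <- pattern
  out
}

#' Generate a synthetic annotated epidermis section
#'
#' Fixture generator for the tissue metrics: a wavy basement-membrane (BM)
#' polyline spanning the image width, a differentiated (K10+) band of
#' configured mean thickness sitting a fixed basal-layer height above the
#' BM, and nuclei placed as Poisson processes along the BM (basal,
#' optionally mitotic) and in the suprabasal compartment.
#'
#' @param width_um lateral extent in micrometres.
#' @param pixel_size micrometres per pixel.
#' @param bm_amplitude_um,bm_wavelength_um BM waviness (sine) parameters.
#' @param basal_height_um height of the basal layer above the BM.
#' @param k10_thickness_um mean thickness of the K10+ band (0 for none).
#' @param basal_density,sb_density nuclei per micrometre of BM.
#' @param mitotic_fraction fraction of basal nuclei flagged mitotic (pHH3+).
#' @param seed integer seed.
#' @return object of class `section_image`: list with `k10_mask` (logical
#'   matrix, rows = y increasing apically), `bm_polyline` (data.frame `x`,
#'   `y` in pixels, 1-px steps), `bm_length_um` (arc length), `nuclei`
#'   (data.frame `x`, `y` in pixels, `compartment`, `mitotic`),
#'   `pixel_size`, `params`, `seed`.
#' @export
make_section_image <- function(width_um = 200, pixel_size = 0.5,
                               bm_amplitude_um = 5, bm_wavelength_um = 50,
                               basal_height_um = 8, k10_thickness_um = 10,
                               basal_density = 0.15, sb_density = 0.1,
                               mitotic_fraction = 0.02, seed = 1) {
  if (width_um <= 0 || pixel_size <= 0 || k10_thickness_um < 0 ||
      basal_density < 0 || sb_density < 0 ||
      mitotic_fraction < 0 || mitotic_fraction > 1) {
    stop("make_section_image: invalid parameters", call. = FALSE)
  }
  set.seed(seed)
  width_px <- round(width_um / pixel_size)
  height_px <- round((bm_amplitude_um * 2 + basal_height_um +
                        k10_thickness_um + 20) / pixel_size)
  xs <- seq_len(width_px)
  bm_base_px <- (bm_amplitude_um + 2) / pixel_size
  bm_y <- bm_base_px + (bm_amplitude_um / pixel_size) *
    sin(2 * pi * xs * pixel_size / bm_wavelength_um)
  # arc length in um
  dx <- diff(xs) * pixel_size
  dy <- diff(bm_y) * pixel_size
  bm_length_um <- sum(sqrt(dx^2 + dy^2))

  # K10 band following the BM; the band has constant thickness measured
  # normal to the BM, so its vertical extent per column is scaled by the
  # local slope factor sqrt(1 + y'^2) (band area = thickness x arc length)
  k10_mask <- matrix(FALSE, nrow = height_px, ncol = width_px)
  if (k10_thickness_um > 0) {
    slope <- c(diff(bm_y), 0)  # dy/dx in px/px == um/um
    vert_px <- (k10_thickness_um / pixel_size) * sqrt(1 + slope^2)
    lo <- bm_y + basal_height_um / pixel_size
    hi <- lo + vert_px
    for (j in xs) {
      rows <- which(seq_len(height_px) >= lo[j] &
                      seq_len(height_px) < hi[j])
      k10_mask[rows, j] <- TRUE
    }
  }

  n_basal <- stats::rpois(1, basal_density * bm_length_um)
  n_sb <- stats::rpois(1, sb_density * bm_length_um)
  basal_x <- stats::runif(n_basal, 1, width_px)
  basal_y <- stats::approx(xs, bm_y, xout = basal_x)$y +
    stats::runif(n_basal, 1, basal_height_um / pixel_size - 1)
  sb_x <- stats::runif(n_sb, 1, width_px)
  sb_y <- stats::approx(xs, bm_y, xout = sb_x)$y +
    basal_height_um / pixel_size +
    stats::runif(n_sb, 0, k10_thickness_um / pixel_size)
  nuclei <- data.frame(
    x = c(basal_x, sb_x), y = c(basal_y, sb_y),
    compartment = rep(c("basal", "suprabasal"), c(n_basal, n_sb)),
    mitotic = c(stats::runif(n_basal) < mitotic_fraction,
                rep(FALSE, n_sb)),
    stringsAsFactors = FALSE)

  structure(list(k10_mask = k10_mask,
                 bm_polyline = data.frame(x = xs, y = bm_y),
                 bm_length_um = bm_length_um,
                 nuclei = nuclei, pixel_size = pixel_size,
                 params = list(k10_thickness_um = k10_thickness_um,
                               basal_height_um = basal_height_um,
                               basal_density = basal_density,
                               sb_density = sb_density,
                               mitotic_fraction = mitotic_fraction),
                 seed = seed),
            class = "section_image")
}

#' Write / read junction image channels as 16-bit grayscale TIFFs
#'
#' One single-plane TIFF per channel (`<channel>.tif`) plus a ground-truth
#' JSON (`ground_truth.json`) holding the path, morphology, parameters and
#' seed. Intensities are scaled by `scale` into the 16-bit range.
#'
#' @param img a `junction_image`.
#' @param dir output directory.
#' @param scale divisor mapping intensities into `[0, 1]` for 16-bit
#'   storage (default 65535, i.e. raw counts are stored as-is).
#' @return `dir`, invisibly.
#' @export
write_junction_tiff <- function(img, dir, scale = 65535) {
  stopifnot(inherits(img, "junction_image"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (ch in names(img$channels)) {
    m <- pmin(pmax(img$channels[[ch]] / scale, 0), 1)
    tiff::writeTIFF(m, file.path(dir, paste0(ch, ".tif")),
                    bits.per.sample = 16L)
  }
  gt <- list(path = img$path, morphology = img$morphology,
             params = img$params, seed = img$seed, scale = scale)
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_junction_tiff
#' @export
read_junction_tiff <- function(dir) {
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                            simplifyVector = TRUE)
  files <- list.files(dir, pattern = "\\.tif$", full.names = TRUE)
  scale <- if (!is.null(gt$scale)) gt$scale else 65535
  chans <- lapply(files, function(f) tiff::readTIFF(f) * scale)
  names(chans) <- sub("\\.tif$", "", basename(files))
  structure(list(channels = chans,
                 path = as.data.frame(gt$path),
                 morphology = gt$morphology, params = gt$params,
                 background_regions = list(), seed = gt$seed),
            class = "junction_image")
}
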