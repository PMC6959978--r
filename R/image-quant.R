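# Bilinear interpolation of a matrix image at (x = column, y = row),
# 1-based pixel-center coordinates. Out-of-bounds clamps to the edge.
bilinear_sample <- function(img, x, y) {
  nr <- nrow(img); nc <- ncol(img)
  x <- pmin(pmax(x, 1), nc); y <- pmin(pmax(y, 1), nr)
  x0 <- pmin(floor(x), nc - 1L); y0 <- pmin(floor(y), nr - 1L)
  fx <- x - x0; fy <- y - y0
  img[cbind(y0, x0)] * (1 - fx) * (1 - fy) +
    img[cbind(y0, x0 + 1L)] * fx * (1 - fy) +
    img[cbind(y0 + 1L, x0)] * (1 - fx) * fy +
    img[cbind(y0 + 1L, x0 + 1L)] * fx * fy
}

# Resample a polyline (data.frame x, y) to ~1-px arc-length steps.
resample_path <- function(path, step = 1) {
  d <- c(0, cumsum(sqrt(diff(path$x)^2 + diff(path$y)^2)))
  s <- seq(0, max(d), by = step)
  data.frame(x = stats::approx(d, path$x, xout = s)$y,
             y = stats::approx(d, path$y, xout = s)$y)
}

#' Orthogonal linescans across a junction path
#'
#' Samples `scan_length` points perpendicular to the local path tangent at
#' the requested fractional positions along the junction (defaults: the
#' 25th, 50th and 75th percentile of the path length). The scan center is
#' re-anchored to the maximum of the anchor channel within the scan; on
#' punctate (zipper) junctions, a scan landing in a gap (anchor intensity
#' below half the along-path maximum) is first shifted along the path to
#' the nearest punctum so that regions lacking junction formation are not
#' measured.
#'
#' @param img a `junction_image` (see [make_junction_image()]).
#' @param channel channel to report intensities from.
#' @param anchor_channel channel used to center the scan (default: first
#'   channel, e.g. E-cadherin).
#' @param positions fractional positions along the path.
#' @param scan_length scan length in pixels (odd; default 21).
#' @return list of `linescan` objects, each a list with `positions`
#'   (data.frame of sampled pixel coordinates), `intensities`,
#'   `center_index` (re-anchored), `path_fraction`.
#' @export
orthogonal_linescans <- function(img, channel,
                                 anchor_channel = names(img$channels)[1],
                                 positions = c(0.25, 0.50, 0.75),
                                 scan_length = 21) {
  stopifnot(inherits(img, "junction_image"))
  if (!channel %in% names(img$channels)) {
    stop("orthogonal_linescans: unknown channel '", channel, "'",
         call. = FALSE)
  }
  p <- resample_path(img$path)
  if (nrow(p) < 3L) stop("orthogonal_linescans: path too short",
                         call. = FALSE)
  anchor_img <- img$channels[[anchor_channel]]
  chan_img <- img$channels[[channel]]
  along <- bilinear_sample(anchor_img, p$x, p$y)
  gap_thresh <- 0.5 * max(along)

  half <- (scan_length - 1) / 2
  lapply(positions, function(fr) {
    i <- max(2L, min(nrow(p) - 1L, round(fr * (nrow(p) - 1L)) + 1L))
    # shift out of zipper gaps to the nearest punctum along the path
    if (along[i] < gap_thresh) {
      ok <- which(along >= gap_thresh)
      if (length(ok)) i <- ok[which.min(abs(ok - i))]
    }
    tx <- p$x[min(i + 1L, nrow(p))] - p$x[max(i - 1L, 1L)]
    ty <- p$y[min(i + 1L, nrow(p))] - p$y[max(i - 1L, 1L)]
    nrm <- sqrt(tx^2 + ty^2)
    nx <- -ty / nrm; ny <- tx / nrm  # unit normal
    off <- seq(-half, half)
    sx <- p$x[i] + off * nx; sy <- p$y[i] + off * ny
    anchor_vals <- bilinear_sample(anchor_img, sx, sy)
    center <- which.max(anchor_vals)  # signal center = max of anchor
    structure(list(positions = data.frame(x = sx, y = sy),
                   intensities = bilinear_sample(chan_img, sx, sy),
                   center_index = center, path_fraction = fr),
              class = "linescan")
  })
}

#' Center intensity of a linescan
#'
#' Geometric mean of the 3 intensity samples nearest the (re-anchored)
#' scan center. If any of the three values is 0 the geometric mean is
#' degenerate: 0 is returned with attribute `degenerate = TRUE`.
#'
#' @param scan a `linescan` from [orthogonal_linescans()].
#' @return intensity value (attribute `degenerate` flags a zero sample).
#' @export
center_intensity <- function(scan) {
  v <- scan$intensities
  if (length(v) < 3L) stop("center_intensity: scan has < 3 samples",
                           call. = FALSE)
  c0 <- scan$center_index
  idx <- order(abs(seq_along(v) - c0))[1:3]
  vals <- v[idx]
  if (any(vals == 0)) {
    return(structure(0, degenerate = TRUE))
  }
  structure(exp(mean(log(vals))), degenerate = FALSE)
}

#' Background-subtracted two-channel intensity ratio
#'
#' `ratio = (num_mean - num_bg) / (den_mean - den_bg)`, the form used for
#' tension-sensor ratios such as alpha18 : total alpha-E-catenin, with the
#' background for each channel taken from a neighbouring cell nucleus.
#' Invariant to a shared multiplicative gain and to a shared additive
#' offset applied to a channel and its own background.
#'
#' @param num_mean,num_bg numerator channel cortical mean and background.
#' @param den_mean,den_bg denominator channel cortical mean and background.
#' @return list of class `ratio_result` with the four inputs and `ratio`.
#' @export
channel_ratio <- function(num_mean, num_bg, den_mean, den_bg) {
  if (any(den_mean - den_bg <= 0)) {
    stop("channel_ratio: denominator not positive after background subtraction",
         call. = FALSE)
  }
  structure(list(numerator_mean = num_mean, numerator_bg = num_bg,
                 denominator_mean = den_mean, denominator_bg = den_bg,
                 ratio = (num_mean - num_bg) / (den_mean - den_bg)),
            class = "ratio_result")
}

#' @export
print.ratio_result <- function(x, ...) {
  cat(sprintf("channel ratio: %.4g\n", x$ratio))
  invisible(x)
}

#' Junction continuity (% of junction length above threshold)
#'
#' Samples the channel at 1-px steps along the junction path (excluding a
#' vertex-trim fraction at each end), sets the threshold as
#' `threshold_frac` times the mean center intensity of three orthogonal
#' scans of the same junction, and returns the percentage of along-path
#' samples above threshold. Mature linear junctions score near 100; spot /
#' zipper junctions score near 100 x duty cycle. Scale-invariant: both the
#' samples and the threshold derive from the same image.
#'
#' @param img a `junction_image`.
#' @param channel channel to measure (default first channel).
#' @param threshold_frac threshold as a fraction of the mean center
#'   intensity (default 0.5).
#' @param trim_frac fraction of the path trimmed at each end to exclude
#'   tricellular vertices (default 0.05).
#' @return percent in `[0, 100]`; attribute `degenerate_threshold` flags a
#'   threshold at or below the image offset floor (non-positive threshold).
#' @export
junction_continuity <- function(img, channel = names(img$channels)[1],
                                threshold_frac = 0.5, trim_frac = 0.05) {
  stopifnot(inherits(img, "junction_image"))
  p <- resample_path(img$path)
  if (nrow(p) < 10L) stop("junction_continuity: path too short (< 10 px)",
                          call. = FALSE)
  keep <- seq(from = max(1L, ceiling(trim_frac * nrow(p))),
              to = min(nrow(p), floor((1 - trim_frac) * nrow(p))))
  p <- p[keep, , drop = FALSE]
  scans <- orthogonal_linescans(img, channel, anchor_channel = channel)
  centers <- vapply(scans, function(s) as.numeric(center_intensity(s)),
                    numeric(1))
  threshold <- threshold_frac * mean(centers)
  vals <- bilinear_sample(img$channels[[channel]], p$x, p$y)
  out <- 100 * mean(vals > threshold)
  attr(out, "degenerate_threshold") <- threshold <= 0
  out
}

#' Apical fraction of a radial cortical intensity profile
#'
#' Fraction of the background-subtracted total intensity that falls within
#' the central 50% of a cortical linescan anchored at the basement-membrane
#' contact point; by convention the central half of the path is the apical
#' surface. Negative background-subtracted values are clamped at 0.
#'
#' @param profile numeric intensity vector (length >= 4) tracing the cortex
#'   from the BM contact point.
#' @param bg constant background level to subtract (default 0).
#' @return fraction in `[0, 1]`, or `NA` if the subtracted profile is all
#'   zero.
#' @export
radial_intensity_fraction <- function(profile, bg = 0) {
  if (length(profile) < 4L) {
    stop("radial_intensity_fraction: profile length must be >= 4",
         call. = FALSE)
  }
  v <- pmax(profile - bg, 0)
  total <- sum(v)
  if (total == 0) return(NA_real_)
  L <- length(v)
  apical <- seq(from = floor(L / 4) + 1L, to = ceiling(3 * L / 4))
  sum(v[apical]) / total
}

#' Classify a radial profile as apical, absent or other LGN recruitment
#'
#' A profile is called `apical` when it has a prominent peak whose center
#' lies within the central 50% of the path (the apical surface); `other`
#' when the prominent peak lies outside the central half; `absent` when no
#' prominent peak exists. The background level and spread are estimated
#' robustly from the profile itself (median and MAD), and peak prominence
#' is the mean of a small window around the maximum minus the background —
#' averaging over the window keeps isolated noise maxima from registering
#' as crescents.
#'
#' @param profile numeric intensity vector.
#' @param k prominence multiplier (default 3): the window mean must exceed
#'   the background by more than `k` robust SDs.
#' @return one of `"apical"`, `"absent"`, `"other"`.
#' @export
lgn_recruitment_class <- function(profile, k = 3) {
  if (length(profile) < 4L) {
    stop("lgn_recruitment_class: profile too short", call. = FALSE)
  }
  L <- length(profile)
  bg <- stats::median(profile)
  s <- stats::mad(profile)
  peak <- which.max(profile)
  half_w <- max(1L, L %/% 40)
  win <- max(1L, peak - half_w):min(L, peak + half_w)
  prominence <- mean(profile[win]) - bg
  if (prominence <= k * s || prominence <= 0) return("absent")
  if (peak > L / 4 && peak <= 3 * L / 4) "apical" else "other"
}

#' Endfoot : apical-cortex anisotropy ratio
#'
#' Paired per-cell ratio of background-subtracted cortical intensity in the
#' basal endfoot plane over the apical plane of the same daughter cell
#' (e.g. for pMLC2 or tensile alpha-E-catenin).
#'
#' @param endfoot_mean,apical_ring_mean mean cortical intensities.
#' @param bg shared background level.
#' @return numeric ratio(s).
#' @export
endfoot_anisotropy <- function(endfoot_mean, apical_ring_mean, bg = 0) {
  if (any(apical_ring_mean - bg <= 0)) {
    stop("endfoot_anisotropy: apical mean not positive after background subtraction",
         call. = FALSE)
  }
  (endfoot_mean - bg) / (apical_ring_mean - bg)
}

#' Tissue stratification metrics from an annotated section
#'
#' Computes the differentiation and density metrics for a section:
#' * `k10_thickness_um` — K10+ mask area divided by basement-membrane arc
#'   length (micrometres);
#' * `basal_density`, `sb_density` — nuclei per micrometre of BM;
#' * `mitotic_index` — mitotic (pHH3+) basal nuclei per 100 micrometres of
#'   BM.
#'
#' @param section a `section_image` (see [make_section_image()]).
#' @return named list of the metrics above.
#' @export
tissue_metrics <- function(section) {
  stopifnot(inherits(section, "section_image"))
  if (section$bm_length_um <= 0) {
    stop("tissue_metrics: zero basement-membrane length", call. = FALSE)
  }
  px_area <- section$pixel_size^2
  k10_area_um2 <- sum(section$k10_mask) * px_area
  nuc <- section$nuclei
  basal <- nuc$compartment == "basal"
  list(k10_thickness_um = k10_area_um2 / section$bm_length_um,
       basal_density = sum(basal) / section$bm_length_um,
       sb_density = sum(!basal) / section$bm_length_um,
       mitotic_index = 100 * sum(nuc$mitotic[basal]) / section$bm_length_um)
}

#' Local cell density (cells per square micrometre)
#'
#' @param n_neighbors number of neighbouring cells counted.
#' @param area_um2 area occupied by those neighbours, square micrometres.
#' @return density in cells per square micrometre.
#' @export
local_density <- function(n_neighbors, area_um2) {
  if (any(area_um2 <= 0)) stop("local_density: area must be > 0",
                               call. = FALSE)
  n_neighbors / area_um2
}
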