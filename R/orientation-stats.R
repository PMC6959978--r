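#' Construct a labelled sample of unsigned division angles
#'
#' Light container used by the distribution statistics: a vector of unsigned
#' angles in `[0, 90]` plus a free-text label (genotype, stage, ...).
#'
#' @param angles numeric vector of unsigned angles in `[0, 90]`, length >= 1.
#' @param label character scalar naming the pool.
#' @return object of class `angle_sample` with elements `angles`, `label`, `n`.
#' @examples
#' s <- angle_sample(c(10, 45, 80), "example")
#' s$n
#' @export
angle_sample <- function(angles, label = "") {
  if (!is.numeric(angles) || length(angles) < 1L) {
    stop("angle_sample: need at least one angle", call. = FALSE)
  }
  if (any(!is.finite(angles)) || any(angles < 0 | angles > 90)) {
    stop("angle_sample: angles must be finite and in [0, 90]", call. = FALSE)
  }
  structure(list(angles = as.numeric(angles), label = as.character(label)[1],
                 n = length(angles)),
            class = "angle_sample")
}

#' @export
print.angle_sample <- function(x, ...) {
  cat(sprintf("angle_sample '%s': n = %d, mean = %.1f deg\n",
              x$label, x$n, mean(x$angles)))
  invisible(x)
}

as_angle_sample <- function(x, label = "") {
  if (inherits(x, "angle_sample")) x else angle_sample(x, label)
}

#' Radial histogram of division angles
#'
#' Counts angles into fixed-width bins over `[0, 90]`; the bins are
#' half-open `[0, w), [w, 2w), ...` with the last bin closed at 90 so the
#' counts always sum to the sample size.
#'
#' @param s an [angle_sample()] or numeric vector of angles.
#' @param bin_width bin width in degrees; must divide 90.
#' @return data.frame with columns `bin_lo`, `bin_hi`, `count`.
#' @export
radial_histogram <- function(s, bin_width = 10) {
  s <- as_angle_sample(s)
  if (!is.numeric(bin_width) || length(bin_width) != 1L || bin_width <= 0 ||
      (90 %% bin_width) != 0) {
    stop("radial_histogram: bin_width must divide 90", call. = FALSE)
  }
  k <- 90 %/% bin_width
  idx <- pmin(floor(s$angles / bin_width), k - 1L) + 1L  # 90 -> last bin
  counts <- tabulate(idx, nbins = k)
  data.frame(bin_lo = (seq_len(k) - 1L) * bin_width,
             bin_hi = seq_len(k) * bin_width,
             count = counts)
}

#' Empirical cumulative frequency distribution of an angle sample
#'
#' Returns the ECDF evaluated at each distinct angle, i.e. the cumulative
#' frequency distribution used to display division-angle pools: sorted
#' angles with nondecreasing cumulative fractions ending at exactly 1.
#'
#' @param s an [angle_sample()] or numeric vector of angles.
#' @return data.frame with columns `angle` (sorted, distinct) and
#'   `cum_fraction`.
#' @export
angle_ecdf <- function(s) {
  s <- as_angle_sample(s)
  x <- sort(s$angles)
  last <- !duplicated(x, fromLast = TRUE)
  data.frame(angle = x[last],
             cum_fraction = seq_along(x)[last] / s$n)
}

test_result <- function(statistic, p_value, test_name, n1, n2 = NA_integer_) {
  structure(list(statistic = unname(statistic), p_value = unname(p_value),
                 test_name = test_name, n1 = n1, n2 = n2),
            class = "orientation_test")
}

#' @export
print.orientation_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (n1 = %d%s)\n", x$test_name,
              x$statistic, x$p_value, x$n1,
              if (is.na(x$n2)) "" else sprintf(", n2 = %d", x$n2)))
  invisible(x)
}

#' One-sample Kolmogorov-Smirnov test against uniformity on [0, 90]
#'
#' Tests whether an angle pool is consistent with a uniform (random)
#' distribution of division angles on `[0, 90]` degrees, the reference used
#' to distinguish random from bimodal pools. Exact p-values are used for
#' n < 35, the asymptotic approximation otherwise.
#'
#' @param s an [angle_sample()] or numeric vector of angles; n >= 5.
#' @return an `orientation_test` with the KS statistic D and p-value.
#' @export
ks_uniform <- function(s) {
  s <- as_angle_sample(s)
  if (s$n < 5L) stop("ks_uniform: need n >= 5 (insufficient data)",
                     call. = FALSE)
  ht <- suppressWarnings(
    stats::ks.test(s$angles, "punif", min = 0, max = 90, exact = s$n < 35))
  test_result(ht$statistic, ht$p.value, "ks_uniform", s$n)
}

#' Two-sample Kolmogorov-Smirnov test between angle pools
#'
#' @param a,b [angle_sample()]s or numeric vectors of angles; both n >= 5.
#' @return an `orientation_test` with the two-sample D and p-value.
#' @export
ks_two_sample <- function(a, b) {
  a <- as_angle_sample(a); b <- as_angle_sample(b)
  if (a$n < 5L || b$n < 5L) {
    stop("ks_two_sample: need n >= 5 in both samples (insufficient data)",
         call. = FALSE)
  }
  ht <- suppressWarnings(stats::ks.test(a$angles, b$angles))
  test_result(ht$statistic, ht$p.value, "ks_two_sample", a$n, b$n)
}

#' Classify an angle pool as random, bimodal or planar-shifted
#'
#' Operational rule for the distribution shapes seen in division-angle
#' pools. A pool is called `random` when the uniformity test does not reject
#' (`p >= alpha`). Non-uniform pools are called `bimodal` when the oblique
#' bin (30-60 degrees) is depleted below both outer bins *and* both outer
#' bins exceed their uniform share (1/3) — the sigmoidal cumulative shape —
#' otherwise `planar_shifted` (mass concentrated toward one end, in practice
#' the planar end). The bin requirement on both outer bins keeps strongly
#' planar-skewed pools (e.g. 97/1/2) out of the bimodal class.
#'
#' @param s an [angle_sample()] or numeric vector of angles; n >= 20.
#' @param alpha significance level of the uniformity gate.
#' @return list of class `distribution_call` with elements `call`
#'   (`"random"`, `"bimodal"` or `"planar_shifted"`), `test`
#'   (the [ks_uniform()] result) and `bin_fractions` (planar/oblique/
#'   perpendicular fractions).
#' @export
classify_distribution <- function(s, alpha = 0.05) {
  s <- as_angle_sample(s)
  if (s$n < 20L) stop("classify_distribution: need n >= 20", call. = FALSE)
  ks <- ks_uniform(s)
  cls <- classify_orientation(s$angles)
  fr <- as.numeric(table(cls) / s$n)
  names(fr) <- orientation_levels()
  call <- if (ks$p_value >= alpha) {
    "random"
  } else if (fr["oblique"] < fr["planar"] && fr["oblique"] < fr["perpendicular"] &&
             fr["planar"] > 1 / 3 && fr["perpendicular"] > 1 / 3) {
    "bimodal"
  } else {
    "planar_shifted"
  }
  structure(list(call = call, test = ks, bin_fractions = fr),
            class = "distribution_call")
}

#' @export
print.distribution_call <- function(x, ...) {
  cat(sprintf("distribution call: %s (KS p = %.3g; planar/oblique/perp = %s)\n",
              x$call, x$test$p_value,
              paste(sprintf("%.2f", x$bin_fractions), collapse = "/")))
  invisible(x)
}

#' Pearson chi-square test of observed counts against expected proportions
#'
#' Compares an observed categorical distribution (e.g. LGN
#' apical/absent/other frequencies) against expected proportions from a
#' control group, with k - 1 degrees of freedom.
#'
#' @param observed integer vector of observed counts (optionally named).
#' @param expected_proportions numeric vector of the same length summing
#'   to 1; every implied expected count must be >= 1.
#' @return an `orientation_test` with the chi-square statistic and p-value.
#' @export
chi_square_categorical <- function(observed, expected_proportions) {
  if (length(observed) != length(expected_proportions)) {
    stop("chi_square_categorical: category mismatch", call. = FALSE)
  }
  if (!is.null(names(observed)) && !is.null(names(expected_proportions)) &&
      !identical(names(observed), names(expected_proportions))) {
    stop("chi_square_categorical: category names do not match", call. = FALSE)
  }
  if (abs(sum(expected_proportions) - 1) > 1e-8) {
    stop("chi_square_categorical: expected proportions must sum to 1",
         call. = FALSE)
  }
  n <- sum(observed)
  if (any(n * expected_proportions < 1)) {
    stop("chi_square_categorical: expected count below 1", call. = FALSE)
  }
  ht <- suppressWarnings(stats::chisq.test(x = observed,
                                           p = expected_proportions))
  test_result(ht$statistic, ht$p.value, "chi_square_categorical",
              as.integer(n))
}

#' Standard two-group comparisons (pass-throughs)
#'
#' Thin wrappers over the standard routines used for scalar intensity and
#' thickness comparisons: Mann-Whitney U, Student's t, and the paired
#' Wilcoxon signed-rank test.
#'
#' @param x,y numeric vectors.
#' @param method one of `"mann_whitney"`, `"t"`, `"wilcoxon_paired"`.
#' @param ... passed to the underlying [stats::wilcox.test()] or
#'   [stats::t.test()] (e.g. `alternative`).
#' @return an `orientation_test`.
#' @export
compare_groups <- function(x, y,
                           method = c("mann_whitney", "t", "wilcoxon_paired"),
                           ...) {
  method <- match.arg(method)
  ht <- switch(method,
    mann_whitney = suppressWarnings(stats::wilcox.test(x, y, ...)),
    t = stats::t.test(x, y, ...),
    wilcoxon_paired = suppressWarnings(stats::wilcox.test(x, y, paired = TRUE,
                                                          ...)))
  test_result(ht$statistic, ht$p.value, method, length(x), length(y))
}

#' Read an angle-sample CSV (columns sample_label, angle_deg)
#'
#' @param path CSV path.
#' @return named list of [angle_sample()]s, one per distinct label.
#' @export
read_angle_samples <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("sample_label", "angle_deg") %in% names(df))) {
    stop("read_angle_samples: need columns sample_label, angle_deg",
         call. = FALSE)
  }
  lapply(split(df$angle_deg, df$sample_label), function(a) angle_sample(a))
}
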