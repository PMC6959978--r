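#' Fold an angle into the division-orientation range [0, 90] degrees
#'
#' Division and spindle angles are reported as the acute angle between an
#' undirected axis and the local basement-membrane direction, so any raw
#' angle (in degrees) is folded into a single quadrant:
#' `fold_angle(x) == fold_angle(x %% 180) == fold_angle(180 - x %% 180)`.
#' Folding is idempotent and is applied at construction time throughout the
#' package, so downstream statistics never see raw angles.
#'
#' @param raw numeric vector of angles in degrees (any finite real values).
#' @return numeric vector of angles in `[0, 90]`.
#' @examples
#' fold_angle(c(120, -30, 45))  # 60 30 45
#' @export
fold_angle <- function(raw) {
  if (!is.numeric(raw) || any(!is.finite(raw))) {
    stop("fold_angle: 'raw' must be finite numeric", call. = FALSE)
  }
  a <- raw %% 180
  ifelse(a > 90, 180 - a, a)
}

#' Division angle between a daughter-daughter axis and the basement membrane
#'
#' The division angle is the acute angle between the vector connecting the
#' centers of the two daughter nuclei and the local basement-membrane
#' direction, folded into `[0, 90]` degrees. The result is invariant to
#' swapping the daughters and to translating both points.
#'
#' @param d1,d2 numeric length-2 vectors `c(x, y)` (or two-column matrices
#'   for vectorized use) giving the daughter-nucleus centers. By convention
#'   y increases apically.
#' @param bm_axis numeric length-2 vector giving the local basement-membrane
#'   direction (need not be unit length, must be nonzero).
#' @return unsigned angle(s) in degrees in `[0, 90]`.
#' @examples
#' division_angle(c(0, 0), c(-5, 5), c(1, 0))  # 45
#' @export
as_points <- function(p) {
  m <- if (is.matrix(p)) p else matrix(p, ncol = 2)
  dimnames(m) <- NULL
  m
}

division_angle <- function(d1, d2, bm_axis) {
  d1 <- as_points(d1); d2 <- as_points(d2)
  if (!all(is.finite(d1)) || !all(is.finite(d2))) {
    stop("division_angle: non-finite coordinates", call. = FALSE)
  }
  if (length(bm_axis) != 2L || !all(is.finite(bm_axis)) ||
      all(bm_axis == 0)) {
    stop("division_angle: 'bm_axis' must be a nonzero length-2 vector",
         call. = FALSE)
  }
  v <- d2 - d1
  if (any(v[, 1] == 0 & v[, 2] == 0)) {
    stop("division_angle: coincident daughter centers (degenerate geometry)",
         call. = FALSE)
  }
  raw <- atan2(v[, 2], v[, 1]) - atan2(bm_axis[2], bm_axis[1])
  unname(fold_angle(raw * 180 / pi))
}

#' Classify an unsigned division angle as planar, oblique or perpendicular
#'
#' Bins partition `[0, 90]` with half-open boundaries: planar `[0, 30)`,
#' oblique `[30, 60)`, perpendicular `[60, 90]`. The half-open convention is
#' a deterministic tie-break; 30 degrees is oblique and 60 degrees is
#' perpendicular.
#'
#' @param a numeric vector of unsigned angles in `[0, 90]`.
#' @return factor with levels `planar`, `oblique`, `perpendicular`.
#' @examples
#' classify_orientation(c(15, 30, 45, 60, 90))
#' @export
classify_orientation <- function(a) {
  if (!is.numeric(a) || any(!is.finite(a)) || any(a < 0 | a > 90)) {
    stop("classify_orientation: angles must be in [0, 90]", call. = FALSE)
  }
  factor(ifelse(a < 30, "planar", ifelse(a < 60, "oblique", "perpendicular")),
         levels = orientation_levels())
}

#' @rdname classify_orientation
#' @export
orientation_levels <- function() c("planar", "oblique", "perpendicular")

#' Signed radial angle of an LGN crescent relative to the basement membrane
#'
#' Angle between the vector from the nucleus center to the LGN signal center
#' and the basement-membrane direction, signed so that crescents on the
#' apical side (+y) are positive and crescents on the basal side negative;
#' range `[-90, +90]` degrees.
#'
#' @param lgn_center,nucleus_center numeric length-2 vectors (or two-column
#'   matrices) of the LGN signal center and nucleus center.
#' @param bm_axis local basement-membrane direction, nonzero length-2 vector.
#' @return signed angle(s) in degrees in `[-90, 90]`.
#' @export
lgn_radial_angle <- function(lgn_center, nucleus_center, bm_axis) {
  lgn <- as_points(lgn_center); nuc <- as_points(nucleus_center)
  if (length(bm_axis) != 2L || all(bm_axis == 0)) {
    stop("lgn_radial_angle: invalid bm_axis", call. = FALSE)
  }
  v <- lgn - nuc
  if (any(v[, 1] == 0 & v[, 2] == 0)) {
    stop("lgn_radial_angle: coincident centers (degenerate geometry)",
         call. = FALSE)
  }
  raw <- (atan2(v[, 2], v[, 1]) - atan2(bm_axis[2], bm_axis[1])) * 180 / pi
  raw <- ((raw + 180) %% 360) - 180  # (-180, 180]
  # crescent direction is directed: magnitude folded to [0,90], sign = apical
  mag <- abs(raw)
  mag <- ifelse(mag > 90, 180 - mag, mag)
  sgn <- ifelse(raw >= 0, 1, -1)
  unname(sgn * mag)
}

#' Deviation between a division/spindle axis and the LGN radial direction
#'
#' The division or spindle axis is an undirected line, so the deviation is
#' the smallest angle between that line and the LGN radial direction, in
#' `[0, 90]` degrees.
#'
#' @param axis_angle numeric, spindle/division axis angle in degrees (signed
#'   or unsigned; treated modulo 180).
#' @param lgn_angle numeric, signed LGN radial angle in `[-90, 90]`.
#' @return deviation(s) in degrees in `[0, 90]`.
#' @export
axis_lgn_deviation <- function(axis_angle, lgn_angle) {
  if (any(!is.finite(axis_angle)) || any(!is.finite(lgn_angle))) {
    stop("axis_lgn_deviation: non-finite input", call. = FALSE)
  }
  fold_angle(axis_angle - lgn_angle)
}

#' Read a division coordinate table and compute division angles
#'
#' Reads a CSV with columns `division_id, frame_t_min, d1_x, d1_y, d2_x,
#' d2_y, bm_dx, bm_dy` (micrometre units, header required) and appends an
#' `angle_deg` column computed with [division_angle()] row by row, each row
#' using its own local basement-membrane direction.
#'
#' @param path path to the CSV file.
#' @return data.frame with the input columns plus `angle_deg`.
#' @export
read_division_coordinates <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("division_id", "frame_t_min", "d1_x", "d1_y", "d2_x", "d2_y",
            "bm_dx", "bm_dy")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("read_division_coordinates: missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df$angle_deg <- vapply(seq_len(nrow(df)), function(i) {
    division_angle(c(df$d1_x[i], df$d1_y[i]), c(df$d2_x[i], df$d2_y[i]),
                   c(df$bm_dx[i], df$bm_dy[i]))
  }, numeric(1))
  df
}
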