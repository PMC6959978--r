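#' Suprabasal : basal cell ratio of a clone
#'
#' @param basal,suprabasal nonnegative cell counts (vectorized); each clone
#'   must contain at least one cell.
#' @return `suprabasal / basal`, or `NA` where `basal == 0` (delamination
#'   candidates have no defined ratio).
#' @export
clone_ratio <- function(basal, suprabasal) {
  if (any(basal < 0) || any(suprabasal < 0) || any(basal + suprabasal < 1)) {
    stop("clone_ratio: counts must be >= 0 with at least one cell per clone",
         call. = FALSE)
  }
  ifelse(basal > 0, suprabasal / basal, NA_real_)
}

#' @rdname classify_clone
#' @export
clone_layers <- function() c("basal", "spinous", "SG3", "above_SG3")

#' Classify a clone by its basal / suprabasal composition
#'
#' Clone subtypes from lineage tracing:
#' * `delamination` — no basal cells, suprabasal cells no higher than the
#'   first stratum granulosum layer (SG3): the founder differentiated by
#'   leaving the basement membrane without dividing.
#' * `excluded` — no basal cells but progeny above SG3 (too old to have
#'   arisen from the trace; removed from analysis).
#' * `balanced` — SB:basal ratio exactly 1.
#' * `sb_rich` — ratio > 1; `basal_rich` — ratio < 1 (this includes clones
#'   with no suprabasal cells, ratio 0).
#'
#' @param basal,suprabasal nonnegative cell counts (vectorized).
#' @param highest_layer highest layer reached by the clone; one of
#'   `clone_layers()`.
#' @return factor with levels `balanced`, `basal_rich`, `sb_rich`,
#'   `delamination`, `excluded`.
#' @export
classify_clone <- function(basal, suprabasal, highest_layer = "spinous") {
  if (any(!highest_layer %in% clone_layers())) {
    stop("classify_clone: invalid highest_layer", call. = FALSE)
  }
  r <- clone_ratio(basal, suprabasal)
  n <- length(r)
  highest_layer <- rep_len(highest_layer, n)
  lab <- character(n)
  nob <- basal == 0
  lab[nob & highest_layer != "above_SG3"] <- "delamination"
  lab[nob & highest_layer == "above_SG3"] <- "excluded"
  lab[!nob & r == 1] <- "balanced"
  lab[!nob & r > 1] <- "sb_rich"
  lab[!nob & r < 1] <- "basal_rich"
  factor(lab, levels = c("balanced", "basal_rich", "sb_rich",
                         "delamination", "excluded"))
}

#' Clonal density array of basal x suprabasal compositions
#'
#' Matrix of clone-composition frequencies: entry `[b, s]` is the fraction
#' of included clones with `b` basal and `s` suprabasal cells (0-based on
#' both axes, capped at `max_basal`/`max_sb` with an overflow bin at the
#' cap). Delamination and excluded clones are left out; entries sum to 1.
#'
#' @param clones data.frame with columns `basal`, `suprabasal` and
#'   optionally `highest_layer`.
#' @param max_basal,max_sb axis caps (default 12).
#' @return numeric matrix with dimnames giving the basal (rows) and
#'   suprabasal (columns) counts, last row/column marked `>=`.
#' @export
density_array <- function(clones, max_basal = 12, max_sb = 12) {
  hl <- if ("highest_layer" %in% names(clones)) clones$highest_layer
        else "spinous"
  cls <- classify_clone(clones$basal, clones$suprabasal, hl)
  keep <- !cls %in% c("delamination", "excluded")
  if (!any(keep)) {
    stop("density_array: no non-delamination clones", call. = FALSE)
  }
  b <- pmin(clones$basal[keep], max_basal)
  s <- pmin(clones$suprabasal[keep], max_sb)
  m <- matrix(0, nrow = max_basal + 1L, ncol = max_sb + 1L,
              dimnames = list(basal = c(0:(max_basal - 1L),
                                        paste0(">=", max_basal)),
                              suprabasal = c(0:(max_sb - 1L),
                                             paste0(">=", max_sb))))
  for (i in seq_along(b)) {
    m[b[i] + 1L, s[i] + 1L] <- m[b[i] + 1L, s[i] + 1L] + 1
  }
  m / sum(m)
}

#' Fate configuration for the clone simulator
#'
#' Per-generation behaviour of each basal cell in a clone: it delaminates
#' (moves suprabasally without dividing) with probability `p_delaminate`,
#' otherwise divides with an orientation outcome drawn from
#' `division_mix`. Planar divisions are symmetric (two basal daughters);
#' perpendicular divisions are asymmetric (one basal, one suprabasal).
#' Oblique divisions correct to planar (symmetric) with probability
#' `p_oblique_corrects_planar`, otherwise they behave asymmetrically
#' (uncorrected oblique or perpendicular-corrected divisions both place one
#' daughter suprabasally).
#'
#' @param p_delaminate per-generation delamination probability.
#' @param division_mix length-3 proportions over
#'   planar/oblique/perpendicular division outcomes (sums to 1).
#' @param p_oblique_corrects_planar probability an oblique division is
#'   corrected to planar (symmetric outcome).
#' @param generations number of division rounds (default 3, matching a
#'   72-hour trace).
#' @return list of class `fate_config`.
#' @export
fate_config <- function(p_delaminate = 0.15,
                        division_mix = c(planar = 1 / 3, oblique = 1 / 3,
                                         perpendicular = 1 / 3),
                        p_oblique_corrects_planar = 0.6,
                        generations = 3) {
  if (p_delaminate < 0 || p_delaminate > 1 ||
      p_oblique_corrects_planar < 0 || p_oblique_corrects_planar > 1) {
    stop("fate_config: probabilities must be in [0, 1]", call. = FALSE)
  }
  if (length(division_mix) != 3L || any(division_mix < 0) ||
      abs(sum(division_mix) - 1) > 1e-8) {
    stop("fate_config: division_mix must be 3 proportions summing to 1",
         call. = FALSE)
  }
  if (generations < 1) stop("fate_config: generations must be >= 1",
                            call. = FALSE)
  structure(list(p_delaminate = p_delaminate,
                 division_mix = stats::setNames(as.numeric(division_mix),
                                                orientation_levels()),
                 p_oblique_corrects_planar = p_oblique_corrects_planar,
                 generations = as.integer(generations)),
            class = "fate_config")
}

#' Simulate clonal lineage-tracing outcomes
#'
#' Each clone starts from a single labelled basal cell. In each generation
#' every basal cell either delaminates (becomes suprabasal without
#' dividing) or divides; symmetric (planar, or corrected-oblique) divisions
#' yield two basal daughters, asymmetric (perpendicular, or uncorrected
#' oblique) divisions yield one basal and one suprabasal daughter.
#' Suprabasal cells are post-mitotic and never divide. The highest layer is
#' recorded as `basal` for purely basal clones and `spinous` otherwise, so
#' zero-basal clones classify as delamination events.
#'
#' @param cfg a [fate_config()].
#' @param n_clones number of clones.
#' @param seed integer seed; results are reproducible given
#'   `(cfg, n_clones, seed)`.
#' @param genotype label copied into the table.
#' @return data.frame with columns `clone_id`, `genotype`, `basal`,
#'   `suprabasal`, `highest_layer`, `class` (from [classify_clone()]).
#' @export
simulate_clones <- function(cfg, n_clones, seed = 1, genotype = "WT") {
  stopifnot(inherits(cfg, "fate_config"), n_clones >= 1)
  set.seed(seed)
  p_sym <- cfg$division_mix["planar"] +
    cfg$division_mix["oblique"] * cfg$p_oblique_corrects_planar
  basal <- integer(n_clones); sb <- integer(n_clones)
  for (k in seq_len(n_clones)) {
    b <- 1L; s <- 0L
    for (g in seq_len(cfg$generations)) {
      if (b == 0L) break
      u <- stats::runif(b)
      delam <- sum(u < cfg$p_delaminate)
      dividing <- b - delam
      sym <- if (dividing > 0) {
        sum(stats::runif(dividing) < p_sym)
      } else 0L
      asym <- dividing - sym
      # delaminating cells move up; symmetric -> 2 basal; asymmetric -> 1+1
      b <- 2L * sym + asym
      s <- s + delam + asym
    }
    basal[k] <- b; sb[k] <- s
  }
  layer <- ifelse(sb > 0, "spinous", "basal")
  data.frame(clone_id = sprintf("clone%05d", seq_len(n_clones)),
             genotype = genotype, basal = basal, suprabasal = sb,
             highest_layer = layer,
             class = classify_clone(basal, sb, layer),
             stringsAsFactors = FALSE)
}

#' Read a clone table CSV
#'
#' Expects columns `clone_id, genotype, basal, suprabasal, highest_layer`;
#' appends the `class` column.
#'
#' @param path CSV path.
#' @return data.frame of clone records with classification.
#' @export
read_clone_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("basal", "suprabasal", "highest_layer")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("read_clone_csv: missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df$class <- classify_clone(df$basal, df$suprabasal, df$highest_layer)
  df
}
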