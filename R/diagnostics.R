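# Behavioral parameter-recovery diagnostics: recover the engine's effective
# physical gates and clinical boundaries purely by probing the public
# surface with constructed inputs. Used by the validation suite and the
# reproduction script; also handy when auditing a configuration.

#' Recover the classification boundaries by bisection
#'
#' Bisects [classify_ratio()] for the ratio at which the call leaves the
#' nonamplified band and the ratio above which it becomes amplified.
#'
#' @param thresholds a [ratio_thresholds()] object.
#' @param tol bisection tolerance; default 1e-9.
#' @return named numeric vector with `nonamp_boundary` and `amp_boundary`.
#' @export
recover_boundaries <- function(thresholds = ratio_thresholds(), tol = 1e-9) {
  bisect <- function(lo, hi, pred) {
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (pred(mid)) hi <- mid else lo <- mid
    }
    hi
  }
  non <- bisect(0, 3, function(r)
    classify_ratio(r, thresholds)$category != "nonamplified")
  amp <- bisect(2, 4, function(r)
    classify_ratio(r, thresholds)$category == "amplified")
  c(nonamp_boundary = non, amp_boundary = amp)
}

#' Recover a channel's merge distance by a separation sweep
#'
#' Renders two ideal supra-threshold point signals at increasing centroid
#' separations and reports the largest separation at which [detect_spots()]
#' still fuses them into a single spot.
#'
#' @param params channel [spot_params()]; default HER2.
#' @param um_per_px calibration of the probe images; fine enough to resolve
#'   the sweep step (default 0.02 um/px).
#' @param separations_um separations swept, default 0.2 to 1.5 um in 0.01
#'   um steps.
#' @return largest separation (um) reported as one spot.
#' @export
sweep_merge_distance <- function(params = her2_spot_params(),
                                 um_per_px = 0.02,
                                 separations_um = seq(0.2, 1.5, by = 0.01)) {
  H <- round(2.0 / um_per_px); W <- round(3.4 / um_per_px)
  sigma <- 0.05 / um_per_px
  r0 <- H / 2; c0 <- W / 4
  one <- function(sep) {
    im <- matrix(0, H, W)
    for (cc in c(c0, c0 + sep / um_per_px))
      im <- im + 230 * exp(-((row(im) - r0)^2 + (col(im) - cc)^2) / (2 * sigma^2))
    im <- matrix(as.integer(pmin(round(im), 255)), H, W)
    nrow(detect_spots(im, params, um_per_px, "her2"))
  }
  counts <- vapply(separations_um, one, integer(1))
  max(separations_um[counts == 1])
}

#' Recover a channel's minimum spot area by an object-size sweep
#'
#' Renders single discs of graded sizes (with sub-pixel centre offsets so
#' measured areas cover every grid step), measures each object's
#' post-threshold area through the detection pipeline, and reports the
#' smallest measured area that the channel's defaults accept as a spot.
#'
#' @param params channel [spot_params()]; default CEP17.
#' @param um_per_px probe calibration; 0.1 um/px makes pixel areas quantize
#'   to the 0.01 um^2 sweep step.
#' @param radii_px disc radii swept, in pixels.
#' @return smallest accepted post-threshold object area, um^2.
#' @export
sweep_min_area <- function(params = cep17_spot_params(), um_per_px = 0.1,
                           radii_px = seq(0.8, 4.0, by = 0.05)) {
  measure_gate <- spot_params(1e-6, params$min_distance_um,
                              params$intensity_frac)
  offsets <- list(c(0, 0), c(0.23, 0.11), c(0.41, 0.37))
  probe <- function(radius, off) {
    im <- disc_image(100, 100, 50.5 + off[1], 50.5 + off[2], radius)
    sized <- detect_spots(im, measure_gate, um_per_px, "cep17")
    if (nrow(sized) != 1) return(c(NA_real_, NA_real_))
    c(sized$area_um2, nrow(detect_spots(im, params, um_per_px, "cep17")))
  }
  res <- do.call(rbind, lapply(radii_px, function(r)
    do.call(rbind, lapply(offsets, function(o) probe(r, o)))))
  res <- res[!is.na(res[, 1]), , drop = FALSE]
  min(res[res[, 2] == 1, 1])
}

disc_image <- function(H, W, ctr_row, ctr_col, radius_px, value = 230) {
  im <- matrix(0L, H, W)
  im[(row(im) - ctr_row)^2 + (col(im) - ctr_col)^2 <= radius_px^2] <-
    as.integer(value)
  im
}

#' Run a synthetic cohort through a classifier and score concordance
#'
#' Generates a labeled cohort, analyzes every case with the automated
#' pipeline (no human correction) and reports the concordance of the output
#' categories against the planted labels.
#'
#' @param profile,n_cases,seed,... passed to [generate_cohort()].
#' @param mode `"nuclei"` or `"tile"`.
#' @param config analysis configuration.
#' @return list with `concordance` (a [concordance()] report), `calls`
#'   (per-case planted and detected categories and ratios).
#' @export
cohort_concordance <- function(profile, n_cases, seed, mode = "nuclei",
                               config = load_config(), ...) {
  cohort <- generate_cohort(profile, n_cases, seed, ...)
  calls <- do.call(rbind, lapply(cohort, function(cs) {
    res <- analyze_case(cs, config = config, mode = mode)$result
    data.frame(case_id = cs$case_id,
               planted_ratio = cs$truth$ratio,
               planted_category = cs$truth$category,
               ratio = res$ratio, category = res$category,
               n_units = res$n_units,
               rejected = "case_rejected" %in% res$qc)
  }))
  list(concordance = concordance(calls$planted_category, calls$category),
       calls = calls)
}
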