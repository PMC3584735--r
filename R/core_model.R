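#' fishratio: automated HER2/CEP17 FISH quantification
#'
#' Dual-probe FISH quantification of HER2 gene amplification: spot detection
#' in the Spectrum Orange (HER2) and Spectrum Green (CEP17) channels, a
#' tile-sampling and a nuclei-sampling classifier, HSR area-mode counting,
#' HER2/CEP17 ratio computation and amplification-status calls, plus a
#' ground-truth synthetic field generator and concordance reporting.
#'
#' @import EBImage
#' @importFrom stats median quantile rnorm runif rpois qpois ppois uniroot
#'   setNames dist hclust cutree
#' @importFrom utils head modifyList write.csv
#' @name fishratio-package
"_PACKAGE"

# ---- parameter constructors -------------------------------------------------

#' Spot detection parameters for one fluorescence channel
#'
#' Physical gates that define a countable FISH spot: a minimum object area,
#' a minimum centroid distance below which neighbouring objects are merged
#' into one spot, and a relative intensity threshold applied to the
#' preprocessed channel.
#'
#' @param min_area_um2 minimum object area in square micrometres (> 0).
#' @param min_distance_um minimum inter-object centroid distance in
#'   micrometres (> 0); objects closer than this are merged.
#' @param intensity_frac relative intensity threshold in (0, 1]: a spot's
#'   peak must reach this fraction of the channel's reference maximum
#'   (the 99.9th percentile of the preprocessed image).
#' @return an object of class `spot_params`.
#' @seealso [her2_spot_params()], [cep17_spot_params()] for the validated
#'   channel defaults.
#' @export
spot_params <- function(min_area_um2, min_distance_um, intensity_frac) {
  stopifnot(
    is.numeric(min_area_um2), length(min_area_um2) == 1L, min_area_um2 > 0,
    is.numeric(min_distance_um), length(min_distance_um) == 1L, min_distance_um > 0,
    is.numeric(intensity_frac), length(intensity_frac) == 1L,
    intensity_frac > 0, intensity_frac <= 1
  )
  structure(list(min_area_um2 = min_area_um2,
                 min_distance_um = min_distance_um,
                 intensity_frac = intensity_frac),
            class = "spot_params")
}

#' @rdname spot_params
#' @details `her2_spot_params()` returns the HER2 (Spectrum Orange) defaults:
#'   area 0.05 um^2, distance 0.8 um, intensity 33%. `cep17_spot_params()`
#'   returns the CEP17 (Spectrum Green) defaults: area 0.18 um^2, distance
#'   0.5 um, intensity 30%.
#' @export
her2_spot_params <- function() spot_params(0.05, 0.8, 0.33)

#' @rdname spot_params
#' @export
cep17_spot_params <- function() spot_params(0.18, 0.5, 0.30)

#' Tile-sampling parameters
#'
#' @param tile_px tile side length in pixels (>= 1); default 71.
#' @param min_coverage minimum fraction of the tile surface occupied by the
#'   counterstain mask for the tile to be accepted; default 0.40.
#' @param min_tiles minimum number of accepted tiles per case below which the
#'   case is rejected; default 32.
#' @return an object of class `tile_params`.
#' @export
tile_params <- function(tile_px = 71L, min_coverage = 0.40, min_tiles = 32L) {
  stopifnot(tile_px >= 1, min_coverage >= 0, min_coverage <= 1, min_tiles >= 1)
  structure(list(tile_px = as.integer(tile_px),
                 min_coverage = min_coverage,
                 min_tiles = as.integer(min_tiles)),
            class = "tile_params")
}

#' Nucleus gating parameters
#'
#' @param min_area_um2,max_area_um2 accepted nucleus area range in square
#'   micrometres; defaults 12 and 400.
#' @param min_roundness minimum circularity `4*pi*A/P^2` in (0, 1];
#'   default 0.60.
#' @param min_nuclei minimum accepted nuclei per case below which the case is
#'   rejected; default 20, mirroring the minimum nucleus count of manual
#'   scoring.
#' @return an object of class `nucleus_params`.
#' @export
nucleus_params <- function(min_area_um2 = 12, max_area_um2 = 400,
                           min_roundness = 0.60, min_nuclei = 20L) {
  stopifnot(min_area_um2 > 0, min_area_um2 < max_area_um2,
            min_roundness > 0, min_roundness <= 1, min_nuclei >= 1)
  structure(list(min_area_um2 = min_area_um2, max_area_um2 = max_area_um2,
                 min_roundness = min_roundness, min_nuclei = as.integer(min_nuclei)),
            class = "nucleus_params")
}

#' HER2/CEP17 ratio classification thresholds
#'
#' The clinical bands used to call a case: ratio < `nonamp_below` is
#' nonamplified, ratio > `amp_above` is amplified, anything in between
#' (inclusive on both ends) is equivocal. Equivocal cases with ratio >=
#' `eligibility_at` are flagged as potential candidates for targeted therapy.
#'
#' @param nonamp_below lower edge of the equivocal band; default 1.8.
#' @param amp_above upper edge of the equivocal band; default 2.2.
#' @param eligibility_at treatment-eligibility cutoff within the equivocal
#'   band; default 2.0.
#' @return an object of class `ratio_thresholds`.
#' @export
ratio_thresholds <- function(nonamp_below = 1.8, amp_above = 2.2,
                             eligibility_at = 2.0) {
  stopifnot(nonamp_below < eligibility_at, eligibility_at <= amp_above)
  structure(list(nonamp_below = nonamp_below, amp_above = amp_above,
                 eligibility_at = eligibility_at),
            class = "ratio_thresholds")
}

# ---- calibrated image -------------------------------------------------------

#' Bundle three co-registered 8-bit channels with a physical scale
#'
#' @param dapi,orange,green integer matrices of identical dimensions with
#'   values in \[0, 255\] holding the DAPI counterstain, HER2 (Spectrum
#'   Orange) and CEP17 (Spectrum Green) channels. Matrices are `[row, col]`.
#' @param um_per_px physical scale, micrometres per pixel (> 0).
#' @return an object of class `calibrated_image`.
#' @export
calibrated_image <- function(dapi, orange, green, um_per_px) {
  chk <- function(m, what) {
    if (!is.matrix(m) || !is.numeric(m))
      stop(what, " must be a numeric matrix", call. = FALSE)
    rng <- range(m)
    if (rng[1] < 0 || rng[2] > 255)
      stop(what, " intensities must lie in [0, 255]", call. = FALSE)
    m
  }
  chk(dapi, "dapi"); chk(orange, "orange"); chk(green, "green")
  if (!identical(dim(dapi), dim(orange)) || !identical(dim(dapi), dim(green)))
    stop("all three channels must have identical dimensions", call. = FALSE)
  stopifnot(is.numeric(um_per_px), length(um_per_px) == 1L, um_per_px > 0)
  structure(list(dapi = dapi, orange = orange, green = green,
                 um_per_px = um_per_px),
            class = "calibrated_image")
}

# ---- ratio arithmetic and classification ------------------------------------

#' HER2/CEP17 ratio from pooled spot-equivalent totals
#'
#' Dividing the pooled totals is identical to dividing the per-unit averages
#' (the number of sampling units cancels), and avoids per-unit divisions by
#' zero.
#'
#' @param total_her2,total_cep17 nonnegative pooled spot-equivalent counts.
#' @return `total_her2 / total_cep17`.
#' @export
compute_ratio <- function(total_her2, total_cep17) {
  stopifnot(is.numeric(total_her2), is.numeric(total_cep17),
            total_her2 >= 0, total_cep17 >= 0)
  if (total_cep17 == 0)
    stop(undefined_ratio_error("HER2/CEP17 ratio undefined: total CEP17 count is zero"))
  total_her2 / total_cep17
}

undefined_ratio_error <- function(msg) {
  structure(class = c("fishratio_undefined_ratio", "error", "condition"),
            list(message = msg, call = NULL))
}

#' Classify a HER2/CEP17 ratio into an amplification category
#'
#' Nonamplified below the lower threshold, amplified strictly above the upper
#' threshold, equivocal in the closed band between them. A case is flagged
#' treatment-eligible when amplified, or when equivocal with ratio at or above
#' the eligibility cutoff.
#'
#' @param ratio nonnegative finite HER2/CEP17 ratio(s); vectorised.
#' @param thresholds a [ratio_thresholds()] object.
#' @return a list with character vector `category` (one of `"nonamplified"`,
#'   `"equivocal"`, `"amplified"`) and logical vector `eligible`.
#' @examples
#' classify_ratio(2.2)  # borderline equivocal, eligible
#' @export
classify_ratio <- function(ratio, thresholds = ratio_thresholds()) {
  stopifnot(inherits(thresholds, "ratio_thresholds"))
  if (!is.numeric(ratio) || any(!is.finite(ratio)) || any(ratio < 0))
    stop("ratio must be finite and nonnegative", call. = FALSE)
  category <- ifelse(ratio < thresholds$nonamp_below, "nonamplified",
              ifelse(ratio > thresholds$amp_above, "amplified", "equivocal"))
  eligible <- category == "amplified" |
    (category == "equivocal" & ratio >= thresholds$eligibility_at)
  list(category = as.character(category), eligible = as.logical(eligible))
}

# ---- case result ------------------------------------------------------------

#' Assemble a per-case quantification result
#'
#' Internal constructor used by both classifiers; exported because edit
#' replays and the acceptance tooling inspect results directly.
#'
#' @param total_her2,total_cep17 pooled spot-equivalent totals over accepted
#'   sampling units.
#' @param n_units number of accepted sampling units (tiles or nuclei).
#' @param mode `"tile"` or `"nuclei"`.
#' @param thresholds a [ratio_thresholds()] object.
#' @param min_units minimum accepted units; fewer flags the case
#'   `case_rejected` and leaves the category `NA`.
#' @param qc character vector of additional QC flags to carry through.
#' @return an object of class `case_result`: a list with `total_her2`,
#'   `total_cep17`, `n_units`, `ratio`, `category`, `eligible`, `mode`, `qc`.
#' @export
case_result <- function(total_her2, total_cep17, n_units, mode,
                        thresholds = ratio_thresholds(),
                        min_units = 1L, qc = character()) {
  stopifnot(mode %in% c("tile", "nuclei"))
  res <- list(total_her2 = total_her2, total_cep17 = total_cep17,
              n_units = as.integer(n_units), ratio = NA_real_,
              category = NA_character_, eligible = NA, mode = mode,
              qc = qc)
  if (n_units < min_units) {
    res$qc <- unique(c(res$qc, "case_rejected"))
  } else {
    res$ratio <- compute_ratio(total_her2, total_cep17)
    cls <- classify_ratio(res$ratio, thresholds)
    res$category <- cls$category
    res$eligible <- cls$eligible
  }
  structure(res, class = "case_result")
}

#' @export
print.case_result <- function(x, ...) {
  cat(sprintf("<case_result: %s-sampling>\n", x$mode))
  cat(sprintf("  units: %d   HER2: %s   CEP17: %s\n",
              x$n_units, format(x$total_her2), format(x$total_cep17)))
  if (is.na(x$category)) {
    cat("  no call")
  } else {
    cat(sprintf("  ratio: %.3f   category: %s%s", x$ratio, x$category,
                if (isTRUE(x$eligible)) " (treatment-eligible)" else ""))
  }
  if (length(x$qc)) cat(sprintf("   [QC: %s]", paste(x$qc, collapse = ", ")))
  cat("\n")
  invisible(x)
}
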