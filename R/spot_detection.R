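# Channel preprocessing, counterstain masking, spot detection and HSR
# area-mode counting. Rasters are [row, col] matrices; EBImage operators are
# orientation-agnostic so matrices are passed through without transposition.

um2_to_px <- function(area_um2, um_per_px) area_um2 / um_per_px^2
px_to_um2 <- function(area_px, um_per_px) area_px * um_per_px^2

odd_disc <- function(radius_px) {
  size <- max(3L, 2L * as.integer(round(radius_px)) + 1L)
  EBImage::makeBrush(size, shape = "disc")
}

#' Build the DAPI counterstain mask
#'
#' Marks nuclear (DAPI-positive) pixels: the counterstain channel is smoothed,
#' thresholded by Otsu's method, holes are filled and specks below a small
#' physical area are discarded.
#'
#' @param dapi 8-bit DAPI raster (`[row, col]` matrix, values 0-255).
#' @param um_per_px physical scale, micrometres per pixel.
#' @param smoothing_sigma_um Gaussian smoothing scale before thresholding;
#'   default 0.3 um.
#' @param min_object_um2 connected components smaller than this are removed;
#'   default 2 um^2.
#' @return a logical matrix of the same shape, `TRUE` on nuclear pixels.
#' @export
build_counterstain_mask <- function(dapi, um_per_px,
                                    smoothing_sigma_um = 0.3,
                                    min_object_um2 = 2) {
  stopifnot(is.matrix(dapi), length(dapi) > 0, um_per_px > 0)
  x <- dapi / 255
  if (max(x) <= 0) return(matrix(FALSE, nrow(dapi), ncol(dapi)))
  sigma_px <- max(smoothing_sigma_um / um_per_px, 0.5)
  s <- as.matrix(EBImage::gblur(x, sigma = sigma_px))
  thr <- EBImage::otsu(EBImage::Image(s), range = c(0, max(s)))
  mask <- s > thr
  mask <- as.matrix(EBImage::fillHull(mask)) > 0
  lab <- EBImage::bwlabel(mask)
  if (max(lab) > 0) {
    areas <- tabulate(lab[lab > 0])
    drop <- which(areas < um2_to_px(min_object_um2, um_per_px))
    if (length(drop)) mask[lab %in% drop] <- FALSE
  }
  mask
}

#' Preprocess a fluorescence channel for spot detection
#'
#' The enhancement chain applied before any spot gate: (1) Gaussian
#' smoothing, (2) white top-hat with a disc structuring element that passes
#' spot-scale objects and removes nuclear-scale background, (3) Laplacian
#' sharpening clipped at zero. A flat background maps to (near-)zero and a
#' compact blob keeps its maximum at its centroid.
#'
#' @param raster 8-bit channel (`[row, col]` matrix).
#' @param um_per_px physical scale, micrometres per pixel.
#' @param smoothing_sigma_um Gaussian sigma; default 0.1 um.
#' @param tophat_radius_um structuring-element radius; default 1.0 um, so
#'   single spots and moderate HSR clusters (up to ~2 um diameter) pass
#'   while nuclear-scale background is removed.
#' @return a nonnegative real-valued matrix of the same shape.
#' @export
preprocess_channel <- function(raster, um_per_px,
                               smoothing_sigma_um = 0.1,
                               tophat_radius_um = 1.0) {
  stopifnot(is.matrix(raster), length(raster) > 0, um_per_px > 0)
  x <- raster / 255
  sigma_px <- max(smoothing_sigma_um / um_per_px, 0.5)
  brush <- odd_disc(tophat_radius_um / um_per_px)
  # replicate-pad so the morphology sees no artificial image boundary
  k <- (nrow(brush) - 1L) %/% 2L + 2L
  nr <- nrow(x); nc <- ncol(x)
  xp <- x[c(rep(1L, k), seq_len(nr), rep(nr, k)),
          c(rep(1L, k), seq_len(nc), rep(nc, k))]
  s <- as.matrix(EBImage::gblur(xp, sigma = sigma_px))
  th <- as.matrix(EBImage::whiteTopHat(s, brush))
  lap <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
  sharp <- th - as.matrix(EBImage::filter2(th, lap))
  pmax(sharp[k + seq_len(nr), k + seq_len(nc)], 0)
}

#' Detect FISH spots in one channel
#'
#' After preprocessing, pixels at or above `intensity_frac` times the
#' channel's reference maximum (the 99.9th percentile of positive
#' preprocessed intensities, a robust maximum) are labelled into connected
#' objects; objects below the channel's minimum area are discarded, and
#' objects whose centroids lie closer than the channel's merge distance are
#' merged into a single spot (single-linkage, preserving total signal).
#' Spots are reported in row-major centroid order.
#'
#' @param raster 8-bit channel (`[row, col]` matrix).
#' @param params a [spot_params()] object; see [her2_spot_params()] /
#'   [cep17_spot_params()] for the validated defaults.
#' @param um_per_px physical scale, micrometres per pixel.
#' @param channel `"her2"` or `"cep17"`, recorded on each spot.
#' @param mask optional logical counterstain mask; when supplied, signal
#'   outside nuclei is suppressed before detection.
#' @param preprocessed optional precomputed [preprocess_channel()] output
#'   (skips preprocessing).
#' @return a data.frame with one row per spot: `channel`, `row`, `col`
#'   (intensity-weighted centroid, 1-based pixel coordinates), `area_um2`,
#'   `peak_frac`, `equivalents` (always 1 here; see
#'   [count_hsr_equivalents()]).
#' @export
detect_spots <- function(raster, params, um_per_px,
                         channel = c("her2", "cep17"),
                         mask = NULL, preprocessed = NULL) {
  channel <- match.arg(channel)
  stopifnot(inherits(params, "spot_params"), um_per_px > 0)
  pre <- if (is.null(preprocessed)) preprocess_channel(raster, um_per_px)
         else preprocessed
  if (!is.null(mask)) {
    stopifnot(identical(dim(mask), dim(pre)))
    pre[!mask] <- 0
  }
  empty <- data.frame(channel = character(), row = numeric(), col = numeric(),
                      area_um2 = numeric(), peak_frac = numeric(),
                      equivalents = integer())
  pos <- pre[pre > 1e-9]
  if (length(pos) == 0) return(empty)
  ref <- quantile(pos, 0.999, names = FALSE)
  thr <- params$intensity_frac * ref
  lab <- EBImage::bwlabel(pre >= thr)
  n <- max(lab)
  if (n == 0) return(empty)

  idx <- which(lab > 0)
  l <- lab[idx]
  nr <- nrow(pre)
  rows <- ((idx - 1L) %% nr) + 1L
  cols <- ((idx - 1L) %/% nr) + 1L
  w <- pre[idx]
  wsum <- rowsum(w, l)[, 1]
  cy <- rowsum(rows * w, l)[, 1] / wsum
  cx <- rowsum(cols * w, l)[, 1] / wsum
  area <- px_to_um2(tabulate(l, nbins = n), um_per_px)
  peak <- vapply(split(w, l), max, numeric(1))

  keep <- area >= params$min_area_um2
  if (!any(keep)) return(empty)
  cy <- cy[keep]; cx <- cx[keep]; area <- area[keep]; peak <- peak[keep]

  # merge objects whose centroids are closer than the channel merge distance
  m <- length(area)
  grp <- seq_len(m)
  if (m > 1) {
    d <- dist(cbind(cy, cx)) * um_per_px
    hc <- hclust(d, method = "single")
    grp <- cutree(hc, h = params$min_distance_um - 1e-9)
  }
  agg_area <- rowsum(area, grp)[, 1]
  wgt <- rowsum(area, grp)[, 1]
  mrow <- rowsum(cy * area, grp)[, 1] / wgt
  mcol <- rowsum(cx * area, grp)[, 1] / wgt
  mpeak <- vapply(split(peak, grp), max, numeric(1))

  out <- data.frame(channel = channel, row = mrow, col = mcol,
                    area_um2 = agg_area, peak_frac = mpeak / ref,
                    equivalents = 1L)
  out <- out[order(out$row, out$col), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Convert HSR clusters to spot-equivalent counts by signal area
#'
#' In specimens with homogeneously staining regions (HSR) individual HER2
#' spots cannot be resolved; counting switches to the signal area in the
#' HER2 channel. Objects whose area stays within `hsr_factor` times the
#' reference single-spot area pass through with one equivalent; larger
#' objects are counted as `round(area / ref_area)` equivalents (at least 2).
#'
#' @param spots a spots data.frame from [detect_spots()].
#' @param ref_area_um2 reference area of one resolved spot; when `NULL`, the
#'   median area of non-cluster spots in the same case is used, falling back
#'   to 0.15 um^2 when fewer than 5 isolated spots are available.
#' @param hsr_factor multiple of the reference area above which an object is
#'   treated as a cluster; default 4.
#' @return the spots data.frame with `equivalents` updated; the attribute
#'   `hsr_mode_used` is `TRUE` when any cluster was converted.
#' @export
count_hsr_equivalents <- function(spots, ref_area_um2 = NULL, hsr_factor = 4) {
  stopifnot(hsr_factor > 1)
  if (nrow(spots) == 0) {
    attr(spots, "hsr_mode_used") <- FALSE
    return(spots)
  }
  if (is.null(ref_area_um2)) {
    med <- median(spots$area_um2)
    isolated <- spots$area_um2 <= hsr_factor * med
    ref_area_um2 <- if (sum(isolated) < 5) 0.15 else median(spots$area_um2[isolated])
  }
  stopifnot(ref_area_um2 > 0)
  cluster <- spots$area_um2 > hsr_factor * ref_area_um2
  spots$equivalents <- ifelse(cluster,
                              pmax(2L, as.integer(round(spots$area_um2 / ref_area_um2))),
                              1L)
  attr(spots, "hsr_mode_used") <- any(cluster)
  spots
}
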