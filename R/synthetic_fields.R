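# Ground-truth generator for synthetic FISH fields, cases and cohorts:
# textured elliptical DAPI nuclei, per-nucleus planted HER2/CEP17 spots with
# a separation guarantee (planted count = detectable count), optional HSR
# clusters, optical blur, additive noise, 8-bit quantization applied last.

#' Solve the zero-truncated Poisson rate for a target mean
#'
#' Per-nucleus probe counts are drawn zero-truncated (every tumor nucleus
#' carries at least one copy of HER2 and of chromosome 17); this solves the
#' rate `lambda` such that `lambda / (1 - exp(-lambda))` equals the requested
#' mean, so configured means are honoured exactly.
#'
#' @param mean_count target mean, must exceed 1.
#' @return the zero-truncated Poisson rate.
#' @export
ztpois_rate <- function(mean_count) {
  stopifnot(mean_count > 1)
  uniroot(function(l) l / (1 - exp(-l)) - mean_count,
          interval = c(1e-9, mean_count), tol = 1e-10)$root
}

rztpois <- function(n, lambda) {
  u <- runif(n, min = ppois(0, lambda), max = 1)
  qpois(u, lambda)
}

#' Specify one synthetic FISH field
#'
#' Defaults emulate the study's imaging conditions: 1088 x 880 pixel 8-bit
#' fields holding elliptical nuclei (mean equivalent diameter 9 um) with
#' per-nucleus Poisson signal counts in both channels.
#'
#' @param width_px,height_px image dimensions; defaults 1088 x 880.
#' @param n_nuclei nuclei per field; default 60.
#' @param nucleus_diameter_um mean and sd of the equivalent diameter,
#'   `c(mean, sd)`; default `c(9, 1)` (about 64 um^2, well inside the
#'   12-400 um^2 gates).
#' @param overlap_frac fraction of nuclei planted overlapping a neighbour;
#'   default 0.
#' @param lambda_her2,lambda_cep17 mean per-nucleus true signal counts;
#'   defaults 2 and 2.
#' @param hsr optional HSR specification, `list(frac=, copies=)`: `frac` of
#'   nuclei carry one unresolvable cluster of `copies` HER2 copies.
#' @param background_noise_sd additive Gaussian noise, 8-bit grey levels;
#'   default 3.
#' @param blur_sigma_um optical blur applied to all channels; default 0.1.
#' @param um_per_px physical scale; default 0.16.
#' @param min_one draw counts zero-truncated with the rate adjusted so the
#'   mean still equals the configured lambda; default `TRUE`.
#' @param seed RNG seed.
#' @return an object of class `field_spec`.
#' @export
field_spec <- function(width_px = 1088L, height_px = 880L, n_nuclei = 60L,
                       nucleus_diameter_um = c(9, 1), overlap_frac = 0,
                       lambda_her2 = 2, lambda_cep17 = 2, hsr = NULL,
                       background_noise_sd = 3, blur_sigma_um = 0.1,
                       um_per_px = 0.16, min_one = TRUE, seed = 1L) {
  stopifnot(width_px >= 16, height_px >= 16, n_nuclei >= 0,
            length(nucleus_diameter_um) == 2, nucleus_diameter_um[1] > 0,
            overlap_frac >= 0, overlap_frac <= 1,
            lambda_her2 >= 0, lambda_cep17 >= 0,
            background_noise_sd >= 0, blur_sigma_um >= 0, um_per_px > 0)
  if (!is.null(hsr))
    stopifnot(is.list(hsr), hsr$frac >= 0, hsr$frac <= 1, hsr$copies >= 2)
  structure(list(width_px = as.integer(width_px),
                 height_px = as.integer(height_px),
                 n_nuclei = as.integer(n_nuclei),
                 nucleus_diameter_um = nucleus_diameter_um,
                 overlap_frac = overlap_frac,
                 lambda_her2 = lambda_her2, lambda_cep17 = lambda_cep17,
                 hsr = hsr, background_noise_sd = background_noise_sd,
                 blur_sigma_um = blur_sigma_um, um_per_px = um_per_px,
                 min_one = min_one, seed = as.integer(seed)),
            class = "field_spec")
}

# add isotropic Gaussian blobs to a raster (bbox-limited rendering)
render_blobs <- function(img, rows, cols, amps, sigma_px) {
  ext <- ceiling(4 * sigma_px)
  nr <- nrow(img); nc <- ncol(img)
  for (i in seq_along(rows)) {
    r0 <- max(1L, floor(rows[i] - ext)); r1 <- min(nr, ceiling(rows[i] + ext))
    c0 <- max(1L, floor(cols[i] - ext)); c1 <- min(nc, ceiling(cols[i] + ext))
    rr <- r0:r1; cc <- c0:c1
    g <- exp(-outer((rr - rows[i])^2, (cc - cols[i])^2, "+") / (2 * sigma_px^2))
    img[rr, cc] <- img[rr, cc] + amps[i] * g
  }
  img
}

# sample a point uniformly inside an ellipse eroded by margin_px
point_in_ellipse <- function(cy, cx, a, b, theta, margin_px) {
  ae <- max(a - margin_px, 0.5); be <- max(b - margin_px, 0.5)
  repeat {
    u <- sqrt(runif(1)); phi <- runif(1, 0, 2 * pi)
    px <- ae * u * cos(phi); py <- be * u * sin(phi)
    return(c(row = cy + px * sin(theta) + py * cos(theta),
             col = cx + px * cos(theta) - py * sin(theta)))
  }
}

#' Generate one synthetic FISH field with ground truth
#'
#' Renders the three channels: textured ellipses in DAPI, Gaussian blobs at
#' planted in-nucleus positions in the HER2 and CEP17 channels. Same-channel
#' spots are kept at least 1.2 times the channel merge distance apart
#' (field-wide), so the planted count equals the detectable count. HSR
#' nuclei render one tight cluster carrying the specified copy number.
#' Quantization to 8 bits happens last, after blur and noise.
#'
#' @param spec a [field_spec()].
#' @return a list with `image` (a [calibrated_image()]) and `truth`: the
#'   nucleus label raster, a per-nucleus data.frame (`id`, `row`, `col`,
#'   true `her2` / `cep17` counts, `hsr` flag), a planted-spot coordinate
#'   data.frame, the planted field `ratio` and `category`.
#' @export
generate_field <- function(spec) {
  stopifnot(inherits(spec, "field_spec"))
  set.seed(spec$seed)
  upp <- spec$um_per_px
  nr <- spec$height_px; nc <- spec$width_px
  dapi <- matrix(0, nr, nc); orange <- matrix(0, nr, nc); green <- matrix(0, nr, nc)
  labels <- matrix(0L, nr, nc)

  n <- spec$n_nuclei
  if (n > 0) {
    dia_px <- pmax(rnorm(n, spec$nucleus_diameter_um[1],
                         spec$nucleus_diameter_um[2]), 3 * upp) / upp
    elong <- runif(n, 1, 1.25)
    a <- dia_px / 2 * elong
    b <- dia_px / 2 / elong
    theta <- runif(n, 0, pi)
    margin <- max(a) + 3

    if (nr - 2 * margin < 1 || nc - 2 * margin < 1)
      stop("infeasible packing: nuclei too large for the field", call. = FALSE)
    n_overlap <- round(n * spec$overlap_frac)
    cy <- numeric(0); cx <- numeric(0)
    tries <- 0L
    while (length(cy) < n - n_overlap) {
      yy <- runif(1, margin, nr - margin)
      xx <- runif(1, margin, nc - margin)
      i <- length(cy) + 1L
      sep_ok <- length(cy) == 0 ||
        all(sqrt((cy - yy)^2 + (cx - xx)^2) >
              1.05 * (pmax(a[seq_along(cy)], b[seq_along(cy)]) + max(a[i], b[i])))
      if (sep_ok) { cy <- c(cy, yy); cx <- c(cx, xx) }
      tries <- tries + 1L
      if (tries > 4000L * n)
        stop("infeasible packing: cannot place ", n, " nuclei", call. = FALSE)
    }
    while (length(cy) < n) {       # overlapping nuclei attach to a neighbour
      j <- sample.int(length(cy), 1)
      i <- length(cy) + 1L
      ang <- runif(1, 0, 2 * pi)
      d <- 0.8 * (max(a[j], b[j]) + max(a[i], b[i]))
      yy <- min(max(cy[j] + d * sin(ang), margin), nr - margin)
      xx <- min(max(cx[j] + d * cos(ang), margin), nc - margin)
      cy <- c(cy, yy); cx <- c(cx, xx)
    }

    # rasterize ellipses; contested pixels go to the nearer nucleus
    metric <- matrix(Inf, nr, nc)
    base <- matrix(0, nr, nc)
    for (i in seq_len(n)) {
      ext <- ceiling(max(a[i], b[i])) + 1L
      rr <- max(1L, floor(cy[i] - ext)):min(nr, ceiling(cy[i] + ext))
      cc <- max(1L, floor(cx[i] - ext)):min(nc, ceiling(cx[i] + ext))
      dy <- rr - cy[i]; dx <- cc - cx[i]
      u <- outer(dy, dx, function(y, x) x * cos(theta[i]) + y * sin(theta[i]))
      v <- outer(dy, dx, function(y, x) -x * sin(theta[i]) + y * cos(theta[i]))
      m <- (u / a[i])^2 + (v / b[i])^2
      inside <- m <= 1
      sub_metric <- metric[rr, cc]
      take <- inside & (m < sub_metric)
      sub_lab <- labels[rr, cc]
      sub_lab[take] <- i
      labels[rr, cc] <- sub_lab
      sub_metric[take] <- m[take]
      metric[rr, cc] <- sub_metric
      amp <- rnorm(1, 150, 12)
      sub <- base[rr, cc]
      tex <- amp * (1 - 0.25 * m[inside]) + rnorm(sum(inside), 0, 8)
      sub[inside] <- pmax(sub[inside], tex)
      base[rr, cc] <- sub
    }
    dapi <- base

    # per-nucleus true counts
    draw <- function(lambda, k) {
      if (lambda <= 0) return(integer(k))
      if (spec$min_one) rztpois(k, if (lambda > 1) ztpois_rate(lambda) else lambda)
      else rpois(k, lambda)
    }
    n_h <- draw(spec$lambda_her2, n)
    n_c <- draw(spec$lambda_cep17, n)
    is_hsr <- rep(FALSE, n)
    if (!is.null(spec$hsr) && spec$hsr$frac > 0) {
      is_hsr[sample.int(n, round(spec$hsr$frac * n))] <- TRUE
      n_h[is_hsr] <- as.integer(spec$hsr$copies)
    }

    sep_h <- 1.2 * 0.8 / upp    # px; 1.2 x HER2 merge distance
    sep_c <- 1.2 * 0.5 / upp
    spot_sigma <- 0.12 / upp
    single_area_um2 <- 0.15

    sp_rows <- list()
    placed_h <- matrix(numeric(0), ncol = 2)
    placed_c <- matrix(numeric(0), ncol = 2)
    place_spots <- function(k, i, placed, sep) {
      pts <- matrix(numeric(0), ncol = 2)
      for (s in seq_len(k)) {
        for (t in seq_len(300)) {
          p <- point_in_ellipse(cy[i], cx[i], a[i], b[i], theta[i],
                                margin_px = spot_sigma * 2 + 1)
          allp <- rbind(placed, pts)
          if (nrow(allp) == 0 ||
              all(sqrt((allp[, 1] - p[1])^2 + (allp[, 2] - p[2])^2) >= sep)) {
            pts <- rbind(pts, p)
            break
          }
        }
      }
      pts
    }

    for (i in seq_len(n)) {
      if (is_hsr[i]) {
        ctr <- point_in_ellipse(cy[i], cx[i], a[i], b[i], theta[i], margin_px = 3)
        rad <- sqrt(n_h[i] * single_area_um2 / pi) / upp
        rr <- max(1L, floor(ctr[1] - rad - 1)):min(nr, ceiling(ctr[1] + rad + 1))
        cc <- max(1L, floor(ctr[2] - rad - 1)):min(nc, ceiling(ctr[2] + rad + 1))
        disc <- outer((rr - ctr[1])^2, (cc - ctr[2])^2, "+") <= rad^2
        sub <- orange[rr, cc]
        sub[disc] <- pmax(sub[disc], 235)
        orange[rr, cc] <- sub
        sp_rows[[length(sp_rows) + 1L]] <-
          data.frame(channel = "her2", row = ctr[1], col = ctr[2],
                     nucleus = i, copies = n_h[i], cluster = TRUE)
      } else if (n_h[i] > 0) {
        pts <- place_spots(n_h[i], i, placed_h, sep_h)
        n_h[i] <- nrow(pts)                  # truth = what was actually placed
        if (nrow(pts)) {
          placed_h <- rbind(placed_h, pts)
          orange <- render_blobs(orange, pts[, 1], pts[, 2],
                                 runif(nrow(pts), 180, 230), spot_sigma)
          sp_rows[[length(sp_rows) + 1L]] <-
            data.frame(channel = "her2", row = pts[, 1], col = pts[, 2],
                       nucleus = i, copies = 1L, cluster = FALSE)
        }
      }
      if (n_c[i] > 0) {
        pts <- place_spots(n_c[i], i, placed_c, sep_c)
        n_c[i] <- nrow(pts)
        if (nrow(pts)) {
          placed_c <- rbind(placed_c, pts)
          green <- render_blobs(green, pts[, 1], pts[, 2],
                                runif(nrow(pts), 180, 230), spot_sigma * 1.4)
          sp_rows[[length(sp_rows) + 1L]] <-
            data.frame(channel = "cep17", row = pts[, 1], col = pts[, 2],
                       nucleus = i, copies = 1L, cluster = FALSE)
        }
      }
    }

    spots <- if (length(sp_rows)) do.call(rbind, sp_rows) else NULL
    nuclei <- data.frame(id = seq_len(n), row = cy, col = cx,
                         her2 = n_h, cep17 = n_c, hsr = is_hsr)
  } else {
    spots <- NULL
    nuclei <- data.frame(id = integer(), row = numeric(), col = numeric(),
                         her2 = integer(), cep17 = integer(), hsr = logical())
  }
  if (is.null(spots))
    spots <- data.frame(channel = character(), row = numeric(),
                        col = numeric(), nucleus = integer(),
                        copies = integer(), cluster = logical())

  quantize <- function(m) {
    if (spec$blur_sigma_um > 0)
      m <- as.matrix(EBImage::gblur(m, sigma = max(spec$blur_sigma_um / upp, 0.5)))
    if (spec$background_noise_sd > 0)
      m <- m + rnorm(length(m), 0, spec$background_noise_sd)
    matrix(as.integer(pmin(pmax(round(m), 0), 255)), nrow(m), ncol(m))
  }
  img <- calibrated_image(quantize(dapi), quantize(orange), quantize(green), upp)

  th <- sum(nuclei$her2); tc <- sum(nuclei$cep17)
  ratio <- if (tc > 0) th / tc else NA_real_
  category <- if (is.na(ratio)) NA_character_ else classify_ratio(ratio)$category
  list(image = img,
       truth = list(labels = labels, nuclei = nuclei, spots = spots,
                    total_her2 = th, total_cep17 = tc,
                    ratio = ratio, category = category))
}

#' Generate a multi-field synthetic case
#'
#' Fields are generated independently from seeds derived from the case seed;
#' the case ground truth aggregates the field truths.
#'
#' @param spec a [field_spec()]; its `seed` is the case seed.
#' @param n_fields number of fields, 1-20 (the study imaged 5-10 fields per
#'   case); default 5.
#' @return a list with `fields` (list of [generate_field()] outputs) and
#'   `truth` (`total_her2`, `total_cep17`, `ratio`, `category`).
#' @export
generate_case <- function(spec, n_fields = 5L) {
  stopifnot(inherits(spec, "field_spec"), n_fields >= 1, n_fields <= 20)
  fields <- lapply(seq_len(n_fields), function(i) {
    fs <- spec
    fs$seed <- as.integer((spec$seed + 7919L * i) %% .Machine$integer.max)
    generate_field(fs)
  })
  th <- sum(vapply(fields, function(f) f$truth$total_her2, numeric(1)))
  tc <- sum(vapply(fields, function(f) f$truth$total_cep17, numeric(1)))
  ratio <- if (tc > 0) th / tc else NA_real_
  category <- if (is.na(ratio)) NA_character_ else classify_ratio(ratio)$category
  list(fields = fields,
       truth = list(total_her2 = th, total_cep17 = tc,
                    ratio = ratio, category = category))
}

#' Generate a labeled synthetic cohort
#'
#' Profile presets mirror the validation cohort design: `nonamplified`
#' (per-nucleus means 2/2, ratio about 1), `amplified` (CEP17 mean 2, HSR
#' clusters of copy number 12 in 80% of nuclei, HER2 mean 8 elsewhere),
#' `amplified_no_hsr` (means 8/2, no clusters), and `equivocal` (means 4/2;
#' cases are redrawn until the planted ratio lies inside \[1.8, 2.2\], so the
#' planted category is equivocal by construction).
#'
#' @param profile one of `"nonamplified"`, `"amplified"`,
#'   `"amplified_no_hsr"`, `"equivocal"`.
#' @param n_cases number of cases.
#' @param seed cohort seed; per-case seeds are derived from it.
#' @param n_fields fields per case; default 1 (60 nuclei per case).
#' @param n_nuclei nuclei per field; default 60.
#' @param ... further overrides passed to [field_spec()].
#' @return a list of cases, each a [generate_case()] result plus `case_id`
#'   and `profile`.
#' @export
generate_cohort <- function(profile = c("nonamplified", "amplified",
                                        "amplified_no_hsr", "equivocal"),
                            n_cases, seed = 1L, n_fields = 1L,
                            n_nuclei = 60L, ...) {
  profile <- match.arg(profile)
  stopifnot(n_cases >= 1)
  preset <- switch(profile,
    nonamplified     = list(lambda_her2 = 2, lambda_cep17 = 2, hsr = NULL),
    amplified        = list(lambda_her2 = 8, lambda_cep17 = 2,
                            hsr = list(frac = 0.8, copies = 12)),
    amplified_no_hsr = list(lambda_her2 = 8, lambda_cep17 = 2, hsr = NULL),
    equivocal        = list(lambda_her2 = 4, lambda_cep17 = 2, hsr = NULL))
  lapply(seq_len(n_cases), function(k) {
    for (attempt in 0:19) {
      case_seed <- as.integer((seed + 104729L * k + 101L * attempt) %%
                                .Machine$integer.max)
      spec <- do.call(field_spec,
                      modifyList(c(preset, list(n_nuclei = n_nuclei,
                                                seed = case_seed)),
                                 list(...)))
      cs <- generate_case(spec, n_fields)
      ok <- switch(profile,
        equivocal = !is.na(cs$truth$ratio) &&
          cs$truth$ratio >= 1.8 && cs$truth$ratio <= 2.2,
        nonamplified = identical(cs$truth$category, "nonamplified"),
        identical(cs$truth$category, "amplified"))
      if (ok) break
    }
    if (!ok) stop("could not realise profile '", profile, "' for case ", k,
                  call. = FALSE)
    c(cs, list(case_id = sprintf("%s_%03d", profile, k), profile = profile))
  })
}
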