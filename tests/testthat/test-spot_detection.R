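upp <- 0.16

test_that("counterstain mask recovers discs and ignores blank images", {
  expect_equal(sum(build_counterstain_mask(matrix(0L, 100, 100), upp)), 0)

  one <- disc_image(200, 200, 100, 100, 20, 200)
  m <- build_counterstain_mask(one, upp)
  expect_lt(abs(sum(m) - pi * 20^2) / (pi * 20^2), 0.10)

  two <- disc_image(200, 200, 60, 60, 15, 200) +
         disc_image(200, 200, 140, 140, 15, 200)
  m2 <- build_counterstain_mask(two, upp)
  expect_equal(max(EBImage::bwlabel(m2)), 2)
})

test_that("preprocessing flattens backgrounds and preserves blob peaks", {
  expect_lt(max(preprocess_channel(matrix(137L, 64, 64), upp)), 1e-6)

  blob <- gauss_blob_image(64, 64, 30.0, 42.0, sigma_px = 1.5)
  p <- preprocess_channel(blob, upp)
  peak <- which(p == max(p), arr.ind = TRUE)[1, ]
  expect_equal(unname(peak), c(30, 42))
  expect_true(all(p >= 0))

  # a field-scale illumination gradient must be suppressed below the blob
  grad <- matrix(rep(seq(0, 120, length.out = 256), each = 256), 256, 256)
  blob2 <- gauss_blob_image(256, 256, 128, 128, sigma_px = 1.5)
  both <- matrix(as.integer(pmin(round(grad) + blob2, 255)), 256, 256)
  pb <- preprocess_channel(both, upp)
  far <- pb[, c(1:80, 176:256)]          # gradient-only region
  expect_lt(max(far), 0.10 * max(pb))
})

test_that("spot detection applies the area, distance and intensity gates", {
  blank <- matrix(0L, 64, 64)
  expect_equal(nrow(detect_spots(blank, her2_spot_params(), upp, "her2")), 0)

  # merge boundary at the HER2 distance gate (fine calibration)
  fine <- 0.02
  sepcount <- function(sep_um) {
    W <- round(3.2 / fine); H <- round(2.0 / fine)
    im <- gauss_blob_image(H, W, rep(H / 2, 2),
                           c(W / 4, W / 4 + sep_um / fine),
                           sigma_px = 0.05 / fine, amp = 230)
    nrow(detect_spots(im, her2_spot_params(), fine, "her2"))
  }
  expect_equal(sepcount(0.79), 1L)
  expect_equal(sepcount(0.80), 2L)
  expect_equal(sepcount(0.81), 2L)

  # an object below the HER2 area gate yields nothing; CEP17 area gate binds
  tiny <- disc_image(100, 100, 50, 50, 0.6)   # ~1 px at 0.16 um/px
  expect_equal(nrow(detect_spots(tiny, her2_spot_params(), upp, "her2")), 0)

  # 12 well-separated blobs, counted and ordered deterministically
  g <- expand.grid(r = seq(30, 220, 60), c = seq(30, 220, 48))[1:12, ]
  im12 <- gauss_blob_image(256, 256, g$r, g$c, sigma_px = 1.2, amp = 210)
  sp <- detect_spots(im12, her2_spot_params(), upp, "her2")
  expect_equal(nrow(sp), 12)
  expect_true(!is.unsorted(sp$row))
  pre <- preprocess_channel(im12, upp)
  expect_equal(nrow(sp), oracle_spot_count(pre, her2_spot_params(), upp))
})

test_that("detected counts equal the brute-force oracle on random fields", {
  set.seed(71)
  for (i in 1:40) {
    H <- sample(48:128, 1); W <- sample(48:128, 1)
    n <- sample(0:20, 1)
    im <- if (n == 0) matrix(0L, H, W) else
      gauss_blob_image(H, W, runif(n, 6, H - 6), runif(n, 6, W - 6),
                       sigma_px = runif(1, 0.8, 1.6),
                       amp = runif(n, 140, 235))
    for (params in list(her2_spot_params(), cep17_spot_params())) {
      pre <- preprocess_channel(im, upp)
      got <- nrow(detect_spots(im, params, upp,
                               if (params$min_distance_um == 0.8) "her2" else "cep17",
                               preprocessed = pre))
      expect_equal(got, oracle_spot_count(pre, params, upp),
                   label = sprintf("instance %d (%dx%d, %d blobs)", i, H, W, n))
    }
  }
})

test_that("relaxing gates never decreases the spot count", {
  set.seed(5)
  im <- gauss_blob_image(128, 128, runif(10, 10, 118), runif(10, 10, 118),
                         sigma_px = 1.2, amp = runif(10, 120, 235))
  base <- nrow(detect_spots(im, spot_params(0.05, 0.8, 0.33), upp, "her2"))
  for (frac in c(0.25, 0.15)) {
    n <- nrow(detect_spots(im, spot_params(0.05, 0.8, frac), upp, "her2"))
    expect_gte(n, base)
    base <- n
  }
  a_strict <- nrow(detect_spots(im, spot_params(0.20, 0.8, 0.33), upp, "her2"))
  a_loose <- nrow(detect_spots(im, spot_params(0.02, 0.8, 0.33), upp, "her2"))
  expect_gte(a_loose, a_strict)
})

test_that("integer shifts translate centroids exactly", {
  im <- gauss_blob_image(96, 96, c(30, 60), c(40, 70), sigma_px = 1.3)
  sp0 <- detect_spots(im, her2_spot_params(), upp, "her2")
  shifted <- matrix(0L, 96, 96)
  shifted[6:96, 4:96] <- im[1:91, 1:93]
  sp1 <- detect_spots(shifted, her2_spot_params(), upp, "her2")
  expect_equal(sp1$row, sp0$row + 5, tolerance = 1e-6)
  expect_equal(sp1$col, sp0$col + 3, tolerance = 1e-6)
})

test_that("HSR area mode converts clusters and conserves at least one count each", {
  sp <- data.frame(channel = "her2", row = 1:6, col = 1,
                   area_um2 = c(0.15, 0.14, 0.16, 0.15, 0.13, 1.5),
                   peak_frac = 1, equivalents = 1L)
  out <- count_hsr_equivalents(sp, hsr_factor = 4)
  expect_true(attr(out, "hsr_mode_used"))
  expect_equal(out$equivalents[1:5], rep(1L, 5))
  expect_equal(out$equivalents[6], 10L)      # 1.5 / median(0.15)
  expect_gte(sum(out$equivalents), nrow(sp))

  # explicit reference area: area equal to it stays a single spot
  one <- data.frame(channel = "her2", row = 1, col = 1, area_um2 = 0.15,
                    peak_frac = 1, equivalents = 1L)
  expect_equal(count_hsr_equivalents(one, ref_area_um2 = 0.15)$equivalents, 1L)
  expect_false(attr(count_hsr_equivalents(one, ref_area_um2 = 0.15),
                    "hsr_mode_used"))

  # all small objects: untouched, no flag
  small <- data.frame(channel = "her2", row = 1:3, col = 1,
                      area_um2 = c(0.1, 0.12, 0.14), peak_frac = 1,
                      equivalents = 1L)
  res <- count_hsr_equivalents(small, ref_area_um2 = 0.15, hsr_factor = 4)
  expect_equal(res$equivalents, rep(1L, 3))
  expect_false(attr(res, "hsr_mode_used"))
})
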