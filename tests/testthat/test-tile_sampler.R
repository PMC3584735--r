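test_that("tile packing fills a full mask to the packing bound", {
  m <- matrix(TRUE, 880, 1088)
  tl <- place_tiles(m, 71)
  expect_equal(nrow(tl), floor(1088 / 71) * floor(880 / 71))  # 180
  expect_true(all(tl$coverage == 1))
})

test_that("a single on-lattice solid square yields exactly one full tile", {
  m <- matrix(FALSE, 300, 300)
  m[97:167, 81:151] <- TRUE            # origin on the stride-8 lattice
  tl <- place_tiles(m, 71)
  full <- tl[tl$coverage == 1, ]
  expect_equal(nrow(full), 1)
  expect_equal(c(full$row, full$col), c(97, 81))
  expect_equal(nrow(place_tiles(matrix(FALSE, 200, 200), 71)), 0)
  expect_error(place_tiles(matrix(TRUE, 50, 50), 71), "exceeds")
})

test_that("placed tiles never overlap and greedy beats the naive grid", {
  set.seed(31)
  for (rep in 1:5) {
    m <- matrix(FALSE, 140, 160)
    for (k in 1:6) {
      r <- sample(20:120, 1); c <- sample(20:140, 1)
      m[pmax(1, r - 14):pmin(140, r + 14), pmax(1, c - 14):pmin(160, c + 14)] <- TRUE
    }
    tl <- place_tiles(m, 24)
    if (nrow(tl) > 1) {
      for (i in 1:(nrow(tl) - 1)) for (j in (i + 1):nrow(tl)) {
        expect_true(abs(tl$row[i] - tl$row[j]) >= 24 ||
                    abs(tl$col[i] - tl$col[j]) >= 24)
      }
    }
    # greedy covered mask pixels >= naive exact-tiling grid on the same mask
    naive <- 0
    for (r in seq(1, 140 - 23, by = 24)) for (c in seq(1, 160 - 23, by = 24))
      naive <- naive + sum(m[r:(r + 23), c:(c + 23)])
    expect_gte(sum(tl$coverage) * 24^2, naive)
  }
})

test_that("spots are assigned to half-open tile boxes without double counting", {
  tiles <- data.frame(row = c(1, 1), col = c(1, 72), side_px = 71,
                      coverage = 1, her2_count = 0L, cep17_count = 0L,
                      accepted = NA)
  spots <- data.frame(
    channel = c("her2", "her2", "cep17", "her2"),
    row = c(1, 10, 40, 200), col = c(1, 72, 100, 200),
    area_um2 = 0.1, peak_frac = 1, equivalents = c(1L, 2L, 1L, 1L))
  out <- fill_tiles(tiles, spots)
  expect_equal(out$her2_count, c(1L, 2L))   # corner spot in its own tile only
  expect_equal(out$cep17_count, c(0L, 1L))
  expect_equal(sum(out$her2_count) + sum(out$cep17_count), 4L)  # far spot uncounted

  none <- fill_tiles(tiles, spots[0, ])
  expect_true(all(none$her2_count == 0L & none$cep17_count == 0L))
})

test_that("tile rejection enforces the coverage and signal rules", {
  tiles <- data.frame(
    row = 1:4, col = 1, side_px = 71,
    coverage = c(0.39, 0.80, 0.40, 0.95),
    her2_count = c(5L, 1L, 1L, 0L),
    cep17_count = c(5L, 0L, 1L, 1L),
    accepted = NA)
  acc <- reject_tiles(tiles, tile_params())
  # 0.39 coverage fails; 1+0 signals fail; 0.40 with 1+1 passes; 0+1 fails
  expect_equal(acc$row, 3L)
  expect_true(all(acc$accepted))
})

test_that("tile-mode case results apply the 32-tile rule and classify", {
  rej <- tile_case_result(make_tiles(31, 2, 2))
  expect_true("case_rejected" %in% rej$qc)
  expect_true(is.na(rej$category))

  amp <- tile_case_result(make_tiles(40, 10, 2))
  expect_equal(amp$ratio, 5.0)
  expect_identical(amp$category, "amplified")

  non <- tile_case_result(make_tiles(32, 2, 2))
  expect_equal(non$ratio, 1.0)
  expect_identical(non$category, "nonamplified")
})

test_that("a dense mask with ample signal accepts close to the packing bound", {
  set.seed(8)
  H <- 360; W <- 420
  mask <- matrix(TRUE, H, W)
  holes <- cbind(sample(20:340, 25), sample(20:400, 25))
  for (i in 1:25)
    mask[(holes[i, 1] - 4):(holes[i, 1] + 4),
         (holes[i, 2] - 4):(holes[i, 2] + 4)] <- FALSE
  n_sp <- 900
  spots <- data.frame(channel = sample(c("her2", "cep17"), n_sp, TRUE),
                      row = runif(n_sp, 1, H), col = runif(n_sp, 1, W),
                      area_um2 = 0.1, peak_frac = 1, equivalents = 1L)
  tl <- reject_tiles(fill_tiles(place_tiles(mask, 71), spots), tile_params())
  bound <- floor(H / 71) * floor(W / 71)
  expect_gte(nrow(tl), 0.8 * bound)
})

test_that("tile mode recovers planted case ratios end to end", {
  hits <- 0L; total <- 0L
  for (r in c(1, 3, 5)) {
    for (s in 1:2) {
      spec <- field_spec(width_px = 820, height_px = 780, n_nuclei = 50,
                         lambda_her2 = 2 * r, lambda_cep17 = 2,
                         seed = 1000L * r + s)
      cs <- generate_case(spec, n_fields = 5)
      got <- analyze_case(cs, mode = "tile")$result$ratio
      total <- total + 1L
      if (abs(got - cs$truth$ratio) <= 0.3) hits <- hits + 1L
    }
  }
  expect_gte(hits / total, 5 / 6)
})
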