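upp <- 0.16

# analyze one generated field in nuclei mode and return the case state
field_state <- function(f, min_nuclei = 5L) {
  ana <- analyze_field(f$image, mode = "nuclei")
  case_state(ana$nset, ana$spots, nucleus_params(min_nuclei = min_nuclei))
}

test_that("segmentation recovers planted non-overlapping nuclei", {
  expect_length(segment_nuclei(matrix(0L, 50, 50),
                               matrix(FALSE, 50, 50), upp)$nuclei$id, 0)

  f <- generate_field(small_field(301, n_nuclei = 10))
  ana <- analyze_field(f$image, mode = "nuclei")
  expect_equal(nrow(ana$nset$nuclei), 10)

  # recall and precision against planted centers
  nuc <- ana$nset$nuclei
  tr <- f$truth$nuclei
  d <- sqrt(outer(nuc$row, tr$row, "-")^2 + outer(nuc$col, tr$col, "-")^2) * upp
  matched <- sum(apply(d, 2, min) < 3)
  expect_gte(matched / nrow(tr), 0.95)
  expect_gte(matched / nrow(nuc), 0.95)
})

test_that("touching nuclei are split by the distance-transform watershed", {
  # two ellipses overlapping ~20% of area, built directly as a mask
  m <- matrix(FALSE, 200, 200)
  rr <- row(m); cc <- col(m)
  c1 <- c(100, 80); c2 <- c(100, 127)    # 27 px apart, radii ~28
  m[((rr - c1[1]) / 28)^2 + ((cc - c1[2]) / 26)^2 <= 1] <- TRUE
  m[((rr - c2[1]) / 28)^2 + ((cc - c2[2]) / 26)^2 <= 1] <- TRUE
  nset <- segment_nuclei(matrix(0L, 200, 200), m, upp)
  expect_equal(nrow(nset$nuclei), 2)
  got <- nset$nuclei[order(nset$nuclei$col), ]
  expect_lt(sqrt(sum((c(got$row[1], got$col[1]) - c1)^2)) * upp, 2)
  expect_lt(sqrt(sum((c(got$row[2], got$col[2]) - c2)^2)) * upp, 2)
})

test_that("nucleus gates enforce area, roundness and signal quality", {
  nuc <- make_nuclei(5, 0, 0, status = "presegmented")
  nuc$area_um2 <- c(11, 401, 100, 100, 100)
  nuc$her2_count <- c(2L, 2L, 3L, 2L, 2L)
  nuc$cep17_count <- c(2L, 2L, 0L, 2L, 2L)
  nuc$roundness <- c(0.9, 0.9, 0.9, 0.4, 0.9)
  labels <- matrix(0L, 40, 40)
  for (i in 1:5) labels[i * 6, i * 6] <- i
  nuc$row <- nuc$col <- seq(6, 30, by = 6)
  nset <- structure(list(labels = labels, nuclei = nuc, um_per_px = upp),
                    class = "nucleus_set")
  spots <- do.call(rbind, lapply(1:5, function(i) data.frame(
    channel = rep(c("her2", "cep17"), c(nuc$her2_count[i], nuc$cep17_count[i])),
    row = i * 6, col = i * 6, area_um2 = 0.1, peak_frac = 1, equivalents = 1L)))
  out <- gate_nuclei(nset, spots, nucleus_params())$nuclei
  # too small, too large, missing CEP17, poor roundness all stay presegmented
  expect_equal(out$status, c(rep("presegmented", 4), "accepted"))
})

test_that("nuclei-mode case results enforce the minimum-nuclei rule", {
  rej <- nuclei_case_result(make_nuclei(19, 3, 2))
  expect_true("case_rejected" %in% rej$qc)

  amp <- nuclei_case_result(make_nuclei(25, 6, 2))
  expect_equal(amp$ratio, 3.0)
  expect_identical(amp$category, "amplified")

  eq <- nuclei_case_result(make_nuclei(60, 2, 1))
  expect_equal(eq$ratio, 2.0)
  expect_identical(eq$category, "equivocal")
  expect_true(eq$eligible)
})

test_that("delete and select edits update the ratio and are idempotent", {
  f <- generate_field(small_field(302, lambda_her2 = 4))
  st <- field_state(f)
  acc_ids <- st$nuclei$id[st$nuclei$status == "accepted"]
  expect_gte(length(acc_ids), 5)

  id <- acc_ids[which.max(st$nuclei$her2_count[match(acc_ids, st$nuclei$id)])]
  st2 <- apply_edit(st, edit_op("delete", id))
  keep <- st$nuclei[st$nuclei$id != id & st$nuclei$status == "accepted", ]
  expect_equal(st2$result$ratio,
               sum(keep$her2_count) / sum(keep$cep17_count))

  # no-ops: delete a deleted nucleus, select an accepted nucleus
  expect_equal(apply_edit(st2, edit_op("delete", id))$nuclei,
               st2$nuclei)
  sel_id <- setdiff(acc_ids, id)[1]
  expect_equal(apply_edit(st2, edit_op("select", sel_id))$nuclei,
               st2$nuclei)

  # promoting a presegmented nucleus adds its counts
  pre_ids <- st$nuclei$id[st$nuclei$status == "presegmented"]
  if (length(pre_ids)) {
    st3 <- apply_edit(st, edit_op("select", pre_ids[1]))
    expect_identical(st3$nuclei$status[st3$nuclei$id == pre_ids[1]], "accepted")
    expect_equal(st3$result$n_units, st$result$n_units + 1L)
  }
})

test_that("add is gate-exempt and add-then-delete restores the ratio", {
  f <- generate_field(small_field(303))
  st <- field_state(f)
  r0 <- st$result$ratio
  # a free-space polygon far from any nucleus still becomes user_added
  corner <- cbind(c(8, 8, 26, 26), c(8, 26, 26, 8))
  free <- all(st$labels[8:26, 8:26] == 0L)
  st2 <- apply_edit(st, edit_op("add", geometry = corner))
  new_id <- max(st2$nuclei$id)
  expect_identical(st2$nuclei$status[st2$nuclei$id == new_id], "user_added")
  if (free) expect_equal(st2$result$n_units, st$result$n_units + 1L)
  st3 <- apply_edit(st2, edit_op("delete", new_id))
  expect_equal(st3$result$ratio, r0)
})

test_that("split and merge conserve spot counts and keep regions disjoint", {
  f <- generate_field(small_field(304, lambda_her2 = 3))
  st <- field_state(f)
  acc <- st$nuclei[st$nuclei$status == "accepted", ]
  d <- as.matrix(dist(acc[, c("row", "col")])); diag(d) <- Inf
  ij <- which(d == min(d), arr.ind = TRUE)[1, ]
  ids <- acc$id[ij]
  before <- sum(acc$her2_count[ij] + acc$cep17_count[ij])

  stm <- apply_edit(st, edit_op("merge", ids))
  mrow <- stm$nuclei[stm$nuclei$id == min(ids), ]
  expect_equal(mrow$her2_count + mrow$cep17_count, before)

  mid <- colMeans(acc[ij, c("row", "col")])
  v <- unlist(acc[ij[2], c("row", "col")] - acc[ij[1], c("row", "col")])
  perp <- c(-v[2], v[1]) / sqrt(sum(v^2))
  line <- rbind(mid + 80 * perp, mid - 80 * perp)
  sts <- apply_edit(stm, edit_op("split", min(ids), geometry = line))
  new_ids <- setdiff(sts$nuclei$id, stm$nuclei$id)
  expect_gte(length(new_ids), 2)
  after <- sum(sts$nuclei$her2_count[sts$nuclei$id %in% new_ids] +
               sts$nuclei$cep17_count[sts$nuclei$id %in% new_ids])
  expect_equal(after, before)

  # label raster stays a partition: every labelled pixel maps to a live id
  expect_true(all(unique(sts$labels[sts$labels > 0]) %in% sts$nuclei$id))
})

test_that("invalid edits fail loudly and leave the state unchanged", {
  f <- generate_field(small_field(305))
  st <- field_state(f)
  expect_error(apply_edit(st, edit_op("select", 999L)), "unknown")
  expect_error(apply_edit(st, edit_op("delete", 999L)), "unknown")
  expect_error(edit_op("merge", 1L), "two")
  expect_error(edit_op("add", geometry = rbind(c(1, 1), c(2, 2))), "polygon")
  expect_error(apply_edit(st, edit_op(
    "add", geometry = rbind(c(-40, -40), c(-40, -20), c(-20, -20)))),
    "outside")
  # a polyline that misses the region cannot split it
  id <- st$nuclei$id[1]
  expect_error(apply_edit(st, edit_op("split", id,
    geometry = rbind(c(1, 1), c(1, 30)))), "partition")
})

test_that("nuclei mode recovers the planted ratio on a full-scale field", {
  spec <- field_spec(n_nuclei = 60, lambda_her2 = 6, lambda_cep17 = 2,
                     seed = 306)
  f <- generate_field(spec)
  res <- nuclei_case_result(analyze_field(f$image, mode = "nuclei")$nset)
  expect_lt(abs(res$ratio - f$truth$ratio), 0.2)
  expect_identical(res$category, f$truth$category)
})
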