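# The nuclei-sampling classifier: DAPI nucleus segmentation with
# distance-transform watershed splitting of touching nuclei, gating by
# area/roundness/signal quality, the five human-correction edit operations
# (add / select / delete / split / merge) with automatic ratio updates, and
# the nuclei-mode case result.

# shape descriptors of one pixel region given its linear indices
region_stats <- function(idx, dims, um_per_px) {
  nr <- dims[1]
  rows <- ((idx - 1L) %% nr) + 1L
  cols <- ((idx - 1L) %/% nr) + 1L
  rr <- range(rows); cc <- range(cols)
  sub <- matrix(0L, rr[2] - rr[1] + 3L, cc[2] - cc[1] + 3L)
  sub[cbind(rows - rr[1] + 2L, cols - cc[1] + 2L)] <- 1L
  sh <- EBImage::computeFeatures.shape(sub)
  perim <- sh[1, "s.perimeter"]
  area_um2 <- length(idx) * um_per_px^2
  roundness <- if (perim > 0) min(1, 4 * pi * length(idx) / perim^2) else 1
  list(area_um2 = area_um2, roundness = roundness,
       row = mean(rows), col = mean(cols),
       border = rr[1] == 1L || cc[1] == 1L || rr[2] == dims[1] || cc[2] == dims[2])
}

# solidity = area / convex hull area, used as the touching-nuclei trigger
region_solidity <- function(idx, nr) {
  rows <- ((idx - 1L) %% nr) + 1L
  cols <- ((idx - 1L) %/% nr) + 1L
  if (length(idx) < 4) return(1)
  h <- grDevices::chull(cols, rows)
  hx <- cols[h]; hy <- rows[h]
  hull_area <- abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
  if (hull_area <= 0) return(1)
  min(1, length(idx) / hull_area)
}

# split one component by seeded growing on the smoothed distance transform;
# seeds are distance maxima at least min_seed_dist_um apart
split_component <- function(comp_mask, um_per_px, min_seed_dist_um = 2) {
  dm <- as.matrix(EBImage::distmap(comp_mask * 1))
  dms <- as.matrix(EBImage::gblur(dm, sigma = 1))
  dms[!comp_mask] <- 0
  mx <- as.matrix(EBImage::dilate(dms, EBImage::makeBrush(5, "disc")))
  peaks <- which(comp_mask & dms >= mx - 1e-9 & dm > 1)
  if (length(peaks) < 2) return(NULL)
  nr <- nrow(comp_mask)
  pr <- ((peaks - 1L) %% nr) + 1L
  pc <- ((peaks - 1L) %/% nr) + 1L
  ord <- order(-dms[peaks])
  keep_r <- numeric(0); keep_c <- numeric(0)
  min_d_px <- min_seed_dist_um / um_per_px
  for (i in ord) {
    if (length(keep_r) == 0 ||
        all(sqrt((keep_r - pr[i])^2 + (keep_c - pc[i])^2) >= min_d_px)) {
      keep_r <- c(keep_r, pr[i]); keep_c <- c(keep_c, pc[i])
    }
  }
  if (length(keep_r) < 2) return(NULL)
  seeds <- matrix(0L, nrow(comp_mask), ncol(comp_mask))
  seeds[cbind(keep_r, keep_c)] <- seq_along(keep_r)
  sub <- as.matrix(EBImage::propagate(dms, seeds, mask = comp_mask))
  if (length(unique(sub[sub > 0])) < 2) return(NULL)
  sub
}

#' Segment individual nuclei from the DAPI counterstain
#'
#' Connected components of the counterstain mask become candidate nuclei;
#' components whose shape indicates touching nuclei (solidity below
#' `solidity_min` or area above `area_factor` times the expected
#' single-nucleus area) are split by seeded growing on the distance
#' transform, with seeds at distance maxima at least `min_seed_dist_um`
#' apart. Regions touching the image border are flagged and are never
#' accepted automatically. All nuclei start with status `"presegmented"`;
#' [gate_nuclei()] promotes suitable ones to `"accepted"`.
#'
#' @param dapi 8-bit DAPI raster (used only for provenance; segmentation
#'   operates on `mask`).
#' @param mask logical counterstain mask from [build_counterstain_mask()].
#' @param um_per_px physical scale, micrometres per pixel.
#' @param expected_area_um2 expected single-nucleus area; default 64 um^2
#'   (a 9-um nucleus).
#' @param solidity_min,area_factor,min_seed_dist_um splitting controls.
#' @return an object of class `nucleus_set`: list with `labels` (integer
#'   label raster), `nuclei` (data.frame: `id`, `row`, `col`, `area_um2`,
#'   `roundness`, `border`, `status`, `her2_count`, `cep17_count`) and
#'   `um_per_px`.
#' @export
segment_nuclei <- function(dapi, mask, um_per_px, expected_area_um2 = 64,
                           solidity_min = 0.9, area_factor = 1.5,
                           min_seed_dist_um = 2) {
  stopifnot(is.matrix(mask), um_per_px > 0)
  labels <- matrix(0L, nrow(mask), ncol(mask))
  comp <- EBImage::bwlabel(mask)
  ncomp <- max(comp)
  nxt <- 1L
  if (ncomp > 0) {
    pix <- split(which(comp > 0), comp[comp > 0])
    for (k in seq_len(ncomp)) {
      idx <- pix[[as.character(k)]]
      needs_split <- length(idx) * um_per_px^2 > area_factor * expected_area_um2 ||
        region_solidity(idx, nrow(mask)) < solidity_min
      sub <- NULL
      if (needs_split) {
        cm <- matrix(FALSE, nrow(mask), ncol(mask))
        cm[idx] <- TRUE
        sub <- split_component(cm, um_per_px, min_seed_dist_um)
      }
      if (is.null(sub)) {
        labels[idx] <- nxt
        nxt <- nxt + 1L
      } else {
        vals <- sort(unique(sub[sub > 0]))
        for (v in vals) {
          labels[sub == v] <- nxt
          nxt <- nxt + 1L
        }
      }
    }
  }
  nucleus_set_from_labels(labels, um_per_px)
}

nucleus_set_from_labels <- function(labels, um_per_px) {
  ids <- sort(unique(labels[labels > 0]))
  rows <- lapply(ids, function(i) {
    st <- region_stats(which(labels == i), dim(labels), um_per_px)
    data.frame(id = i, row = st$row, col = st$col, area_um2 = st$area_um2,
               roundness = st$roundness, border = st$border,
               status = "presegmented", her2_count = 0L, cep17_count = 0L)
  })
  nuclei <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = integer(), row = numeric(), col = numeric(),
               area_um2 = numeric(), roundness = numeric(), border = logical(),
               status = character(), her2_count = integer(),
               cep17_count = integer())
  structure(list(labels = labels, nuclei = nuclei, um_per_px = um_per_px),
            class = "nucleus_set")
}

# sum spot equivalents whose centroid pixel carries each label
spot_counts_by_label <- function(labels, spots) {
  n <- max(labels, 0L)
  her2 <- integer(n); cep17 <- integer(n)
  if (nrow(spots)) {
    r <- pmin(pmax(as.integer(round(spots$row)), 1L), nrow(labels))
    c <- pmin(pmax(as.integer(round(spots$col)), 1L), ncol(labels))
    lab <- labels[cbind(r, c)]
    ok <- lab > 0
    if (any(ok)) {
      agg <- rowsum(spots$equivalents[ok],
                    paste(lab[ok], spots$channel[ok], sep = ":"))
      key <- strsplit(rownames(agg), ":", fixed = TRUE)
      for (i in seq_along(key)) {
        id <- as.integer(key[[i]][1])
        if (key[[i]][2] == "her2") her2[id] <- agg[i, 1] else cep17[id] <- agg[i, 1]
      }
    }
  }
  list(her2 = her2, cep17 = cep17)
}

#' Gate segmented nuclei by size, shape and signal quality
#'
#' A nucleus is accepted when its area lies within the configured range, its
#' roundness (circularity) reaches the threshold, it does not touch the
#' image border, and it contains at least one HER2 and one CEP17
#' spot-equivalent — the same eligibility rule a technologist applies when
#' selecting nuclei to score. All other nuclei remain `"presegmented"`.
#'
#' @param nset a `nucleus_set` from [segment_nuclei()].
#' @param spots spots data.frame (both channels).
#' @param params a [nucleus_params()] object.
#' @return the `nucleus_set` with counts attached and statuses updated.
#' @export
gate_nuclei <- function(nset, spots, params = nucleus_params()) {
  stopifnot(inherits(nset, "nucleus_set"), inherits(params, "nucleus_params"))
  nuc <- nset$nuclei
  if (nrow(nuc)) {
    cnt <- spot_counts_by_label(nset$labels, spots)
    nuc$her2_count <- cnt$her2[nuc$id]
    nuc$cep17_count <- cnt$cep17[nuc$id]
    editable <- nuc$status %in% c("presegmented", "accepted")
    ok <- nuc$area_um2 >= params$min_area_um2 &
          nuc$area_um2 <= params$max_area_um2 &
          nuc$roundness >= params$min_roundness &
          !nuc$border &
          nuc$her2_count >= 1L & nuc$cep17_count >= 1L
    nuc$status[editable] <- ifelse(ok[editable], "accepted", "presegmented")
  }
  nset$nuclei <- nuc
  nset
}

#' Aggregate accepted nuclei into a nuclei-mode case result
#'
#' Accepted nuclei are those with status `"accepted"` or `"user_added"`.
#' Cases with fewer accepted nuclei than `min_nuclei` are rejected;
#' otherwise the ratio is the quotient of pooled spot-equivalent totals.
#'
#' @param x a `nucleus_set`, a `case_state`, or a nuclei data.frame.
#' @param params a [nucleus_params()] object.
#' @param thresholds a [ratio_thresholds()] object.
#' @param qc extra QC flags to carry into the result.
#' @return a [case_result()] with `mode = "nuclei"`.
#' @export
nuclei_case_result <- function(x, params = nucleus_params(),
                               thresholds = ratio_thresholds(),
                               qc = character()) {
  nuc <- if (is.data.frame(x)) x else x$nuclei
  acc <- nuc[nuc$status %in% c("accepted", "user_added"), , drop = FALSE]
  case_result(total_her2 = sum(acc$her2_count),
              total_cep17 = sum(acc$cep17_count),
              n_units = nrow(acc), mode = "nuclei",
              thresholds = thresholds, min_units = params$min_nuclei, qc = qc)
}

# ---- interactive correction -------------------------------------------------

#' Construct a human-correction edit operation
#'
#' The five correction operations of the interactive phase: `add` a nucleus
#' from a closed polygon, `select` a pre-segmented nucleus into the
#' analysis, `delete` a selected nucleus, `split` overlapping nuclei along a
#' polyline, and `merge` separated parts of one nucleus.
#'
#' @param kind one of `"add"`, `"select"`, `"delete"`, `"split"`, `"merge"`.
#' @param target_ids nucleus ids the operation applies to (all kinds except
#'   `add`; `split` takes exactly one, `merge` at least two).
#' @param geometry for `add`, a closed simple polygon as an `n x 2` matrix of
#'   `(row, col)` vertices; for `split`, a polyline crossing the region.
#' @return an object of class `edit_op`.
#' @export
edit_op <- function(kind, target_ids = NULL, geometry = NULL) {
  kind <- match.arg(kind, c("add", "select", "delete", "split", "merge"))
  if (!is.null(geometry)) {
    geometry <- as.matrix(geometry)
    stopifnot(ncol(geometry) == 2, nrow(geometry) >= 2)
  }
  if (kind == "add" && (is.null(geometry) || nrow(geometry) < 3))
    stop("add requires a polygon with at least 3 vertices", call. = FALSE)
  if (kind == "split" && (length(target_ids) != 1 || is.null(geometry)))
    stop("split requires one target id and a polyline", call. = FALSE)
  if (kind %in% c("select", "delete") && length(target_ids) < 1)
    stop(kind, " requires at least one target id", call. = FALSE)
  if (kind == "merge" && length(target_ids) < 2)
    stop("merge requires at least two target ids", call. = FALSE)
  structure(list(kind = kind, target_ids = as.integer(target_ids),
                 geometry = geometry),
            class = "edit_op")
}

# even-odd rasterization of a closed polygon; returns linear pixel indices
polygon_pixels <- function(poly, dims) {
  pr <- poly[, 1]; pc <- poly[, 2]
  if (any(pr < 0.5) || any(pc < 0.5) || any(pr > dims[1] + 0.5) ||
      any(pc > dims[2] + 0.5))
    stop("polygon lies outside the image", call. = FALSE)
  r0 <- max(1L, floor(min(pr))); r1 <- min(dims[1], ceiling(max(pr)))
  c0 <- max(1L, floor(min(pc))); c1 <- min(dims[2], ceiling(max(pc)))
  gr <- expand.grid(row = r0:r1, col = c0:c1, KEEP.OUT.ATTRS = FALSE)
  n <- nrow(poly)
  inside <- rep(FALSE, nrow(gr))
  j <- n
  for (i in seq_len(n)) {
    cross <- ((pr[i] > gr$row) != (pr[j] > gr$row)) &
      (gr$col < (pc[j] - pc[i]) * (gr$row - pr[i]) / (pr[j] - pr[i]) + pc[i])
    inside <- xor(inside, cross & !is.na(cross))
    j <- i
  }
  (gr$col[inside] - 1L) * dims[1] + gr$row[inside]
}

# distance from pixels to a polyline, used to carve the split cut
near_polyline <- function(rows, cols, line, width = 0.75) {
  near <- rep(FALSE, length(rows))
  for (i in seq_len(nrow(line) - 1)) {
    a <- line[i, ]; b <- line[i + 1, ]
    ab <- b - a
    len2 <- sum(ab^2)
    t <- if (len2 == 0) rep(0, length(rows)) else
      pmin(1, pmax(0, ((rows - a[1]) * ab[1] + (cols - a[2]) * ab[2]) / len2))
    d <- sqrt((rows - (a[1] + t * ab[1]))^2 + (cols - (a[2] + t * ab[2]))^2)
    near <- near | d <= width
  }
  near
}

#' Initialise an editable case state
#'
#' Bundles the segmented nuclei, the detected spots and the scoring
#' parameters; the case result is computed immediately and kept current
#' through every subsequent [apply_edit()].
#'
#' @param nset a gated `nucleus_set` (see [gate_nuclei()]).
#' @param spots spots data.frame (both channels).
#' @param params a [nucleus_params()] object.
#' @param thresholds a [ratio_thresholds()] object.
#' @param qc QC flags carried into every recomputed result.
#' @return an object of class `case_state`.
#' @export
case_state <- function(nset, spots, params = nucleus_params(),
                       thresholds = ratio_thresholds(), qc = character()) {
  stopifnot(inherits(nset, "nucleus_set"))
  st <- structure(list(labels = nset$labels, nuclei = nset$nuclei,
                       spots = spots, um_per_px = nset$um_per_px,
                       params = params, thresholds = thresholds,
                       qc = qc, journal = list(), result = NULL),
                  class = "case_state")
  recompute_result(st)
}

recompute_result <- function(state) {
  state$result <- tryCatch(
    nuclei_case_result(state$nuclei, state$params, state$thresholds,
                       qc = state$qc),
    fishratio_undefined_ratio = function(e) {
      r <- case_result(0, 1, 0, "nuclei", state$thresholds,
                       min_units = state$params$min_nuclei,
                       qc = unique(c(state$qc, "undefined_ratio")))
      r$total_cep17 <- 0
      r
    })
  state
}

# gate a freshly created region (split/merge product) and return its row
gated_nucleus_row <- function(state, id, idx) {
  st <- region_stats(idx, dim(state$labels), state$um_per_px)
  cnt <- local({
    m <- matrix(0L, nrow(state$labels), ncol(state$labels))
    m[idx] <- 1L
    spot_counts_by_label(m, state$spots)
  })
  p <- state$params
  ok <- st$area_um2 >= p$min_area_um2 && st$area_um2 <= p$max_area_um2 &&
    st$roundness >= p$min_roundness && !st$border &&
    cnt$her2[1] >= 1L && cnt$cep17[1] >= 1L
  data.frame(id = id, row = st$row, col = st$col, area_um2 = st$area_um2,
             roundness = st$roundness, border = st$border,
             status = if (ok) "accepted" else "presegmented",
             her2_count = cnt$her2[1], cep17_count = cnt$cep17[1])
}

#' Apply one human-correction edit and update the result
#'
#' Semantics of the five operations: `add` creates a new accepted nucleus
#' from the polygon (automatic gates are *not* re-applied — the user
#' overrides the classifier); `select` promotes a pre-segmented nucleus to
#' accepted; `delete` retires a nucleus from the analysis; `split`
#' partitions a region along the polyline into two (or more) nuclei, each
#' re-gated; `merge` unites regions into one re-gated nucleus. The case
#' result is recomputed after every edit and the edit is appended to a
#' replayable journal. Invalid edits (unknown ids, polygon outside the
#' image, a split polyline that does not partition the region) raise an
#' error and leave the state unchanged.
#'
#' @param state a [case_state()].
#' @param op an [edit_op()].
#' @return the updated `case_state`.
#' @export
apply_edit <- function(state, op) {
  stopifnot(inherits(state, "case_state"), inherits(op, "edit_op"))
  nuc <- state$nuclei
  if (op$kind != "add") {
    missing_ids <- setdiff(op$target_ids, nuc$id)
    if (length(missing_ids))
      stop("unknown nucleus id(s): ", paste(missing_ids, collapse = ", "),
           call. = FALSE)
  }
  dims <- dim(state$labels)

  if (op$kind == "add") {
    idx <- polygon_pixels(op$geometry, dims)
    # background pixels and pixels of deleted nuclei are claimable
    deleted <- nuc$id[nuc$status == "deleted"]
    idx <- idx[state$labels[idx] == 0L | state$labels[idx] %in% deleted]
    if (length(idx) == 0)
      stop("polygon rasterizes to no free pixels", call. = FALSE)
    id <- max(nuc$id, 0L) + 1L
    state$labels[idx] <- id
    st <- region_stats(idx, dims, state$um_per_px)
    cnt <- local({
      m <- matrix(0L, dims[1], dims[2]); m[idx] <- 1L
      spot_counts_by_label(m, state$spots)
    })
    state$nuclei <- rbind(nuc, data.frame(
      id = id, row = st$row, col = st$col, area_um2 = st$area_um2,
      roundness = st$roundness, border = st$border, status = "user_added",
      her2_count = cnt$her2[1], cep17_count = cnt$cep17[1]))
  } else if (op$kind == "select") {
    sel <- nuc$id %in% op$target_ids & nuc$status == "presegmented"
    nuc$status[sel] <- "accepted"
    state$nuclei <- nuc
  } else if (op$kind == "delete") {
    sel <- nuc$id %in% op$target_ids & nuc$status != "deleted"
    nuc$status[sel] <- "deleted"
    state$nuclei <- nuc
  } else if (op$kind == "split") {
    id <- op$target_ids
    idx <- which(state$labels == id)
    if (length(idx) == 0) stop("nucleus ", id, " has no pixels", call. = FALSE)
    nr <- dims[1]
    rows <- ((idx - 1L) %% nr) + 1L
    cols <- ((idx - 1L) %/% nr) + 1L
    cut <- near_polyline(rows, cols, op$geometry)
    keep_idx <- idx[!cut]
    m <- matrix(0L, dims[1], dims[2])
    m[keep_idx] <- 1L
    parts <- EBImage::bwlabel(m)
    npart <- max(parts)
    if (npart < 2)
      stop("split polyline does not partition the region", call. = FALSE)
    # reassign cut pixels to the nearest part so no signal is lost
    cut_idx <- idx[cut]
    if (length(cut_idx)) {
      cr <- ((cut_idx - 1L) %% nr) + 1L
      cc <- ((cut_idx - 1L) %/% nr) + 1L
      kr <- ((keep_idx - 1L) %% nr) + 1L
      kc <- ((keep_idx - 1L) %/% nr) + 1L
      for (i in seq_along(cut_idx)) {
        j <- which.min((kr - cr[i])^2 + (kc - cc[i])^2)
        parts[cut_idx[i]] <- parts[keep_idx[j]]
      }
    }
    base_id <- max(nuc$id, 0L)
    new_rows <- vector("list", npart)
    for (v in seq_len(npart)) {
      pidx <- which(parts == v)
      state$labels[pidx] <- base_id + v
      new_rows[[v]] <- gated_nucleus_row(state, base_id + v, pidx)
    }
    state$nuclei <- rbind(nuc[nuc$id != id, , drop = FALSE],
                          do.call(rbind, new_rows))
  } else if (op$kind == "merge") {
    idx <- which(state$labels %in% op$target_ids)
    if (length(idx) == 0) stop("merge targets have no pixels", call. = FALSE)
    new_id <- min(op$target_ids)
    state$labels[idx] <- new_id
    state$nuclei <- rbind(nuc[!(nuc$id %in% op$target_ids), , drop = FALSE],
                          gated_nucleus_row(state, new_id, idx))
  }
  state$nuclei <- state$nuclei[order(state$nuclei$id), , drop = FALSE]
  rownames(state$nuclei) <- NULL
  state$journal <- c(state$journal, list(op))
  recompute_result(state)
}

#' Replay a journal of edits
#'
#' @param state a [case_state()].
#' @param ops a list of [edit_op()] objects (or a parsed JSON journal: a list
#'   of lists with fields `kind`, `target_ids`, `geometry`).
#' @return the state after applying every edit in order.
#' @export
replay_edits <- function(state, ops) {
  for (op in ops) {
    if (!inherits(op, "edit_op"))
      op <- edit_op(op$kind,
                    target_ids = op$target_ids,
                    geometry = if (!is.null(op$geometry))
                      matrix(unlist(op$geometry), ncol = 2, byrow = TRUE))
    state <- apply_edit(state, op)
  }
  state
}
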