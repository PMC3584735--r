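# The tile-sampling classifier: non-overlapping equal squares placed to
# maximize covered nuclear material, per-tile spot counts, tile- and
# case-level rejection rules.

# summed-area table lookup of box sums over a 0/1 matrix
box_sums <- function(mask, r0, c0, side) {
  sat <- apply(apply(mask, 2, cumsum), 1, cumsum)  # sat[c, r] after transpose
  sat <- t(sat)
  pad <- matrix(0, nrow(mask) + 1L, ncol(mask) + 1L)
  pad[-1, -1] <- sat
  r1 <- r0 + side; c1 <- c0 + side  # half-open upper corners (exclusive)
  pad[cbind(r1, c1)] - pad[cbind(r0, c1)] - pad[cbind(r1, c0)] + pad[cbind(r0, c0)]
}

#' Place non-overlapping square tiles over the counterstain mask
#'
#' Greedy placement that emulates the tile-sampling objective: cover as much
#' nuclear material and as little empty space as possible. Candidate origins
#' form a stride-8 lattice united with the exact tiling lattice of stride
#' `tile_px`; candidates are ranked by descending mask coverage with
#' row-major tie-breaking, and accepted greedily subject to non-overlap.
#' Zero-coverage candidates are never emitted. Fully deterministic.
#'
#' @param mask logical counterstain mask (`[row, col]`).
#' @param tile_px tile side length in pixels; must not exceed either image
#'   dimension.
#' @param stride candidate lattice stride in pixels; default 8.
#' @return a data.frame with one row per tile: `row`, `col` (1-based origin,
#'   top-left pixel), `side_px`, `coverage`, `her2_count`, `cep17_count`,
#'   `accepted` (filled later by [fill_tiles()] / [reject_tiles()]).
#' @export
place_tiles <- function(mask, tile_px, stride = 8L) {
  stopifnot(is.matrix(mask))
  nr <- nrow(mask); nc <- ncol(mask)
  tile_px <- as.integer(tile_px)
  if (tile_px > nr || tile_px > nc)
    stop("tile_px exceeds image dimensions", call. = FALSE)
  m <- mask * 1L
  orow <- sort(unique(c(seq(1L, nr - tile_px + 1L, by = stride),
                        seq(1L, nr - tile_px + 1L, by = tile_px))))
  ocol <- sort(unique(c(seq(1L, nc - tile_px + 1L, by = stride),
                        seq(1L, nc - tile_px + 1L, by = tile_px))))
  cand <- expand.grid(row = orow, col = ocol, KEEP.OUT.ATTRS = FALSE)
  cov <- box_sums(m, cand$row, cand$col, tile_px) / tile_px^2
  keep <- cov > 0
  cand <- cand[keep, , drop = FALSE]; cov <- cov[keep]
  ord <- order(-cov, cand$row, cand$col)
  cand <- cand[ord, , drop = FALSE]; cov <- cov[ord]

  sel_r <- integer(0); sel_c <- integer(0); sel_cov <- numeric(0)
  for (i in seq_len(nrow(cand))) {
    r <- cand$row[i]; c <- cand$col[i]
    if (length(sel_r) == 0 ||
        !any(abs(sel_r - r) < tile_px & abs(sel_c - c) < tile_px)) {
      sel_r <- c(sel_r, r); sel_c <- c(sel_c, c); sel_cov <- c(sel_cov, cov[i])
    }
  }
  # greedy can be blocked below the exact tiling grid; keep whichever covers
  # more nuclear material (ties favour the greedy placement)
  grid <- cand$row %% tile_px == 1L & cand$col %% tile_px == 1L
  if (sum(cov[grid]) > sum(sel_cov)) {
    sel_r <- cand$row[grid]; sel_c <- cand$col[grid]; sel_cov <- cov[grid]
  }
  data.frame(row = sel_r, col = sel_c, side_px = rep(tile_px, length(sel_r)),
             coverage = sel_cov,
             her2_count = integer(length(sel_r)),
             cep17_count = integer(length(sel_r)),
             accepted = rep(NA, length(sel_r)))
}

#' Count spot-equivalents falling inside each tile
#'
#' A spot is assigned to the tile whose half-open pixel box
#' `[origin, origin + side)` contains its centroid; since tiles are
#' non-overlapping, each spot is counted in at most one tile.
#'
#' @param tiles data.frame from [place_tiles()].
#' @param spots spots data.frame (both channels concatenated), e.g. from
#'   [detect_spots()] after optional [count_hsr_equivalents()].
#' @return `tiles` with `her2_count` / `cep17_count` filled.
#' @export
fill_tiles <- function(tiles, spots) {
  tiles$her2_count <- 0L
  tiles$cep17_count <- 0L
  if (nrow(tiles) == 0 || nrow(spots) == 0) return(tiles)
  for (i in seq_len(nrow(tiles))) {
    r0 <- tiles$row[i]; c0 <- tiles$col[i]; s <- tiles$side_px[i]
    inside <- spots$row >= r0 & spots$row < r0 + s &
              spots$col >= c0 & spots$col < c0 + s
    tiles$her2_count[i] <- sum(spots$equivalents[inside & spots$channel == "her2"])
    tiles$cep17_count[i] <- sum(spots$equivalents[inside & spots$channel == "cep17"])
  }
  tiles
}

#' Apply the tile rejection rules
#'
#' A tile is rejected when less than `min_coverage` of its surface is
#' occupied by nuclei, or when it contains at most one fluorescent signal in
#' total (a tile with a single orange or single green signal — or none — is
#' uninformative).
#'
#' @param tiles data.frame with counts filled by [fill_tiles()].
#' @param params a [tile_params()] object.
#' @return the accepted tiles only, with `accepted = TRUE`.
#' @export
reject_tiles <- function(tiles, params = tile_params()) {
  stopifnot(inherits(params, "tile_params"))
  ok <- tiles$coverage >= params$min_coverage &
        (tiles$her2_count + tiles$cep17_count) >= 2L
  out <- tiles[ok, , drop = FALSE]
  out$accepted <- if (nrow(out)) TRUE else logical(0)
  rownames(out) <- NULL
  out
}

#' Aggregate accepted tiles into a tile-mode case result
#'
#' Cases with fewer accepted tiles (pooled over the case's fields) than
#' `min_tiles` are rejected. Otherwise the HER2/CEP17 ratio is the quotient
#' of pooled totals — identical to the quotient of per-tile averages — and
#' the category follows [classify_ratio()].
#'
#' @param accepted data.frame of accepted tiles pooled over fields.
#' @param params a [tile_params()] object.
#' @param thresholds a [ratio_thresholds()] object.
#' @return a [case_result()] with `mode = "tile"`.
#' @export
tile_case_result <- function(accepted, params = tile_params(),
                             thresholds = ratio_thresholds()) {
  stopifnot(inherits(params, "tile_params"))
  case_result(total_her2 = sum(accepted$her2_count),
              total_cep17 = sum(accepted$cep17_count),
              n_units = nrow(accepted), mode = "tile",
              thresholds = thresholds, min_units = params$min_tiles)
}
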