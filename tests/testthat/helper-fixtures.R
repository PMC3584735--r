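# Shared fixtures: programmatic image builders and an independent
# spot-counting oracle (threshold -> 4-connected components -> area filter ->
# single-linkage centroid-distance merge), kept free of the package's
# detection code path.

# integer 8-bit raster with isotropic Gaussian blobs at (rows, cols)
gauss_blob_image <- function(H, W, rows, cols, sigma_px, amp = 220) {
  im <- matrix(0, H, W)
  amp <- rep_len(amp, length(rows))
  for (i in seq_along(rows))
    im <- im + amp[i] * exp(-((row(im) - rows[i])^2 + (col(im) - cols[i])^2) /
                              (2 * sigma_px^2))
  matrix(as.integer(pmin(round(im), 255)), H, W)
}

disc_image <- function(H, W, ctr_row, ctr_col, radius_px, value = 230) {
  im <- matrix(0L, H, W)
  im[(row(im) - ctr_row)^2 + (col(im) - ctr_col)^2 <= radius_px^2] <- as.integer(value)
  im
}

# independent flood-fill labeling, 4-connectivity
oracle_label <- function(bin) {
  nr <- nrow(bin); nc <- ncol(bin)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (start in which(bin)) {
    if (lab[start] > 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      r <- ((p - 1L) %% nr) + 1L; c <- ((p - 1L) %/% nr) + 1L
      for (q in c(if (r > 1) p - 1L, if (r < nr) p + 1L,
                  if (c > 1) p - nr, if (c < nc) p + nr)) {
        if (bin[q] && lab[q] == 0L) { lab[q] <- cur; queue <- c(queue, q) }
      }
    }
  }
  lab
}

# brute-force spot count from a preprocessed raster, per the documented rule
oracle_spot_count <- function(pre, params, um_per_px) {
  pos <- pre[pre > 1e-9]
  if (!length(pos)) return(0L)
  thr <- params$intensity_frac * quantile(pos, 0.999, names = FALSE)
  lab <- oracle_label(pre >= thr)
  n <- max(lab)
  if (n == 0) return(0L)
  keep <- integer(0); cy <- numeric(0); cx <- numeric(0)
  nr <- nrow(pre)
  for (k in seq_len(n)) {
    idx <- which(lab == k)
    if (length(idx) * um_per_px^2 >= params$min_area_um2) {
      w <- pre[idx]
      keep <- c(keep, k)
      cy <- c(cy, sum((((idx - 1L) %% nr) + 1L) * w) / sum(w))
      cx <- c(cx, sum((((idx - 1L) %/% nr) + 1L) * w) / sum(w))
    }
  }
  m <- length(keep)
  if (m <= 1) return(m)
  # union-find transitive merge of centroid pairs closer than the gate
  parent <- seq_len(m)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    if (sqrt((cy[i] - cy[j])^2 + (cx[i] - cx[j])^2) * um_per_px <
        params$min_distance_um) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  length(unique(vapply(seq_len(m), find, integer(1))))
}

# minimal accepted-tile / nuclei tables for result-level tests
make_tiles <- function(n, her2_each, cep17_each) {
  data.frame(row = seq_len(n), col = 1L, side_px = 71L, coverage = 1,
             her2_count = rep_len(her2_each, n),
             cep17_count = rep_len(cep17_each, n), accepted = TRUE)
}

make_nuclei <- function(n, her2_each, cep17_each, status = "accepted") {
  data.frame(id = seq_len(n), row = 1, col = 1, area_um2 = 100,
             roundness = 0.9, border = FALSE, status = status,
             her2_count = rep_len(her2_each, n),
             cep17_count = rep_len(cep17_each, n))
}

# small field spec used across tests (kept fast)
small_field <- function(seed, n_nuclei = 12, ...) {
  field_spec(width_px = 420, height_px = 420, n_nuclei = n_nuclei,
             seed = seed, ...)
}
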