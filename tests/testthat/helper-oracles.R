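# Independent brute-force oracles and small fixture builders used across the
# suite. These deliberately avoid the package's own code paths.

# Recursive (stack-based) flood-fill labeling; labels assigned in
# column-major scan order of each component's first pixel.
flood_fill_label <- function(mask, connectivity = 8L) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  cur <- 0L
  for (cc in seq_len(W)) for (rr in seq_len(H)) {
    if (mask[rr, cc] && lab[rr, cc] == 0L) {
      cur <- cur + 1L
      stack <- list(c(rr, cc))
      lab[rr, cc] <- cur
      while (length(stack)) {
        p <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        for (dr in -1:1) for (dc in -1:1) {
          if (dr == 0L && dc == 0L) next
          if (connectivity == 4L && abs(dr) + abs(dc) != 1L) next
          r2 <- p[1L] + dr; c2 <- p[2L] + dc
          if (r2 >= 1L && r2 <= H && c2 >= 1L && c2 <= W &&
              mask[r2, c2] && lab[r2, c2] == 0L) {
            lab[r2, c2] <- cur
            stack[[length(stack) + 1L]] <- c(r2, c2)
          }
        }
      }
    }
  }
  lab
}

# Full detection oracle: recomputes background, threshold, labels and
# per-object measurements with plain loops.
oracle_detect <- function(pix, k_sigma = 5, min_diameter_um = 0,
                          um_per_px = 1, connectivity = 8L) {
  bg <- median(pix)
  thr <- bg + k_sigma * mad(pix)
  lab <- flood_fill_label(pix > thr, connectivity)
  n <- max(lab)
  rows <- list()
  for (id in seq_len(n)) {
    idx <- which(lab == id, arr.ind = TRUE)
    area <- nrow(idx)
    d <- 2 * sqrt(area / pi) * um_per_px
    if (d < min_diameter_um) next
    rows[[length(rows) + 1L]] <- data.frame(
      label = id, area_px = area,
      equiv_diameter_um = d,
      centroid_row = mean(idx[, 1L] - 1),
      centroid_col = mean(idx[, 2L] - 1),
      integrated_intensity = max(0, sum(pix[idx] - bg)))
  }
  if (!length(rows)) {
    return(data.frame(label = integer(), area_px = integer(),
                      equiv_diameter_um = numeric(), centroid_row = numeric(),
                      centroid_col = numeric(),
                      integrated_intensity = numeric()))
  }
  do.call(rbind, rows)
}

# Exact two-tailed signed-rank p by full enumeration of sign assignments.
enum_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) return(1)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Ws <- as.vector(signs %*% r)
  min(1, 2 * min(mean(Ws <= W + 1e-9), mean(Ws >= W - 1e-9)))
}

# Random test image: Poisson background plus a few bright disks of random
# size and brightness, so component labeling has real work to do.
random_blob_image <- function(side = 64L, n_blobs = sample(2:8, 1)) {
  pix <- matrix(rpois(side * side, 20), side, side)
  for (b in seq_len(n_blobs)) {
    cx <- runif(1, 5, side - 5); cy <- runif(1, 5, side - 5)
    rad <- runif(1, 1, 4)
    amp <- runif(1, 60, 400)
    rr <- pmax(1, floor(cy - rad - 1)):pmin(side, ceiling(cy + rad + 1))
    cc <- pmax(1, floor(cx - rad - 1)):pmin(side, ceiling(cx + rad + 1))
    for (r in rr) for (cl in cc) {
      if ((r - cy)^2 + (cl - cx)^2 <= rad^2) {
        pix[r, cl] <- pix[r, cl] + as.integer(round(amp * runif(1, 0.5, 1)))
      }
    }
  }
  pix
}

# A small, fast parameter set for rendering tests.
small_image_spec <- function(sampled_fraction = 0.5, ...) {
  image_spec(width_px = 256L, height_px = 256L,
             sampled_fraction = sampled_fraction, ...)
}

# Random assay parameters for property tests (valid by construction).
random_assay_params <- function() {
  assay_params(
    load_mean = runif(1, 50, 200),
    load_cv = runif(1, 0, 0.5),
    leak_frac = runif(1, 0, 0.3),
    kill_frac_by_et = c("1" = runif(1)),
    apoptotic_frac = runif(1),
    necrotic_retention = runif(1),
    apoptotic_retention = runif(1),
    bodies_per_cell = sample(2:8, 1),
    live_diameter_um = 10, body_diameter_um = 4)
}
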