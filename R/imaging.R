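# Synthetic fluorescence-image renderer: the camera forward model for the
# image cytometer's single calcein channel.

#' Sample the particles that appear in one imaged field
#'
#' Resuspending the pellet and loading an aliquot on the counting slide
#' randomizes particle positions, and the cytometer images only part of the
#' chamber. Each particle of the well is therefore retained independently
#' with probability `sampled_fraction` and placed uniformly at random in the
#' field, keeping particle centres at least `min_spacing_um` apart (dilute
#' monolayer) and `edge_margin_um` away from the borders (no spot
#' truncation).
#'
#' @param state a [simulate_well()] result.
#' @param spec an [image_spec()].
#' @param seed RNG seed.
#' @return particle table with `particle_id` (row index into
#'   `state$particles`), `kind`, `calcein`, `diameter_um` and continuous
#'   0-based pixel coordinates `x_px` (column) and `y_px` (row).
#' @export
sample_field <- function(state, spec, seed) {
  if (!inherits(state, "well_state")) abort_param("`state` must be a well_state")
  if (!inherits(spec, "image_spec")) abort_param("`spec` must be an image_spec")
  withr::with_seed(seed, sample_field_(state, spec))
}

sample_field_ <- function(state, spec) {
  p <- state$particles
  empty <- data.frame(particle_id = integer(), kind = character(),
                      calcein = numeric(), diameter_um = numeric(),
                      x_px = numeric(), y_px = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(p) == 0L) return(empty)
  keep <- which(runif(nrow(p)) < spec$sampled_fraction)
  if (length(keep) == 0L) return(empty)
  pos <- place_in_field(length(keep), spec)
  data.frame(particle_id = keep, kind = p$kind[keep],
             calcein = p$calcein[keep], diameter_um = p$diameter_um[keep],
             x_px = pos$x, y_px = pos$y, stringsAsFactors = FALSE)
}

# Dart-throwing placement with a uniform grid hash for neighbour queries.
place_in_field <- function(n, spec) {
  margin <- spec$edge_margin_um / spec$um_per_px
  s <- spec$min_spacing_um / spec$um_per_px
  xlo <- margin; xhi <- spec$width_px - margin
  ylo <- margin; yhi <- spec$height_px - margin
  if (xhi <= xlo || yhi <= ylo) {
    abort_config("field is smaller than twice `edge_margin_um`")
  }
  cell <- s
  nx <- max(1L, ceiling((xhi - xlo) / cell))
  ny <- max(1L, ceiling((yhi - ylo) / cell))
  grid <- new.env(parent = emptyenv())
  xs <- numeric(n); ys <- numeric(n)
  max_tries <- 2000L
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      x <- runif(1, xlo, xhi); y <- runif(1, ylo, yhi)
      gx <- min(nx, max(1L, 1L + floor((x - xlo) / cell)))
      gy <- min(ny, max(1L, 1L + floor((y - ylo) / cell)))
      ok <- TRUE
      for (dx in -1:1) for (dy in -1:1) {
        key <- paste0(gx + dx, ",", gy + dy)
        pts <- grid[[key]]
        if (!is.null(pts) &&
            any((pts[, 1L] - x)^2 + (pts[, 2L] - y)^2 < s^2)) {
          ok <- FALSE
        }
      }
      if (ok) {
        key <- paste0(gx, ",", gy)
        grid[[key]] <- rbind(grid[[key]], c(x, y))
        xs[i] <- x; ys[i] <- y
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      abort_config(sprintf(
        "could not place %d particles at min spacing %g um in a %dx%d px field; lower `sampled_fraction` or enlarge the field",
        n, spec$min_spacing_um, spec$width_px, spec$height_px))
    }
  }
  list(x = xs, y = ys)
}

spot_sigma_px <- function(diameter_um, spec) {
  pmax(spec$psf_sigma_um, diameter_um / 4) / spec$um_per_px
}

#' Render a field image from sampled particles
#'
#' Each particle contributes an isotropic, pixel-integrated Gaussian spot
#' with total signal `gain * calcein` counts and spatial sigma
#' `max(psf_sigma_um, diameter_um/4) / um_per_px`. Poisson shot noise is
#' applied to signal plus background offset, Gaussian read noise added, and
#' the image quantized and clipped to the bit depth. The `truth` table
#' records the noiseless total per rendered particle, enabling oracle tests
#' of the detection stage.
#'
#' @param sampled particle table from [sample_field()].
#' @param spec an [image_spec()].
#' @param seed RNG seed for the noise.
#' @param shot_noise,read_noise logicals; disable to obtain the noiseless
#'   expected image (still quantized and clipped).
#' @return an object of class `field_image`: list with integer matrix
#'   `pixels` (`height_px` x `width_px`), `spec`, and `truth` data frame
#'   (`particle_id`, `kind`, `x_px`, `y_px`, `sigma_px`,
#'   `true_total_counts`).
#' @export
render_field <- function(sampled, spec, seed, shot_noise = TRUE,
                         read_noise = TRUE) {
  if (!inherits(spec, "image_spec")) abort_param("`spec` must be an image_spec")
  H <- spec$height_px; W <- spec$width_px
  if (nrow(sampled) > 0L &&
      (any(sampled$x_px < 0) || any(sampled$x_px > W) ||
       any(sampled$y_px < 0) || any(sampled$y_px > H))) {
    abort_param("sampled particles must lie inside the field")
  }
  expected <- matrix(spec$background_offset, nrow = H, ncol = W)
  n <- nrow(sampled)
  sig <- if (n) spot_sigma_px(sampled$diameter_um, spec) else numeric()
  for (i in seq_len(n)) {
    s <- sig[i]
    total <- spec$gain * sampled$calcein[i]
    if (total <= 0) next
    cx <- sampled$x_px[i]; cy <- sampled$y_px[i]
    r0 <- max(0L, floor(cy - 5 * s)); r1 <- min(H - 1L, ceiling(cy + 5 * s))
    c0 <- max(0L, floor(cx - 5 * s)); c1 <- min(W - 1L, ceiling(cx + 5 * s))
    rr <- r0:r1; cc <- c0:c1
    # pixel i is centred on integer coordinate i and spans [i-0.5, i+0.5)
    wr <- pnorm(rr + 0.5, cy, s) - pnorm(rr - 0.5, cy, s)
    wc <- pnorm(cc + 0.5, cx, s) - pnorm(cc - 0.5, cx, s)
    expected[rr + 1L, cc + 1L] <- expected[rr + 1L, cc + 1L] +
      total * (wr %o% wc)
  }
  pix <- withr::with_seed(seed, {
    out <- if (shot_noise) {
      matrix(rpois(length(expected), expected), nrow = H)
    } else expected
    if (read_noise && spec$read_noise_sd > 0) {
      out <- out + matrix(rnorm(length(out), 0, spec$read_noise_sd), nrow = H)
    }
    out
  })
  maxval <- 2L^spec$bit_depth - 1L
  pix <- matrix(as.integer(pmin(maxval, pmax(0, round(pix)))), nrow = H)
  truth <- data.frame(
    particle_id = if (n) sampled$particle_id else integer(),
    kind = if (n) sampled$kind else character(),
    x_px = if (n) sampled$x_px else numeric(),
    y_px = if (n) sampled$y_px else numeric(),
    sigma_px = sig,
    true_total_counts = if (n) spec$gain * sampled$calcein else numeric(),
    stringsAsFactors = FALSE)
  structure(list(pixels = pix, spec = spec, truth = truth),
            class = "field_image")
}

#' Write and read field images as single-channel TIFF
#'
#' Pixel counts are stored losslessly at the spec's bit depth; the truth
#' table, when present, is written as a CSV next to the image
#' (`<path>.truth.csv`).
#'
#' @param field a [render_field()] result.
#' @param path TIFF file path.
#' @param truth write the ground-truth CSV alongside?
#' @return `write_field_tiff()` returns `path` invisibly; `read_field_tiff()`
#'   returns an integer pixel matrix.
#' @export
write_field_tiff <- function(field, path, truth = TRUE) {
  maxval <- 2^field$spec$bit_depth - 1
  tiff::writeTIFF(field$pixels / maxval, path,
                  bits.per.sample = field$spec$bit_depth)
  if (truth && nrow(field$truth)) {
    write.csv(field$truth, paste0(path, ".truth.csv"), row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_field_tiff
#' @export
read_field_tiff <- function(path) {
  pix <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(pix)) == 3L) pix <- pix[, , 1L]
  storage.mode(pix) <- "integer"
  pix
}
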