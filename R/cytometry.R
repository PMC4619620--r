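# Object detection, integrated-intensity measurement and live-cell gating —
# the counting core of the image-cytometry readout.

#' Label connected foreground components
#'
#' @param mask logical matrix (foreground = `TRUE`).
#' @param connectivity 4 or 8.
#' @return integer matrix of labels (0 = background); labels are assigned in
#'   column-major order of each component's first pixel, starting at 1.
#' @export
label_components <- function(mask, connectivity = 8L) {
  if (!is.matrix(mask)) abort_param("`mask` must be a matrix")
  H <- nrow(mask); W <- ncol(mask)
  fg <- which(mask)
  lab <- matrix(0L, H, W)
  if (length(fg) == 0L) return(lab)
  vid <- integer(H * W)
  vid[fg] <- seq_along(fg)

  offsets <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8L) {
    offsets <- c(offsets, list(c(1L, 1L), c(-1L, 1L)))
  } else if (connectivity != 4L) {
    abort_param("`connectivity` must be 4 or 8")
  }
  edges <- list()
  for (off in offsets) {
    dr <- off[1L]; dc <- off[2L]
    r <- max(1L, 1L - dr):min(H, H - dr)
    c <- max(1L, 1L - dc):min(W, W - dc)
    both <- mask[r, c, drop = FALSE] & mask[r + dr, c + dc, drop = FALSE]
    if (any(both)) {
      hit <- which(both)
      rr <- r[(hit - 1L) %% length(r) + 1L]
      cc <- c[(hit - 1L) %/% length(r) + 1L]
      a <- (cc - 1L) * H + rr
      b <- (cc + dc - 1L) * H + rr + dr
      edges[[length(edges) + 1L]] <- rbind(vid[a], vid[b])
    }
  }
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (length(edges)) {
    g <- igraph::add_edges(g, as.vector(do.call(cbind, edges)))
  }
  memb <- igraph::components(g)$membership
  # relabel so labels follow the first (column-major) pixel of each component
  first <- tapply(fg, memb, min)
  relabel <- integer(length(first))
  relabel[order(first)] <- seq_along(first)
  lab[fg] <- relabel[memb]
  lab
}

#' Detect fluorescent objects and measure integrated intensities
#'
#' Background is estimated as the image median (robust to bright objects).
#' The binary mask keeps pixels above the threshold — Otsu's method on the
#' full histogram, or background plus `k_sigma` robust standard deviations
#' (MAD-based; the default, stable on sparse fields where foreground area is
#' tiny). Connected components are labeled at the configured connectivity,
#' components smaller than `min_diameter_um` equivalent diameter are
#' dropped, and each object's background-subtracted pixel sum is reported.
#'
#' @param image a [render_field()] result, or a plain integer pixel matrix
#'   (then `um_per_px` and `bit_depth` must be given).
#' @param params a [detection_params()] object.
#' @param um_per_px,bit_depth image scale and bit depth when `image` is a
#'   bare matrix.
#' @return an object table: data frame with `label`, `area_px`,
#'   `equiv_diameter_um`, `centroid_row`, `centroid_col` (0-based pixels)
#'   and `integrated_intensity` (counts, clamped at 0), sorted by label.
#'   A constant (e.g. fully saturated) image yields an empty table with a
#'   warning.
#' @export
detect_objects <- function(image, params = detection_params(),
                           um_per_px = NULL, bit_depth = 16L) {
  if (inherits(image, "field_image")) {
    pix <- image$pixels
    um_per_px <- image$spec$um_per_px
    bit_depth <- image$spec$bit_depth
  } else if (is.matrix(image)) {
    pix <- image
    if (is.null(um_per_px)) {
      abort_param("`um_per_px` is required when `image` is a bare matrix")
    }
  } else {
    abort_param("`image` must be a field_image or a pixel matrix")
  }
  if (length(pix) == 0L) abort_param("`image` is empty")

  bg <- median(pix)
  rng <- range(pix)
  if (rng[1L] == rng[2L]) {
    warning("constant image: no objects detected")
    return(empty_object_table())
  }
  thr <- switch(params$threshold_method,
    k_sigma = bg + params$k_sigma * mad(pix),
    otsu = {
      maxval <- 2^bit_depth - 1
      EBImage::otsu(EBImage::Image(pix / maxval), range = c(0, 1),
                    levels = 2^bit_depth) * maxval
    })
  mask <- pix > thr
  if (!any(mask)) {
    warning("no pixels above threshold: no objects detected")
    return(empty_object_table())
  }
  lab <- label_components(mask, params$connectivity)
  measure_objects(pix, lab, bg, um_per_px, params$min_diameter_um)
}

empty_object_table <- function() {
  data.frame(label = integer(), area_px = integer(),
             equiv_diameter_um = numeric(), centroid_row = numeric(),
             centroid_col = numeric(), integrated_intensity = numeric(),
             stringsAsFactors = FALSE)
}

measure_objects <- function(pix, lab, bg, um_per_px, min_diameter_um) {
  fg <- which(lab > 0L)
  l <- lab[fg]
  H <- nrow(pix)
  rows <- (fg - 1L) %% H           # 0-based
  cols <- (fg - 1L) %/% H
  area <- tabulate(l)
  ids <- seq_along(area)
  vals <- as.numeric(pix[fg]) - bg
  intensity <- pmax(0, rowsum(vals, l)[, 1L])
  out <- data.frame(
    label = ids,
    area_px = area,
    equiv_diameter_um = 2 * sqrt(area / pi) * um_per_px,
    centroid_row = rowsum(as.numeric(rows), l)[, 1L] / area,
    centroid_col = rowsum(as.numeric(cols), l)[, 1L] / area,
    integrated_intensity = as.numeric(intensity),
    stringsAsFactors = FALSE)
  out <- out[out$equiv_diameter_um >= min_diameter_um, , drop = FALSE]
  out <- out[order(out$label), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Convert ground-truth particles to an object table
#'
#' Builds the per-object measurement table directly from simulated particle
#' states, bypassing rendering and detection: each particle becomes one
#' object with integrated intensity `gain * calcein` and its physical
#' equivalent diameter. This is the measurement-table analysis route, useful
#' when per-object measurements are available without images and for
#' large-sample statistics where image rendering adds nothing.
#'
#' @param particles particle table (from a `well_state` or [sample_field()]).
#' @param gain AU-to-counts conversion, as in [image_spec()].
#' @param um_per_px pixel scale used to express the equivalent area.
#' @return an object table as from [detect_objects()].
#' @export
particles_to_object_table <- function(particles, gain = 100, um_per_px = 1) {
  n <- nrow(particles)
  if (n == 0L) return(empty_object_table())
  d_px <- particles$diameter_um / um_per_px
  data.frame(
    label = seq_len(n),
    area_px = as.integer(pmax(1L, round(pi * (d_px / 2)^2))),
    equiv_diameter_um = particles$diameter_um,
    centroid_row = if (!is.null(particles$y_px)) particles$y_px else rep(NA_real_, n),
    centroid_col = if (!is.null(particles$x_px)) particles$x_px else rep(NA_real_, n),
    integrated_intensity = gain * particles$calcein,
    stringsAsFactors = FALSE)
}

#' Derive the live-cell gate from spontaneous controls
#'
#' The live-cell acceptance rule excludes any object whose integrated
#' fluorescence intensity falls below the target cells of the spontaneous
#' control: the intensity bound is the `q`-th percentile (linear
#' interpolation) of the pooled spontaneous-control intensities, after the
#' diameter prefilter. This is a reproducible, data-driven formalization of
#' the histogram gate drawn against the spontaneous control.
#'
#' @param spontaneous_tables list of object tables from spontaneous wells.
#' @param q percentile in `[0, 100]` (default 5).
#' @param min_diameter_um minimum equivalent diameter of gated objects.
#' @return an object of class `gate`: list with `min_integrated_intensity`,
#'   `min_diameter_um`, `percentile_q`.
#' @export
derive_gate <- function(spontaneous_tables, q = 5, min_diameter_um = 1) {
  if (inherits(spontaneous_tables, "data.frame")) {
    spontaneous_tables <- list(spontaneous_tables)
  }
  if (!is.numeric(q) || q < 0 || q > 100) {
    abort_param("`q` must be a percentile in [0, 100]")
  }
  pooled <- unlist(lapply(spontaneous_tables, function(tb) {
    tb$integrated_intensity[tb$equiv_diameter_um >= min_diameter_um]
  }))
  if (length(pooled) == 0L) {
    abort_gating("no spontaneous-control objects to gate on; check that spontaneous wells were imaged and detected")
  }
  structure(list(
    min_integrated_intensity = unname(quantile(pooled, q / 100, type = 7)),
    min_diameter_um = min_diameter_um,
    percentile_q = q), class = "gate")
}

#' Count live target cells
#'
#' An object is counted as a live cell when its integrated intensity and
#' equivalent diameter are both at or above the gate bounds (boundaries
#' inclusive).
#'
#' @param objects an object table.
#' @param gate a [derive_gate()] result.
#' @return integer live-cell count.
#' @export
count_live <- function(objects, gate) {
  if (!inherits(gate, "gate")) abort_param("`gate` must be a gate object")
  sum(objects$integrated_intensity >= gate$min_integrated_intensity &
        objects$equiv_diameter_um >= gate$min_diameter_um)
}

# ---- table / gate I/O ----------------------------------------------------

#' Read and write object tables and gates
#'
#' Object tables round-trip as CSV with the exact column set of
#' [detect_objects()]; gates serialize to JSON.
#'
#' @param objects an object table.
#' @param gate a `gate` object.
#' @param path file path.
#' @return writers return `path` invisibly; readers the parsed object.
#' @export
write_object_table <- function(objects, path) {
  write.csv(objects[, c("label", "area_px", "equiv_diameter_um",
                        "centroid_row", "centroid_col",
                        "integrated_intensity")],
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_object_table
#' @export
read_object_table <- function(path) {
  tb <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "area_px", "equiv_diameter_um", "centroid_row",
            "centroid_col", "integrated_intensity")
  missing <- setdiff(need, names(tb))
  if (length(missing)) {
    abort_config(sprintf("object table %s lacks columns: %s", path,
                         paste(missing, collapse = ", ")))
  }
  tb[, need]
}

#' @rdname write_object_table
#' @export
write_gate <- function(gate, path) {
  jsonlite::write_json(unclass(gate), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_object_table
#' @export
read_gate <- function(path) {
  lst <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(lst[c("min_integrated_intensity", "min_diameter_um",
                  "percentile_q")], class = "gate")
}
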