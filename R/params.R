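# Parameter containers for the assay simulator, imaging model and detection
# stage, plus YAML/JSON (de)serialization.

#' Assay parameters for the calcein cytotoxicity simulator
#'
#' Describes calcein loading, spontaneous leak and the two NK-mediated lysis
#' modes over the 4-hour endpoint assay. Killing is a single end-of-assay
#' Bernoulli event per target cell; necrosis-like lysis leaves one dim
#' remnant retaining `necrotic_retention` of the cell's calcein, apoptotic
#' lysis fragments the cell into `bodies_per_cell` small apoptotic bodies
#' jointly retaining `apoptotic_retention` of it. Everything not retained in
#' a particle ends up in the supernatant, so calcein is conserved exactly.
#'
#' @param load_mean mean calcein per loaded cell, arbitrary units (AU).
#' @param load_cv coefficient of variation of loading (lognormal; `0` gives
#'   identical loads).
#' @param leak_frac fraction of a live cell's calcein released spontaneously
#'   over the assay (deterministic, same for every live cell).
#' @param kill_frac_by_et named numeric vector mapping effector-to-target
#'   (E:T) ratio (names, e.g. `"2"`, `"1"`, `"0.5"`) to the probability that
#'   a target cell is killed. Ratios absent from the map are rejected, never
#'   interpolated.
#' @param apoptotic_frac fraction of killed cells dying apoptotically (the
#'   rest die necrosis-like).
#' @param necrotic_retention fraction of a necrotically killed cell's calcein
#'   retained in its remnant.
#' @param apoptotic_retention fraction of an apoptotically killed cell's
#'   calcein retained across its apoptotic bodies.
#' @param bodies_per_cell number of apoptotic bodies per apoptotic cell.
#' @param body_split_conc concentration of the symmetric Dirichlet split of
#'   retained calcein across bodies; larger values give more even fragments.
#' @param live_diameter_um mean live-cell diameter, micrometres.
#' @param body_diameter_um mean apoptotic-body diameter, micrometres; must be
#'   smaller than `live_diameter_um`. Necrotic remnants keep the cell size.
#' @param chamber_um side of the square counting-chamber region over which
#'   particle positions are drawn uniformly, micrometres.
#' @return an object of class `assay_params`.
#' @export
assay_params <- function(load_mean = 100,
                         load_cv = 0.3,
                         leak_frac = 0.1,
                         kill_frac_by_et = c("2" = 0.9, "1" = 0.6,
                                             "0.5" = 0.35),
                         apoptotic_frac = 0.7,
                         necrotic_retention = 0.1,
                         apoptotic_retention = 0.5,
                         bodies_per_cell = 6L,
                         body_split_conc = 8,
                         live_diameter_um = 10,
                         body_diameter_um = 4,
                         chamber_um = 3000) {
  check_positive(load_mean, "load_mean")
  if (!is.numeric(load_cv) || load_cv < 0) abort_param("`load_cv` must be >= 0")
  check_fraction(leak_frac, "leak_frac")
  if (length(kill_frac_by_et) < 1L || is.null(names(kill_frac_by_et)) ||
      any(!nzchar(names(kill_frac_by_et)))) {
    abort_param("`kill_frac_by_et` must be a named numeric vector keyed by E:T ratio")
  }
  check_fraction(kill_frac_by_et, "kill_frac_by_et")
  check_fraction(apoptotic_frac, "apoptotic_frac")
  check_fraction(necrotic_retention, "necrotic_retention")
  check_fraction(apoptotic_retention, "apoptotic_retention")
  bodies_per_cell <- check_count(bodies_per_cell, "bodies_per_cell")
  check_positive(body_split_conc, "body_split_conc")
  check_positive(live_diameter_um, "live_diameter_um")
  check_positive(body_diameter_um, "body_diameter_um")
  if (body_diameter_um >= live_diameter_um) {
    abort_param("`body_diameter_um` must be smaller than `live_diameter_um`")
  }
  check_positive(chamber_um, "chamber_um")
  structure(list(load_mean = load_mean, load_cv = load_cv,
                 leak_frac = leak_frac,
                 kill_frac_by_et = kill_frac_by_et,
                 apoptotic_frac = apoptotic_frac,
                 necrotic_retention = necrotic_retention,
                 apoptotic_retention = apoptotic_retention,
                 bodies_per_cell = bodies_per_cell,
                 body_split_conc = body_split_conc,
                 live_diameter_um = live_diameter_um,
                 body_diameter_um = body_diameter_um,
                 chamber_um = chamber_um),
            class = "assay_params")
}

#' Look up the kill fraction for an E:T ratio
#'
#' @param params an [assay_params()] object.
#' @param et_ratio numeric E:T ratio.
#' @return the kill probability. Ratios not present in `kill_frac_by_et`
#'   raise a configuration error rather than being interpolated.
#' @export
kill_frac_for_et <- function(params, et_ratio) {
  keys <- suppressWarnings(as.numeric(names(params$kill_frac_by_et)))
  hit <- which(!is.na(keys) & abs(keys - et_ratio) < 1e-12)
  if (length(hit) != 1L) {
    abort_config(sprintf(
      "E:T ratio %g has no entry in `kill_frac_by_et` (have: %s); ratios are not interpolated",
      et_ratio, paste(names(params$kill_frac_by_et), collapse = ", ")))
  }
  unname(params$kill_frac_by_et[hit])
}

#' Specification of a single assay well
#'
#' @param role `"test"` (targets plus NK effectors), `"spontaneous"`
#'   (targets in plain media; baseline control) or `"maximum"` (targets fully
#'   solubilized with Triton X-100; ceiling control).
#' @param et_ratio effector-to-target ratio; must be positive for test wells
#'   and 0 for controls.
#' @param n_targets number of calcein-loaded target cells seeded.
#' @param seed RNG seed for this well.
#' @return an object of class `well_spec`.
#' @export
well_spec <- function(role, et_ratio = 0, n_targets, seed) {
  role <- match.arg(role, c("test", "spontaneous", "maximum"))
  if ((role == "test") != (et_ratio > 0)) {
    abort_param("test wells require `et_ratio` > 0; control wells require `et_ratio` = 0")
  }
  n_targets <- check_count(n_targets, "n_targets")
  seed <- check_count(seed, "seed", min = 0L)
  structure(list(role = role, et_ratio = et_ratio, n_targets = n_targets,
                 seed = seed),
            class = "well_spec")
}

#' Imaging model for the cytometer field
#'
#' Forward model of the single fluorescence channel of an image cytometer: a
#' particle of calcein content `c` renders as an isotropic Gaussian spot of
#' total signal `gain * c` counts; Poisson shot noise acts on signal plus
#' `background_offset`, Gaussian read noise is added, and the result is
#' quantized and clipped to the bit depth. Exposure time and optics are
#' absorbed into the single `gain` constant since only relative intensities
#' matter downstream.
#'
#' @param width_px,height_px image dimensions in pixels.
#' @param um_per_px physical pixel pitch, micrometres per pixel.
#' @param psf_sigma_um Gaussian blur scale of the optics, micrometres; the
#'   rendered spot sigma is `max(psf_sigma_um, diameter_um/4)`.
#' @param gain AU-to-counts conversion for integrated spot signal.
#' @param background_offset mean background level, counts.
#' @param read_noise_sd Gaussian read noise standard deviation, counts.
#' @param bit_depth 8 or 16.
#' @param sampled_fraction fraction of the well's particles that land in the
#'   imaged field (the 20 ul aliquot placed on the counting slide images only
#'   part of the well's contents).
#' @param min_spacing_um minimum particle centre-to-centre distance when
#'   placing particles in the field, micrometres.
#' @param edge_margin_um margin kept free of particle centres along the
#'   image borders, micrometres, so spots are not truncated.
#' @return an object of class `image_spec`.
#' @export
image_spec <- function(width_px = 1024L, height_px = 1024L,
                       um_per_px = 1,
                       psf_sigma_um = 1,
                       gain = 100,
                       background_offset = 100,
                       read_noise_sd = 2,
                       bit_depth = 16L,
                       sampled_fraction = 0.03,
                       min_spacing_um = 15,
                       edge_margin_um = 13) {
  width_px <- check_count(width_px, "width_px")
  height_px <- check_count(height_px, "height_px")
  check_positive(um_per_px, "um_per_px")
  check_positive(psf_sigma_um, "psf_sigma_um")
  check_positive(gain, "gain")
  if (!is.numeric(background_offset) || background_offset < 0) {
    abort_param("`background_offset` must be >= 0")
  }
  if (!is.numeric(read_noise_sd) || read_noise_sd < 0) {
    abort_param("`read_noise_sd` must be >= 0")
  }
  if (!bit_depth %in% c(8L, 16L)) abort_param("`bit_depth` must be 8 or 16")
  if (!is.numeric(sampled_fraction) || sampled_fraction <= 0 ||
      sampled_fraction > 1) {
    abort_param("`sampled_fraction` must lie in (0, 1]")
  }
  check_positive(min_spacing_um, "min_spacing_um")
  if (!is.numeric(edge_margin_um) || edge_margin_um < 0) {
    abort_param("`edge_margin_um` must be >= 0")
  }
  structure(list(width_px = width_px, height_px = height_px,
                 um_per_px = um_per_px, psf_sigma_um = psf_sigma_um,
                 gain = gain, background_offset = background_offset,
                 read_noise_sd = read_noise_sd,
                 bit_depth = as.integer(bit_depth),
                 sampled_fraction = sampled_fraction,
                 min_spacing_um = min_spacing_um,
                 edge_margin_um = edge_margin_um),
            class = "image_spec")
}

#' Object-detection parameters
#'
#' @param threshold_method `"k_sigma"` (background median plus `k_sigma`
#'   robust standard deviations; stable on sparse fields) or `"otsu"` (Otsu's
#'   method on the full histogram).
#' @param k_sigma threshold multiplier for the `k_sigma` method.
#' @param min_diameter_um minimum equivalent diameter retained, micrometres.
#'   The default of 1.5 um removes one-pixel shot-noise specks (equivalent
#'   diameter 1.13 um at 1 um/px) while comfortably retaining apoptotic
#'   bodies, so that their exclusion from live counts happens at the
#'   intensity gate, as in the assay itself.
#' @param connectivity pixel connectivity for component labeling, 4 or 8.
#' @return an object of class `detection_params`.
#' @export
detection_params <- function(threshold_method = c("k_sigma", "otsu"),
                             k_sigma = 5,
                             min_diameter_um = 1.5,
                             connectivity = 8L) {
  threshold_method <- match.arg(threshold_method)
  check_positive(k_sigma, "k_sigma")
  if (!is.numeric(min_diameter_um) || min_diameter_um < 0) {
    abort_param("`min_diameter_um` must be >= 0")
  }
  if (!connectivity %in% c(4L, 8L)) abort_param("`connectivity` must be 4 or 8")
  structure(list(threshold_method = threshold_method, k_sigma = k_sigma,
                 min_diameter_um = min_diameter_um,
                 connectivity = as.integer(connectivity)),
            class = "detection_params")
}

# ---- serialization -------------------------------------------------------

params_to_list <- function(x) {
  out <- unclass(x)
  if (!is.null(out$kill_frac_by_et)) out$kill_frac_by_et <- as.list(out$kill_frac_by_et)
  out
}

#' Read and write parameter files
#'
#' Parameter objects serialize to YAML or JSON with fields named exactly as
#' in the constructors; the format is chosen from the file extension
#' (`.yaml`/`.yml` or `.json`).
#'
#' @param x an `assay_params`, `image_spec`, `detection_params` or
#'   `well_spec` object.
#' @param path file path.
#' @return `write_params()` returns `path` invisibly; the readers return the
#'   validated object.
#' @export
write_params <- function(x, path) {
  lst <- params_to_list(x)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(lst, path)
  }
  invisible(path)
}

read_params_list <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
}

#' @rdname write_params
#' @export
read_assay_params <- function(path) {
  lst <- read_params_list(path)
  if (!is.null(lst$kill_frac_by_et)) {
    lst$kill_frac_by_et <- unlist(lst$kill_frac_by_et)
  }
  do.call(assay_params, lst)
}

#' @rdname write_params
#' @export
read_image_spec <- function(path) do.call(image_spec, read_params_list(path))

#' @rdname write_params
#' @export
read_detection_params <- function(path) {
  do.call(detection_params, read_params_list(path))
}
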