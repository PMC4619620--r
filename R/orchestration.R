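# Plate-level configuration and end-to-end execution:
# simulate -> render -> detect -> gate -> count -> readouts -> compare.

#' Plate configuration
#'
#' Describes one complete cytotoxicity plate: test wells at each E:T ratio
#' in `n_test_replicates`, plus `n_control_replicates` each of spontaneous
#' (plain media) and maximum (Triton X-100) controls. Counting runs either
#' through the full imaging pipeline (`counting_mode = "render"`: sample a
#' field, render it, detect and measure objects) or directly on per-particle
#' measurement tables (`counting_mode = "table"`, equivalent to analyzing
#' exported per-object measurements; every particle is measured, so counts
#' carry no field-sampling noise).
#'
#' @param cell_line_label free-text label of the target cell line.
#' @param assay_params an [assay_params()].
#' @param image_spec an [image_spec()].
#' @param detection_params a [detection_params()].
#' @param gate_percentile_q spontaneous-control percentile for the intensity
#'   gate (see [derive_gate()]).
#' @param gate_min_diameter_um diameter bound of the gate.
#' @param et_ratios E:T ratios of the test wells; each must have an entry in
#'   `assay_params$kill_frac_by_et`.
#' @param n_test_replicates test replicates per E:T ratio.
#' @param n_control_replicates replicates of each control.
#' @param n_targets_per_well target cells seeded per well.
#' @param master_seed master RNG seed; per-well seeds derive from it via
#'   [derive_seed()].
#' @param counting_mode `"render"` or `"table"`.
#' @param fluorescence_per_au plate-reader proportionality constant between
#'   supernatant calcein (AU) and measured fluorescence; cancels in the
#'   release formula.
#' @return an object of class `plate_config`.
#' @export
plate_config <- function(cell_line_label = "K562",
                         assay_params = calcytox::assay_params(),
                         image_spec = calcytox::image_spec(),
                         detection_params = calcytox::detection_params(),
                         gate_percentile_q = 5,
                         gate_min_diameter_um = 1,
                         et_ratios = c(2, 1, 0.5),
                         n_test_replicates = 3L,
                         n_control_replicates = 6L,
                         n_targets_per_well = 10000L,
                         master_seed = 1L,
                         counting_mode = c("render", "table"),
                         fluorescence_per_au = 1) {
  counting_mode <- match.arg(counting_mode)
  if (length(et_ratios) < 1L) abort_config("`et_ratios` must be non-empty")
  n_test_replicates <- check_count(n_test_replicates, "n_test_replicates")
  n_control_replicates <- check_count(n_control_replicates,
                                      "n_control_replicates")
  n_targets_per_well <- check_count(n_targets_per_well, "n_targets_per_well")
  master_seed <- check_count(master_seed, "master_seed", min = 0L)
  check_positive(fluorescence_per_au, "fluorescence_per_au")
  # surface configuration errors before any simulation runs
  for (et in et_ratios) kill_frac_for_et(assay_params, et)
  structure(list(cell_line_label = cell_line_label,
                 assay_params = assay_params, image_spec = image_spec,
                 detection_params = detection_params,
                 gate_percentile_q = gate_percentile_q,
                 gate_min_diameter_um = gate_min_diameter_um,
                 et_ratios = et_ratios,
                 n_test_replicates = n_test_replicates,
                 n_control_replicates = n_control_replicates,
                 n_targets_per_well = n_targets_per_well,
                 master_seed = master_seed,
                 counting_mode = counting_mode,
                 fluorescence_per_au = fluorescence_per_au),
            class = "plate_config")
}

#' Plate layout implied by a configuration
#'
#' @param config a [plate_config()].
#' @return data frame with `well_index`, `well_id`, `role`, `et_ratio`,
#'   `seed` (derived from the master seed).
#' @export
plate_layout <- function(config) {
  rows <- list()
  for (et in config$et_ratios) {
    for (r in seq_len(config$n_test_replicates)) {
      rows[[length(rows) + 1L]] <- data.frame(
        well_id = sprintf("ET%s_r%d", gsub("\\.", "p", format(et)), r),
        role = "test", et_ratio = et, stringsAsFactors = FALSE)
    }
  }
  for (r in seq_len(config$n_control_replicates)) {
    rows[[length(rows) + 1L]] <- data.frame(
      well_id = sprintf("SPON_r%d", r), role = "spontaneous", et_ratio = 0,
      stringsAsFactors = FALSE)
  }
  for (r in seq_len(config$n_control_replicates)) {
    rows[[length(rows) + 1L]] <- data.frame(
      well_id = sprintf("MAX_r%d", r), role = "maximum", et_ratio = 0,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- cbind(well_index = seq_len(nrow(out)), out)
  out$seed <- vapply(out$well_index,
                     function(i) derive_seed(config$master_seed, i), 1L)
  out
}

#' Run a full plate end to end
#'
#' Simulates every well, counts live cells through the configured route,
#' derives the gate from the spontaneous controls only, and computes both
#' percent-specific-lysis readouts per E:T ratio plus their paired Wilcoxon
#' comparison. Deterministic for a fixed `master_seed`.
#'
#' @param config a [plate_config()].
#' @param write_dir optional directory; when given, all intermediate images
#'   (TIFF + ground-truth CSV, render mode), object tables (CSV), the gate
#'   (JSON), the plate map and the result tables (CSV) are written there.
#' @param verbose log one line per well to `stderr`?
#' @return an object of class `plate_result`: list with `wells` (per-well
#'   rows), `gate`, `lysis` (per test well and method), `summary` (per E:T
#'   medians), `comparisons` (per E:T Wilcoxon), `dynamic_range`, `layout`
#'   and `config`.
#' @export
run_plate <- function(config, write_dir = NULL, verbose = FALSE) {
  if (!inherits(config, "plate_config")) {
    abort_config("`config` must be a plate_config")
  }
  layout <- plate_layout(config)
  ispec <- config$image_spec
  if (!is.null(write_dir) && !dir.exists(write_dir)) {
    dir.create(write_dir, recursive = TRUE)
  }

  tables <- vector("list", nrow(layout))
  wells <- layout
  wells$n_targets <- config$n_targets_per_well
  wells$supernatant_fluorescence <- NA_real_
  wells$n_objects <- NA_integer_
  images <- character(nrow(layout))

  for (i in seq_len(nrow(layout))) {
    w <- layout[i, ]
    spec <- well_spec(w$role, w$et_ratio, config$n_targets_per_well, w$seed)
    state <- simulate_well(spec, config$assay_params)
    wells$supernatant_fluorescence[i] <-
      state$supernatant_calcein * config$fluorescence_per_au

    if (config$counting_mode == "render") {
      sampled <- sample_field(state, ispec, derive_seed(w$seed, 1L))
      field <- render_field(sampled, ispec, derive_seed(w$seed, 2L))
      objects <- suppressWarnings(
        detect_objects(field, config$detection_params))
      if (!is.null(write_dir)) {
        img_path <- file.path(write_dir, paste0(w$well_id, ".tif"))
        write_field_tiff(field, img_path)
        images[i] <- img_path
      }
    } else {
      objects <- particles_to_object_table(state$particles,
                                           gain = ispec$gain,
                                           um_per_px = ispec$um_per_px)
    }
    tables[[i]] <- objects
    wells$n_objects[i] <- nrow(objects)
    if (!is.null(write_dir)) {
      write_object_table(objects,
                         file.path(write_dir, paste0(w$well_id, ".objects.csv")))
    }
    if (verbose) {
      message(sprintf("[well %s] role=%s E:T=%g seed=%d objects=%d supernatant=%.4g",
                      w$well_id, w$role, w$et_ratio, w$seed, nrow(objects),
                      wells$supernatant_fluorescence[i]))
    }
  }

  result <- summarize_plate(wells, tables,
                            gate_percentile_q = config$gate_percentile_q,
                            gate_min_diameter_um = config$gate_min_diameter_um)
  result$config <- config
  result$layout <- layout

  if (!is.null(write_dir)) {
    map <- data.frame(well_id = wells$well_id, role = wells$role,
                      et_ratio = wells$et_ratio,
                      image = ifelse(nzchar(images), basename(images), ""),
                      table = paste0(wells$well_id, ".objects.csv"),
                      supernatant_fluorescence = wells$supernatant_fluorescence,
                      stringsAsFactors = FALSE)
    write.csv(map, file.path(write_dir, "plate_map.csv"), row.names = FALSE)
    write_gate(result$gate, file.path(write_dir, "gate.json"))
    write_plate_result(result, write_dir)
  }
  result
}

# Shared downstream stage: gate from spontaneous wells, live counts, both
# percent-lysis formulas (controls averaged before the formulas), per-E:T
# medians and the paired method comparison.
summarize_plate <- function(wells, tables, gate_percentile_q = 5,
                            gate_min_diameter_um = 1) {
  spont_idx <- which(wells$role == "spontaneous")
  if (length(spont_idx) == 0L) {
    abort_gating("plate has no spontaneous wells; the live-cell gate cannot be derived")
  }
  gate <- derive_gate(tables[spont_idx], q = gate_percentile_q,
                      min_diameter_um = gate_min_diameter_um)
  wells$live_count <- vapply(tables, count_live, 1L, gate = gate)

  spont_count <- mean(wells$live_count[spont_idx])
  have_release <- !any(is.na(wells$supernatant_fluorescence))
  max_idx <- which(wells$role == "maximum")
  spont_release <- if (have_release) {
    mean(wells$supernatant_fluorescence[spont_idx])
  } else NA_real_
  max_release <- if (have_release && length(max_idx)) {
    mean(wells$supernatant_fluorescence[max_idx])
  } else NA_real_

  test_idx <- which(wells$role == "test")
  lysis <- list()
  for (i in test_idx) {
    imaging <- percent_lysis_imaging(spont_count, wells$live_count[i])
    lysis[[length(lysis) + 1L]] <- data.frame(
      well_id = wells$well_id[i], et_ratio = wells$et_ratio[i],
      method = "imaging", value = imaging, qc_flag = lysis_qc_flag(imaging),
      stringsAsFactors = FALSE)
    if (have_release && !is.na(max_release)) {
      release <- percent_lysis_release(wells$supernatant_fluorescence[i],
                                       spont_release, max_release)
      lysis[[length(lysis) + 1L]] <- data.frame(
        well_id = wells$well_id[i], et_ratio = wells$et_ratio[i],
        method = "release", value = release,
        qc_flag = lysis_qc_flag(release), stringsAsFactors = FALSE)
    }
  }
  lysis <- if (length(lysis)) do.call(rbind, lysis) else
    data.frame(well_id = character(), et_ratio = numeric(),
               method = character(), value = numeric(), qc_flag = logical())

  ets <- unique(wells$et_ratio[test_idx])
  summary_rows <- list(); comparisons <- list()
  for (et in ets) {
    rel <- lysis$value[lysis$et_ratio == et & lysis$method == "release"]
    img <- lysis$value[lysis$et_ratio == et & lysis$method == "imaging"]
    summary_rows[[length(summary_rows) + 1L]] <- data.frame(
      et_ratio = et,
      median_release = if (length(rel)) median(rel) else NA_real_,
      median_imaging = median(img), n_replicates = length(img))
    if (length(rel) == length(img) && length(rel) > 0L) {
      comparisons[[length(comparisons) + 1L]] <- compare_methods(rel, img, et)
    }
  }
  comp_df <- if (length(comparisons)) {
    do.call(rbind, lapply(comparisons, function(cm) data.frame(
      et_ratio = cm$et_ratio, median_release = cm$median_release,
      median_imaging = cm$median_imaging, W = cm$statistic,
      p_two_tailed = cm$p_value, n_pairs = cm$n_pairs)))
  } else {
    data.frame(et_ratio = numeric(), median_release = numeric(),
               median_imaging = numeric(), W = numeric(),
               p_two_tailed = numeric(), n_pairs = integer())
  }

  dr <- if (have_release && !is.na(max_release) && max_release > 0) {
    dynamic_range(max_release, spont_release)
  } else NULL

  structure(list(wells = wells, gate = gate, lysis = lysis,
                 summary = do.call(rbind, summary_rows),
                 comparisons = comp_df, dynamic_range = dr,
                 spontaneous_live_count = spont_count,
                 spontaneous_release = spont_release,
                 maximum_release = max_release),
            class = "plate_result")
}

#' @export
print.plate_result <- function(x, ...) {
  cat(sprintf("<plate_result> %d wells, gate >= %.4g counts / >= %.3g um\n",
              nrow(x$wells), x$gate$min_integrated_intensity,
              x$gate$min_diameter_um))
  if (!is.null(x$dynamic_range)) {
    cat(sprintf("  spontaneous release %.1f%% of maximum (dynamic range %.1f%%)\n",
                x$dynamic_range$spont_pct_of_max,
                x$dynamic_range$dynamic_range_pct))
  }
  cat("  percent specific lysis (medians):\n")
  print(x$summary, row.names = FALSE)
  if (nrow(x$comparisons)) {
    cat("  paired Wilcoxon, imaging vs release:\n")
    print(x$comparisons, row.names = FALSE)
  }
  invisible(x)
}

#' Write plate-result tables as CSV
#'
#' Writes `wells.csv`, `lysis.csv` (well_id, role, et_ratio, method, value,
#' qc_flag) and `comparison.csv` (et_ratio, median_release, median_imaging,
#' W, p_two_tailed, n_pairs).
#'
#' @param result a `plate_result`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_plate_result <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write.csv(result$wells, file.path(dir, "wells.csv"), row.names = FALSE)
  roles <- result$wells$role[match(result$lysis$well_id, result$wells$well_id)]
  lysis <- cbind(result$lysis[, "well_id", drop = FALSE], role = roles,
                 result$lysis[, c("et_ratio", "method", "value", "qc_flag")])
  write.csv(lysis, file.path(dir, "lysis.csv"), row.names = FALSE)
  write.csv(result$comparisons, file.path(dir, "comparison.csv"),
            row.names = FALSE)
  invisible(dir)
}

#' Read and write plate configurations
#'
#' A plate configuration serializes to YAML or JSON with nested
#' `assay_params`, `image_spec` and `detection_params` sections named
#' exactly as the constructor arguments.
#'
#' @param config a [plate_config()].
#' @param path file path (`.yaml`/`.yml` or `.json`).
#' @return `write_plate_config()` returns `path` invisibly;
#'   `read_plate_config()` the validated configuration.
#' @export
write_plate_config <- function(config, path) {
  lst <- unclass(config)
  lst$assay_params <- params_to_list(config$assay_params)
  lst$image_spec <- params_to_list(config$image_spec)
  lst$detection_params <- params_to_list(config$detection_params)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(lst, path)
  }
  invisible(path)
}

#' @rdname write_plate_config
#' @export
read_plate_config <- function(path) {
  lst <- read_params_list(path)
  if (!is.null(lst$assay_params)) {
    lst$assay_params$kill_frac_by_et <- unlist(lst$assay_params$kill_frac_by_et)
    lst$assay_params <- do.call(assay_params, lst$assay_params)
  }
  if (!is.null(lst$image_spec)) {
    lst$image_spec <- do.call(image_spec, lst$image_spec)
  }
  if (!is.null(lst$detection_params)) {
    lst$detection_params <- do.call(detection_params, lst$detection_params)
  }
  if (!is.null(lst$et_ratios)) lst$et_ratios <- unlist(lst$et_ratios)
  do.call(plate_config, lst)
}

#' Paired method comparison from a long lysis table
#'
#' @param lysis data frame with columns `well_id`, `et_ratio`, `method`
#'   (`"release"`/`"imaging"`) and `value`, as written by
#'   [write_plate_result()].
#' @return comparison data frame (`et_ratio`, `median_release`,
#'   `median_imaging`, `W`, `p_two_tailed`, `n_pairs`).
#' @export
compare_lysis_table <- function(lysis) {
  need <- c("well_id", "et_ratio", "method", "value")
  if (!all(need %in% names(lysis))) {
    abort_config("lysis table must have columns well_id, et_ratio, method, value")
  }
  out <- list()
  for (et in unique(lysis$et_ratio[lysis$method == "imaging"])) {
    sub <- lysis[lysis$et_ratio == et, ]
    rel <- sub$value[sub$method == "release"][order(sub$well_id[sub$method == "release"])]
    img <- sub$value[sub$method == "imaging"][order(sub$well_id[sub$method == "imaging"])]
    if (length(rel) != length(img) || length(rel) == 0L) next
    cm <- compare_methods(rel, img, et)
    out[[length(out) + 1L]] <- data.frame(
      et_ratio = et, median_release = cm$median_release,
      median_imaging = cm$median_imaging, W = cm$statistic,
      p_two_tailed = cm$p_value, n_pairs = cm$n_pairs)
  }
  if (!length(out)) abort_config("no paired release/imaging values found")
  do.call(rbind, out)
}

#' Analyze externally produced images or object tables
#'
#' Analysis-only entry point: takes a plate map identifying each well's
#' role, E:T ratio and its image (TIFF) or per-object measurement table
#' (CSV), and runs the pipeline from the detection stage onward — identical
#' to [run_plate()]'s downstream behaviour. When a well has a table it is
#' used directly (bypassing detection); otherwise the image is read and
#' objects detected. Release-based lysis is additionally computed when the
#' map carries a `supernatant_fluorescence` column with maximum wells
#' present.
#'
#' @param plate_map data frame or CSV path with columns `well_id`, `role`,
#'   `et_ratio`, and `image` and/or `table` (file paths, relative to `dir`);
#'   optional `supernatant_fluorescence`.
#' @param image_spec an [image_spec()] supplying pixel scale and bit depth
#'   for image input.
#' @param detection_params a [detection_params()].
#' @param gate_percentile_q,gate_min_diameter_um gate settings, as in
#'   [plate_config()].
#' @param dir base directory for relative paths in the map.
#' @param prefer `"table"` (default) or `"image"` when a well has both.
#' @return a `plate_result` (without simulation ground truth).
#' @export
analyze_images <- function(plate_map,
                           image_spec = calcytox::image_spec(),
                           detection_params = calcytox::detection_params(),
                           gate_percentile_q = 5,
                           gate_min_diameter_um = 1,
                           dir = ".",
                           prefer = c("table", "image")) {
  prefer <- match.arg(prefer)
  if (is.character(plate_map)) {
    dir <- dirname(plate_map)
    plate_map <- read.csv(plate_map, stringsAsFactors = FALSE)
  }
  need <- c("well_id", "role", "et_ratio")
  if (!all(need %in% names(plate_map))) {
    abort_config("plate map must have columns well_id, role, et_ratio")
  }
  if (!any(plate_map$role == "spontaneous")) {
    abort_gating("plate map lists no spontaneous wells; the live-cell gate cannot be derived")
  }
  has <- function(col, i) {
    col %in% names(plate_map) && !is.na(plate_map[[col]][i]) &&
      nzchar(plate_map[[col]][i])
  }
  n <- nrow(plate_map)
  tables <- vector("list", n)
  ok <- rep(TRUE, n)
  for (i in seq_len(n)) {
    use_table <- has("table", i) && (prefer == "table" || !has("image", i))
    res <- tryCatch({
      if (use_table) {
        suppressWarnings(read_object_table(file.path(dir, plate_map$table[i])))
      } else if (has("image", i)) {
        pix <- read_field_tiff(file.path(dir, plate_map$image[i]))
        suppressWarnings(detect_objects(pix, detection_params,
                                        um_per_px = image_spec$um_per_px,
                                        bit_depth = image_spec$bit_depth))
      } else {
        abort_config(sprintf("well %s has neither image nor table",
                             plate_map$well_id[i]))
      }
    }, error = function(e) {
      if (inherits(e, "calcytox_config_error")) stop(e)
      warning(sprintf("well %s: could not analyze input (%s); skipping",
                      plate_map$well_id[i], conditionMessage(e)))
      NULL
    })
    if (is.null(res)) ok[i] <- FALSE else tables[[i]] <- res
  }
  wells <- plate_map[ok, need, drop = FALSE]
  wells$supernatant_fluorescence <-
    if ("supernatant_fluorescence" %in% names(plate_map)) {
      as.numeric(plate_map$supernatant_fluorescence[ok])
    } else NA_real_
  if (!any(wells$role == "spontaneous")) {
    abort_gating("no spontaneous well could be analyzed; gate cannot be derived")
  }
  summarize_plate(wells, tables[ok], gate_percentile_q = gate_percentile_q,
                  gate_min_diameter_um = gate_min_diameter_um)
}
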