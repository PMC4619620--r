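# Plate-level execution, file round-trips and the analysis-only entry point.

small_plate_config <- function(...) {
  plate_config(assay_params = assay_params(kill_frac_by_et = c("1" = 0.6)),
               image_spec = image_spec(width_px = 384L, height_px = 384L,
                                       sampled_fraction = 0.05),
               et_ratios = 1, n_test_replicates = 2L,
               n_control_replicates = 2L, n_targets_per_well = 2000L,
               ...)
}

test_that("plate layout enumerates wells with derived seeds", {
  cfg <- plate_config(n_test_replicates = 3L, n_control_replicates = 6L,
                      counting_mode = "table")
  lay <- plate_layout(cfg)
  expect_equal(nrow(lay), 3 * 3 + 6 + 6)
  expect_equal(sum(lay$role == "test"), 9L)
  expect_equal(anyDuplicated(lay$well_id), 0L)
  expect_equal(anyDuplicated(lay$seed), 0L)
  expect_equal(lay$seed,
               vapply(lay$well_index, derive_seed, 1L,
                      master_seed = cfg$master_seed))
})

test_that("configuration errors surface before any simulation", {
  expect_error(plate_config(et_ratios = c(2, 1, 0.25), counting_mode = "table"),
               class = "calcytox_config_error")
  expect_error(plate_config(n_test_replicates = 0L, counting_mode = "table"),
               class = "calcytox_param_error")
})

test_that("plates are bitwise reproducible for a fixed master seed", {
  cfg <- small_plate_config(master_seed = 123L, counting_mode = "table")
  a <- run_plate(cfg)
  b <- run_plate(cfg)
  expect_identical(a$wells, b$wells)
  expect_identical(a$lysis, b$lysis)
  expect_identical(a$gate, b$gate)
  c2 <- run_plate(small_plate_config(master_seed = 124L,
                                     counting_mode = "table"))
  expect_false(identical(a$wells$supernatant_fluorescence,
                         c2$wells$supernatant_fluorescence))
})

test_that("with no killing configured both readouts sit at zero", {
  cfg <- plate_config(
    assay_params = assay_params(kill_frac_by_et = c("1" = 0)),
    et_ratios = 1, n_test_replicates = 3L, n_control_replicates = 3L,
    n_targets_per_well = 5000L, master_seed = 5L, counting_mode = "table")
  res <- run_plate(cfg)
  expect_lt(max(abs(res$lysis$value[res$lysis$method == "release"])), 2)
  expect_lt(max(abs(res$lysis$value[res$lysis$method == "imaging"])), 2)
})

test_that("halving target density leaves expected imaging lysis unchanged", {
  imaging_mean <- function(n, seed) {
    cfg <- plate_config(
      assay_params = assay_params(kill_frac_by_et = c("1" = 0.6)),
      et_ratios = 1, n_test_replicates = 3L, n_control_replicates = 3L,
      n_targets_per_well = n, master_seed = seed, counting_mode = "table")
    res <- run_plate(cfg)
    mean(res$lysis$value[res$lysis$method == "imaging"])
  }
  hi <- mean(vapply(1:3, function(s) imaging_mean(10000L, s), 1))
  lo <- mean(vapply(4:6, function(s) imaging_mean(5000L, s), 1))
  expect_lt(abs(hi - lo), 2)
})

test_that("run_plate artifacts round-trip and analysis reproduces its counts", {
  dir <- withr::local_tempdir()
  cfg <- small_plate_config(master_seed = 9L, counting_mode = "render")
  res <- run_plate(cfg, write_dir = dir)

  expect_true(file.exists(file.path(dir, "plate_map.csv")))
  expect_true(file.exists(file.path(dir, "gate.json")))
  expect_equal(read_gate(file.path(dir, "gate.json")), res$gate)

  # object-table route: identical downstream results
  again <- analyze_images(file.path(dir, "plate_map.csv"),
                          image_spec = cfg$image_spec,
                          detection_params = cfg$detection_params,
                          prefer = "table")
  expect_equal(again$wells$live_count,
               res$wells$live_count[match(again$wells$well_id,
                                          res$wells$well_id)])
  expect_equal(again$lysis$value, res$lysis$value)

  # image route: re-detection from the written TIFFs gives the same counts
  via_images <- analyze_images(file.path(dir, "plate_map.csv"),
                               image_spec = cfg$image_spec,
                               detection_params = cfg$detection_params,
                               prefer = "image")
  expect_equal(via_images$wells$live_count, again$wells$live_count)
  expect_equal(via_images$lysis$value, again$lysis$value)
})

test_that("analysis without spontaneous wells is a gating error", {
  map <- data.frame(well_id = "A", role = "test", et_ratio = 1,
                    table = "a.csv")
  expect_error(analyze_images(map), class = "calcytox_gating_error")
})

test_that("an unreadable well input warns and the run continues", {
  dir <- withr::local_tempdir()
  cfg <- small_plate_config(master_seed = 11L, counting_mode = "render")
  run_plate(cfg, write_dir = dir)
  map <- read.csv(file.path(dir, "plate_map.csv"))
  map$table[map$role == "test"][1] <- "missing.csv"
  expect_warning(
    res <- analyze_images(map, image_spec = cfg$image_spec, dir = dir,
                          prefer = "table"),
    "skipping")
  expect_equal(sum(res$wells$role == "test"), 1L)
})

test_that("plate result tables are written as CSV", {
  dir <- withr::local_tempdir()
  cfg <- small_plate_config(master_seed = 13L, counting_mode = "table")
  res <- run_plate(cfg, write_dir = dir)
  lys <- read.csv(file.path(dir, "lysis.csv"))
  expect_equal(names(lys),
               c("well_id", "role", "et_ratio", "method", "value", "qc_flag"))
  comp <- read.csv(file.path(dir, "comparison.csv"))
  expect_equal(names(comp), c("et_ratio", "median_release", "median_imaging",
                              "W", "p_two_tailed", "n_pairs"))
})

test_that("plate configurations round-trip through YAML and JSON", {
  cfg <- small_plate_config(master_seed = 21L, counting_mode = "table",
                            gate_percentile_q = 10)
  for (ext in c(".yaml", ".json")) {
    f <- withr::local_tempfile(fileext = ext)
    write_plate_config(cfg, f)
    expect_equal(read_plate_config(f), cfg)
  }
})

test_that("lysis tables support the standalone paired comparison", {
  cfg <- small_plate_config(master_seed = 23L, counting_mode = "table")
  res <- run_plate(cfg)
  comp <- compare_lysis_table(res$lysis)
  expect_equal(comp, res$comparisons)
  expect_error(compare_lysis_table(data.frame(x = 1)),
               class = "calcytox_config_error")
})

test_that("the command-line front end quantifies and compares results", {
  skip_on_os("windows")
  cli <- system.file("cli", "calcytox", package = "calcytox")
  skip_if(cli == "", "CLI script not installed")
  dir <- withr::local_tempdir()
  cfg <- small_plate_config(master_seed = 31L, counting_mode = "table")
  res <- run_plate(cfg, write_dir = dir)

  out2 <- file.path(dir, "requant")
  code <- system2("Rscript", c(cli, "quantify", "--map",
                               file.path(dir, "plate_map.csv"),
                               "--out", out2),
                  stdout = FALSE, stderr = FALSE)
  expect_equal(code, 0L)
  lys <- read.csv(file.path(out2, "lysis.csv"))
  expect_equal(lys$value, res$lysis$value)

  cmp_file <- file.path(dir, "cmp.csv")
  code <- system2("Rscript", c(cli, "compare", "--lysis",
                               file.path(out2, "lysis.csv"),
                               "--out", cmp_file),
                  stdout = FALSE, stderr = FALSE)
  expect_equal(code, 0L)
  expect_equal(read.csv(cmp_file)$p_two_tailed, res$comparisons$p_two_tailed)

  # a plate map without spontaneous wells exits with the gating code
  map <- read.csv(file.path(dir, "plate_map.csv"))
  bad <- file.path(dir, "bad_map.csv")
  write.csv(map[map$role == "test", ], bad, row.names = FALSE)
  code <- system2("Rscript", c(cli, "quantify", "--map", bad, "--out",
                               file.path(dir, "x")),
                  stdout = FALSE, stderr = FALSE)
  expect_equal(code, 3L)
})
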