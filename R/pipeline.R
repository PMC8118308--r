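# End-to-end orchestration: a JSON-configurable run (synthesize or load ->
# morphometry -> burden -> group statistics) with a reproducibility
# manifest, and a fixtures generator materializing the standard test scenes.

#' Default run configuration
#'
#' A two-group synthetic study mirroring the acquisition design the package
#' models: a control and an infected-like group of animals, several SHG
#' frames per animal, with the infected group's needle length scaled by
#' `length_multiplier` and its needle count by `density_multiplier`. Every
#' tunable of the morphometry and comparison stages is explicit here.
#'
#' @param seed top-level seed; per-image substreams are derived from it.
#' @param output_dir where results and the manifest are written.
#' @param groups list of two group specs: `n_animals`, `images_per_animal`,
#'   `length_multiplier`, `density_multiplier`.
#' @param field base [needle_field_params] values as a list.
#' @param morphometry a [morphometry_config].
#' @param comparison list: `metric`, `method`, `per_animal` (aggregate
#'   within animal before testing).
#' @return list of class `run_config`.
#' @export
default_run_config <- function(seed = 1L, output_dir = tempfile("crystalscope_run_"),
                               groups = list(
                                 control = list(n_animals = 2L, images_per_animal = 4L,
                                                length_multiplier = 1, density_multiplier = 1),
                                 infected = list(n_animals = 3L, images_per_animal = 3L,
                                                 length_multiplier = 0.67, density_multiplier = 1.5)),
                               field = list(image_shape = c(256L, 256L),
                                            pixel_size_um = 0.5, n_needles = 20L,
                                            width_px = 3, intensity_amplitude = 50,
                                            background_level = 10, noise_sd = 5,
                                            length_um = list(family = "GAMMA", shape = 4,
                                                             scale = 3, min = 5, max = 30)),
                               morphometry = morphometry_config(),
                               comparison = list(metric = "mean_length_um",
                                                 method = "mann_whitney",
                                                 per_animal = FALSE)) {
  structure(list(seed = as.integer(seed), output_dir = output_dir,
                 groups = groups, field = field, morphometry = morphometry,
                 comparison = comparison),
            class = "run_config")
}

#' Read a run configuration from JSON
#' @param path JSON file with the fields of [default_run_config()].
#' @export
read_run_config <- function(path) {
  stop_if(!file.exists(path), fmt("no such config file: %s", path))
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- default_run_config()
  for (f in intersect(names(raw), c("seed", "output_dir", "groups", "field",
                                    "comparison")))
    cfg[[f]] <- raw[[f]]
  if (!is.null(raw$morphometry))
    cfg$morphometry <- do.call(morphometry_config, as.list(raw$morphometry))
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

#' Run the end-to-end synthetic study pipeline
#'
#' Synthesizes the per-animal SHG fields of each group, runs morphometry on
#' every image, compares the configured metric between groups, writes
#' per-image results (JSON), an object table (CSV), the comparison
#' (`stats.json`) and a manifest with config echo, per-stage timings and
#' output checksums. Rerunning an identical config reproduces all numeric
#' outputs exactly.
#'
#' @param config a `run_config` (see [default_run_config()]), or the path to
#'   a JSON config.
#' @return the manifest, invisibly; side effect: files under
#'   `config$output_dir`.
#' @export
run_pipeline <- function(config = default_run_config()) {
  if (is.character(config)) config <- read_run_config(config)
  stop_if(!inherits(config, "run_config"), "config must be a run_config")
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  stop_if(!dir.exists(config$output_dir),
          fmt("cannot create output directory %s", config$output_dir))
  t0 <- Sys.time()
  timings <- list()
  warnings_log <- character(0)

  n_images <- sum(vapply(config$groups, function(g)
    g$n_animals * g$images_per_animal, numeric(1)))
  seeds <- derive_seeds(config$seed, n_images)
  si <- 0L

  results <- list(); animal_ids <- list()
  object_tables <- list()
  t_stage <- Sys.time()
  for (gname in names(config$groups)) {
    g <- config$groups[[gname]]
    res_g <- list(); ids_g <- character(0)
    for (an in seq_len(g$n_animals)) {
      for (im in seq_len(g$images_per_animal)) {
        si <- si + 1L
        fld <- config$field
        lm <- g$length_multiplier %||% 1
        if (identical(toupper(fld$length_um$family), "GAMMA"))
          fld$length_um$scale <- fld$length_um$scale * lm
        else if (identical(toupper(fld$length_um$family), "FIXED"))
          fld$length_um$value <- fld$length_um$value * lm
        if (!is.null(fld$length_um$min)) fld$length_um$min <- fld$length_um$min * lm
        if (!is.null(fld$length_um$max)) fld$length_um$max <- fld$length_um$max * lm
        fld$n_needles <- round((fld$n_needles) * (g$density_multiplier %||% 1))
        fld$seed <- seeds[si]
        params <- do.call(needle_field_params, fld)
        gen <- generate_needle_field(params)
        mr <- run_morphometry(gen$image, config$morphometry)
        res_g <- c(res_g, list(mr))
        ids_g <- c(ids_g, fmt("%s_animal%d", gname, an))
        tab <- mr$objects
        if (nrow(tab)) {
          tab$group <- gname; tab$animal <- an; tab$image <- im
          object_tables <- c(object_tables, list(tab))
        }
        jsonlite::write_json(
          list(group = gname, animal = an, image = im, seed = seeds[si],
               threshold = mr$threshold, n_objects_total = mr$n_objects_total,
               n_passed = mr$n_passed, n_failed_overlap = mr$n_failed_overlap,
               n_failed_size = mr$n_failed_size,
               density_per_mm2 = mr$density_per_mm2,
               mean_length_um = mr$length_summary$mean,
               analysis_area_mm2 = mr$analysis_area_mm2),
          file.path(config$output_dir,
                    fmt("morph_%s_a%d_i%d.json", gname, an, im)),
          auto_unbox = TRUE, digits = NA)
      }
    }
    results[[gname]] <- res_g
    animal_ids[[gname]] <- ids_g
  }
  timings$morphometry_s <- as.numeric(difftime(Sys.time(), t_stage, units = "secs"))

  t_stage <- Sys.time()
  obj_path <- file.path(config$output_dir, "objects.csv")
  all_obj <- do.call(rbind, object_tables)
  utils::write.csv(all_obj, obj_path, row.names = FALSE)
  cmp <- compare_study(results, metric = config$comparison$metric,
                       method = config$comparison$method,
                       animal_ids = if (isTRUE(config$comparison$per_animal))
                         animal_ids else NULL)
  stats_path <- file.path(config$output_dir, "stats.json")
  jsonlite::write_json(
    list(metric = cmp$metric, method = cmp$method, statistic = cmp$statistic,
         p_value = cmp$p_value, n_per_group = cmp$n_per_group,
         effect_direction = cmp$effect_direction,
         group_values = cmp$group_values),
    stats_path, auto_unbox = TRUE, digits = NA)
  timings$statistics_s <- as.numeric(difftime(Sys.time(), t_stage, units = "secs"))

  outputs <- list.files(config$output_dir, full.names = TRUE)
  outputs <- setdiff(outputs, file.path(config$output_dir, "manifest.json"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("crystalscope")),
    seed = config$seed,
    config = list(groups = config$groups, field = config$field,
                  morphometry = unclass(config$morphometry),
                  comparison = config$comparison),
    outputs = as.list(tools::md5sum(sort(outputs))),
    timings_s = timings,
    total_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    warnings = warnings_log)
  jsonlite::write_json(manifest, file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Materialize the standard synthetic test scenes
#'
#' Writes loadable fixtures with ground truth beside each: a disjoint needle
#' field and one with forced crossings (TIFF + truth JSON), hyperspectral
#' cubes on the CH-stretch and fingerprint axes (multi-page TIFF + sidecar +
#' class-map JSON), a reflectance section with masks, and the four reference
#' spectra as CSV on both axes.
#'
#' @param output_dir writable directory.
#' @param seed RNG seed; fixed seed gives identical fixtures everywhere.
#' @return character vector of the written paths, invisibly.
#' @export
make_fixtures <- function(output_dir, seed = 1L) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  stop_if(!dir.exists(output_dir), fmt("cannot create directory %s", output_dir))
  probe <- file.path(output_dir, ".write_probe")
  ok <- tryCatch({ writeLines("x", probe); TRUE }, error = function(e) FALSE)
  stop_if(!ok, fmt("directory %s is not writable", output_dir))
  unlink(probe)
  paths <- character(0)
  put <- function(p) { paths <<- c(paths, p); p }
  sds <- derive_seeds(seed, 4L)

  truth_json <- function(truth, path) {
    jsonlite::write_json(
      list(needles = truth$needles,
           crossing_pairs = if (nrow(truth$crossing_pairs))
             as.data.frame(truth$crossing_pairs) else list(),
           pixel_counts = vapply(truth$pixel_sets, nrow, integer(1))),
      path, auto_unbox = TRUE, digits = NA)
    path
  }

  f1 <- generate_needle_field(needle_field_params(
    image_shape = c(256L, 256L), n_needles = 15L,
    length_um = list(family = "FIXED", value = 10), noise_sd = 0, seed = sds[1L]))
  put(write_image(f1$image, file.path(output_dir, "needle_field_disjoint.tif")))
  put(truth_json(f1$truth, file.path(output_dir, "needle_field_disjoint_truth.json")))

  f2 <- generate_needle_field(needle_field_params(
    image_shape = c(256L, 256L), n_needles = 10L,
    length_um = list(family = "FIXED", value = 10), noise_sd = 0,
    n_forced_crossing_pairs = 2L, seed = sds[2L]))
  put(write_image(f2$image, file.path(output_dir, "needle_field_crossing.tif")))
  put(truth_json(f2$truth, file.path(output_dir, "needle_field_crossing_truth.json")))

  ch_axis <- wavenumber_axis(2825, 3075, 5)
  fp_axis <- wavenumber_axis(1600, 1800, 2)
  classes <- matrix("BACKGROUND", 16L, 16L)
  classes[1:8, 1:8] <- "CE_CRYSTAL_LINOLEATE"
  classes[1:8, 9:16] <- "FC_CRYSTAL"
  classes[9:16, 1:8] <- "PROTEIN"
  classes[9:16, 9:16] <- "AMORPHOUS_LIPID"
  for (ax in list(list(axis = ch_axis, tag = "ch"),
                  list(axis = fp_axis, tag = "fingerprint"))) {
    gc_ <- generate_cube(spectral_scene(classes, noise_sd = 0.01, seed = sds[3L]),
                         ax$axis)
    cube_path <- file.path(output_dir, fmt("cube_%s.tif", ax$tag))
    put(write_cube(gc_$cube, cube_path))
    put(sidecar_path_for(cube_path))
    jsonlite::write_json(list(class_map = classes),
                         put(file.path(output_dir,
                                       fmt("cube_%s_truth.json", ax$tag))),
                         auto_unbox = TRUE, digits = NA)
    for (sp in REFERENCE_SPECIES)
      put(write_spectrum(synth_reference_spectrum(sp, ax$axis),
                         file.path(output_dir,
                                   fmt("ref_%s_%s.csv", tolower(sp), ax$tag))))
  }

  rf <- generate_reflectance_section(seed = sds[4L])
  put(write_image(rf$image, file.path(output_dir, "reflectance_section.tif")))
  jsonlite::write_json(
    list(plaque_pixels = sum(rf$plaque_mask), crystal_pixels = sum(rf$crystal_mask),
         crystal_fraction = sum(rf$crystal_mask) / sum(rf$plaque_mask)),
    put(file.path(output_dir, "reflectance_section_truth.json")),
    auto_unbox = TRUE, digits = NA)

  invisible(paths)
}
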