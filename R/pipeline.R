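#' Default pipeline configuration
#'
#' One block per stage. Mask thresholds, the 100-pixel component filter and
#' the 50 active-contour iterations are the pipeline's standard published
#' defaults; scene, camera and design parameters are the synthetic study
#' conditions. Scene leaf color tracks each plant's phenotype: the HSV
#' value (lightness) of its blades is an affine function of the plant's
#' noise-free linear predictor, so the imaging chain carries the known
#' effect structure through to the statistics.
#'
#' @param seed Integer master seed; per-plant seeds are derived from it.
#' @param n_per_cell Plants per variety x water x treatment cell.
#' @return Nested configuration list of class \code{run_config}.
#' @export
default_config <- function(seed = 1L, n_per_cell = 2L) {
  structure(list(
    seed = as.integer(seed),
    design = list(n_per_cell = as.integer(n_per_cell)),
    scene = list(size = c(200L, 288L), n_leaves = c(3L, 10L),
                 sat_range = c(0.45, 0.75),
                 hue_base = c(0.19, 0.33),
                 hue_jitter = 0.025,
                 value_span = c(0.32, 0.70)),
    camera = list(bayer_pattern = "RGGB", black_level = 512L,
                  white_level = 65535L, wb_gains = c(r = 1.9, b = 1.6),
                  camera_matrix = rbind(c(0.96, 0.03, 0.01),
                                        c(0.03, 0.95, 0.02),
                                        c(0.01, 0.04, 0.95)),
                  distortion_M = rbind(c(1.030, -0.015, 0.005),
                                       c(-0.010, 1.025, -0.008),
                                       c(0.004, -0.015, 1.020)),
                  distortion_b = c(0.008, -0.006, 0.004),
                  noise_sd = 0.002),
    mask = unclass(mask_params()),
    develop = list(quantize = TRUE),
    stats = list(response = "PC1")),
    class = "run_config")
}

#' Validate a pipeline configuration
#'
#' Checks threshold ranges, factor-level spellings, design sizes and
#' camera invariants, returning a machine-readable violation list (empty
#' when the configuration is valid) rather than raising on first failure.
#'
#' @param config A configuration list (see [default_config()]).
#' @return Character vector of violations, each naming the offending field;
#'   length 0 for a valid configuration.
#' @export
validate_config <- function(config) {
  v <- character()
  bad <- function(msg) v[[length(v) + 1L]] <<- msg
  rng01 <- function(x) all(is.finite(x)) && all(x >= 0) && all(x <= 1)

  if (is.null(config$seed) || is.na(config$seed)) bad("seed: missing")
  if (is.null(config$design$n_per_cell) || config$design$n_per_cell < 1) {
    bad("design$n_per_cell: must be >= 1")
  }
  m <- config$mask
  if (!is.null(m)) {
    if (!rng01(m$hue_ranges)) bad("mask$hue_ranges: bounds must lie in [0, 1]")
    if (!rng01(m$sat_range)) bad("mask$sat_range: bounds must lie in [0, 1]")
    if (!rng01(m$val_range)) bad("mask$val_range: bounds must lie in [0, 1]")
    if (!rng01(m$refine_sat_range)) {
      bad("mask$refine_sat_range: bounds must lie in [0, 1]")
    }
    if (!is.null(m$min_component_px) && m$min_component_px < 1) {
      bad("mask$min_component_px: must be >= 1")
    }
    if (!is.null(m$ac_iterations) && m$ac_iterations < 0) {
      bad("mask$ac_iterations: must be >= 0")
    }
    if (!is.null(m$connectivity) && !m$connectivity %in% c(4, 8)) {
      bad("mask$connectivity: must be 4 or 8")
    }
  }
  cam <- config$camera
  if (!is.null(cam)) {
    if (!cam$bayer_pattern %in% BAYER_PATTERNS) {
      bad(paste0("camera$bayer_pattern: must be one of ",
                 paste(BAYER_PATTERNS, collapse = ", ")))
    }
    if (cam$black_level >= cam$white_level) {
      bad("camera$black_level: must be below camera$white_level")
    }
    if (!is.null(cam$noise_sd) && cam$noise_sd < 0) {
      bad("camera$noise_sd: must be >= 0")
    }
  }
  if (!is.null(config$design$varieties) &&
      !all(config$design$varieties %in% VARIETY_LEVELS)) {
    bad(paste0("design$varieties: unknown level(s) ",
               paste(setdiff(config$design$varieties, VARIETY_LEVELS),
                     collapse = ", "),
               "; allowed: ", paste(VARIETY_LEVELS, collapse = ", ")))
  }
  v
}

#' Read a configuration from YAML
#'
#' Blocks present in the file override the matching entries of
#' [default_config()]; everything else keeps its default.
#'
#' @param path YAML file.
#' @return \code{run_config} list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  config <- default_config()
  for (block in names(user)) {
    if (is.list(user[[block]]) && is.list(config[[block]])) {
      for (fld in names(user[[block]])) config[[block]][[fld]] <- user[[block]][[fld]]
    } else {
      config[[block]] <- user[[block]]
    }
  }
  config
}

#' Run the full synthetic-study pipeline
#'
#' Simulate, develop, segment, quantify, analyse: generates the factorial
#' phenotype table, renders one scene per plant-harvest record with leaf
#' lightness tied to the record's linear predictor, pushes each scene
#' through the camera model and the development + segmentation +
#' median-RGB chain, fits the uncentered PCA, and runs the group
#' comparisons and the color-intensity linear model with its single-term
#' deletion table. A plant whose mask comes back empty is recorded and
#' skipped, never fatal.
#'
#' @param config A [default_config()]-style list.
#' @param out_dir Optional directory; when given, the scored table, the two
#'   statistics tables, the PCA model and the run manifest are written
#'   there as CSV/JSON.
#' @return List with \code{table} (scored plant table), \code{pca},
#'   \code{harvest_comparisons}, \code{water_comparisons}, \code{model},
#'   \code{drop1}, \code{shapiro}, and \code{manifest} (parameter snapshot,
#'   per-plant status, output hashes).
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL) {
  violations <- validate_config(config)
  if (length(violations)) {
    stop("invalid configuration:\n  - ", paste(violations, collapse = "\n  - "))
  }
  chart <- make_reference_chart()
  params <- do.call(mask_params, config$mask[names(config$mask) %in%
    names(formals(mask_params))])
  pheno <- generate_phenotype_table(config$design$n_per_cell,
                                    seed = config$seed)
  eta <- pheno$linear_predictor
  # map the linear predictor onto blade lightness (HSV value)
  vspan <- config$scene$value_span
  vmid <- vspan[1] + (vspan[2] - vspan[1]) *
    (eta - min(eta)) / max(max(eta) - min(eta), 1e-9)

  cam_cfg <- config$camera
  status <- character(nrow(pheno))
  pixel_sets <- vector("list", nrow(pheno))
  names(pixel_sets) <- paste(pheno$plant_id, pheno$harvest, sep = ":")
  truth_med <- matrix(NA_real_, nrow(pheno), 3L)
  iou <- rep(NA_real_, nrow(pheno))
  for (i in seq_len(nrow(pheno))) {
    seed_i <- (config$seed * 1000L + i) %% .Machine$integer.max
    n_leaves <- config$scene$n_leaves[1] +
      (seed_i %% (config$scene$n_leaves[2] - config$scene$n_leaves[1] + 1L))
    # one plant's leaves share pigmentation: a per-plant base hue with small
    # between-leaf jitter, and lightness tracking the linear predictor
    hmid <- local_rng(seed_i + 7L, stats::runif(1, config$scene$hue_base[1],
                                                config$scene$hue_base[2]))
    spec <- list(h = hmid + c(-1, 1) * config$scene$hue_jitter,
                 s = config$scene$sat_range,
                 v = pmin(pmax(c(vmid[i] - 0.04, vmid[i] + 0.04), 0.05), 0.95))
    scene <- render_scene(n_leaves = n_leaves, leaf_color_spec = spec,
                          size = config$scene$size, chart = chart,
                          seed = seed_i)
    cam <- camera_model(bayer_pattern = cam_cfg$bayer_pattern,
                        black_level = cam_cfg$black_level,
                        white_level = cam_cfg$white_level,
                        wb_gains = cam_cfg$wb_gains,
                        camera_matrix = cam_cfg$camera_matrix,
                        color_distortion = affine_color_map(
                          cam_cfg$distortion_M, cam_cfg$distortion_b),
                        noise_sd = cam_cfg$noise_sd, seed = seed_i + 1L)
    cfa <- apply_camera_model(scene$image, cam)
    dev <- develop(cfa, scene$truth$chart$corners, chart,
                   quantize = config$develop$quantize)
    seg <- segment_leaves(dev$image, params)
    pixel_sets[[i]] <- seg
    status[i] <- if (seg$empty) "empty-mask" else "ok"
    tm <- scene$truth$true_leaf_mask
    if (any(tm)) {
      truth_med[i, ] <- apply(scene$image, 3, function(p) stats::median(p[tm]))
      iou[i] <- sum(seg$mask & tm) / sum(seg$mask | tm)
    }
  }

  pheno$true_median_r <- truth_med[, 1]
  pheno$true_median_g <- truth_med[, 2]
  pheno$true_median_b <- truth_med[, 3]
  pheno$mask_iou <- iou
  table <- build_color_table(pheno, pixel_sets)
  scored <- score_color_table(table)
  tab <- scored$table

  shapiro <- lapply(c(PC1 = "PC1", PC2 = "PC2", PC3 = "PC3"),
                    function(ax) shapiro_wilk(tab[[ax]]))
  harvest_cmp <- do.call(rbind, lapply(WATER_LEVELS, function(w) {
    sub <- tab[tab$water_status == w, ]
    cbind(water_status = w,
          compare_groups(sub, "harvest", "plant_id"))
  }))
  water_cmp <- do.call(rbind, lapply(HARVEST_LEVELS, function(h) {
    sub <- tab[tab$harvest == h, ]
    cbind(harvest = h,
          compare_groups(sub, "water_status", "stratum"))
  }))
  model <- fit_color_model(tab, response = config$stats$response)
  dtab <- drop1_anova(model)

  manifest <- list(seed = config$seed,
                   parameters = config,
                   assumed_defaults = c("camera$bayer_pattern",
                                        "camera$black_level",
                                        "mask$connectivity",
                                        "scene$size"),
                   n_records = nrow(tab),
                   plant_status = stats::setNames(status, names(pixel_sets)),
                   n_empty = sum(status == "empty-mask"))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(
      scored_table = file.path(out_dir, "plant_table_scored.csv"),
      harvest_comparisons = file.path(out_dir, "comparisons_harvest.csv"),
      water_comparisons = file.path(out_dir, "comparisons_water.csv"),
      drop1 = file.path(out_dir, "model_drop1.csv"),
      pca = file.path(out_dir, "pca_model.json"))
    utils::write.csv(tab, paths["scored_table"], row.names = FALSE)
    utils::write.csv(harvest_cmp, paths["harvest_comparisons"], row.names = FALSE)
    utils::write.csv(water_cmp, paths["water_comparisons"], row.names = FALSE)
    utils::write.csv(dtab, paths["drop1"], row.names = FALSE)
    jsonlite::write_json(list(loadings = scored$pca$loadings,
                              variance_explained = scored$pca$variance_explained,
                              n = scored$pca$n),
                         paths["pca"], digits = NA)
    manifest$outputs <- as.list(tools::md5sum(unname(paths)))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }

  list(table = tab, pca = scored$pca, harvest_comparisons = harvest_cmp,
       water_comparisons = water_cmp, model = model, drop1 = dtab,
       shapiro = shapiro, manifest = manifest)
}
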