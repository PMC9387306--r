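#!/usr/bin/env Rscript
# Stage 1: simulate the study's inputs.
#
# Generates the factorial phenotype table (4 varieties x 2 water statuses x
# 2 climate treatments x 2 harvests) and, for every plant-harvest record,
# renders a ground-truthed leaf-on-white scene and photographs it through
# the forward camera model into a raw CFA frame. Frames and truth masks are
# binary scratch output; the tables that downstream stages and the reader
# need go under results/.

suppressMessages(library(ryecolor))

seed <- 1L
cfg <- default_config(seed = seed, n_per_cell = 1L)
frame_dir <- "scratch/analysis/frames"
dir.create(frame_dir, recursive = TRUE, showWarnings = FALSE)
dir.create("results", showWarnings = FALSE)

pheno <- generate_phenotype_table(cfg$design$n_per_cell, seed = seed)
utils::write.csv(pheno, "results/phenotypes.csv", row.names = FALSE)

chart <- make_reference_chart()
eta <- pheno$linear_predictor
vspan <- cfg$scene$value_span
vmid <- vspan[1] + (vspan[2] - vspan[1]) * (eta - min(eta)) /
  max(max(eta) - min(eta), 1e-9)

index <- data.frame()
for (i in seq_len(nrow(pheno))) {
  seed_i <- seed * 1000L + i
  set.seed(seed_i + 7L)
  hmid <- stats::runif(1, cfg$scene$hue_base[1], cfg$scene$hue_base[2])
  spec <- list(h = hmid + c(-1, 1) * cfg$scene$hue_jitter,
               s = cfg$scene$sat_range,
               v = pmin(pmax(c(vmid[i] - 0.04, vmid[i] + 0.04), 0.05), 0.95))
  n_leaves <- cfg$scene$n_leaves[1] +
    (seed_i %% (cfg$scene$n_leaves[2] - cfg$scene$n_leaves[1] + 1L))
  sc <- render_scene(n_leaves = n_leaves, leaf_color_spec = spec,
                     size = cfg$scene$size, chart = chart, seed = seed_i)
  cam <- camera_model(bayer_pattern = cfg$camera$bayer_pattern,
                      black_level = cfg$camera$black_level,
                      white_level = cfg$camera$white_level,
                      wb_gains = cfg$camera$wb_gains,
                      camera_matrix = cfg$camera$camera_matrix,
                      color_distortion = affine_color_map(
                        cfg$camera$distortion_M, cfg$camera$distortion_b),
                      noise_sd = cfg$camera$noise_sd, seed = seed_i + 1L)
  cfa <- apply_camera_model(sc$image, cam)
  key <- sprintf("%s_%s", pheno$plant_id[i], pheno$harvest[i])
  tif <- file.path(frame_dir, paste0(key, ".tif"))
  write_cfa(cfa, tif, chart_corners = sc$truth$chart$corners)
  write_mask_png(sc$truth$true_leaf_mask,
                 file.path(frame_dir, paste0(key, "_truth.png")))
  tm <- sc$truth$true_leaf_mask
  tmed <- apply(sc$image, 3, function(p) stats::median(p[tm]))
  index <- rbind(index, data.frame(
    plant_id = pheno$plant_id[i], harvest = pheno$harvest[i],
    frame = tif, n_leaves = n_leaves, truth_px = sum(tm),
    true_median_r = tmed[1], true_median_g = tmed[2], true_median_b = tmed[3]))
}
utils::write.csv(index, "results/frame_index.csv", row.names = FALSE)

cat(sprintf(
  "Simulated %d plant-harvest records (%d plants, 2 harvests each).\n",
  nrow(pheno), length(unique(pheno$plant_id))))
cat(sprintf("Raw frames: %s (%d x %d, %s mosaic, black %d, white %d)\n",
            frame_dir, cfg$scene$size[1], cfg$scene$size[2],
            cfg$camera$bayer_pattern, cfg$camera$black_level,
            cfg$camera$white_level))
cat("Tables: results/phenotypes.csv, results/frame_index.csv\n")
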