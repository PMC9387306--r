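#!/usr/bin/env Rscript
# Stage 4: reduce leaf pixels to per-plant median RGB and extract the
# color-intensity axis.
#
# Joins the imaging output to the phenotype table, fits the uncentered,
# unscaled PCA of the median RGB matrix, and scores every record. The
# first axis is the "color intensity": all-positive loadings, so higher
# scores are lighter leaves.

suppressMessages(library(ryecolor))

pheno <- utils::read.csv("results/phenotypes.csv")
pheno$harvest <- factor(pheno$harvest, levels = c("DAS72", "DAS101"))
pheno$variety <- factor(pheno$variety,
                        levels = c("Aberchoice", "Abergain", "Carraig",
                                   "Dunluce"))
pheno$water_status <- factor(pheno$water_status, levels = c("logged", "normal"))
pheno$treatment <- factor(pheno$treatment, levels = c("ambient", "climate2050"))
index <- utils::read.csv("results/frame_index.csv")

keys <- sub("\\.tif$", "", basename(index$frame))
pixel_sets <- lapply(keys, function(k) {
  utils::read.csv(file.path("scratch/analysis/pixels", paste0(k, ".csv")))
})
names(pixel_sets) <- paste(index$plant_id, index$harvest, sep = ":")

tab <- build_color_table(pheno, pixel_sets)
scored <- score_color_table(tab)
utils::write.csv(scored$table, "results/plant_table_scored.csv",
                 row.names = FALSE)
jsonlite::write_json(list(loadings = scored$pca$loadings,
                          variance_explained = scored$pca$variance_explained,
                          n = scored$pca$n),
                     "results/pca_model.json", digits = NA)

ve <- 100 * scored$pca$variance_explained
cat(sprintf("Uncentered PCA of %d median-RGB records.\n", scored$pca$n))
cat(sprintf("Variance explained: PC1 %.1f%%, PC2 %.1f%%, PC3 %.1f%%\n",
            ve[1], ve[2], ve[3]))
cat("PC1 loadings (all positive -> a lightness axis):",
    paste(sprintf("%.3f", scored$pca$loadings[, 1]), collapse = ", "), "\n")
cat("Tables: results/plant_table_scored.csv, results/pca_model.json\n")
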