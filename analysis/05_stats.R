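#!/usr/bin/env Rscript
# Stage 5: the statistical layer.
#
# Normality screen of the PC axes, paired rank comparisons between
# harvests (within water status) and between water statuses (within
# harvest), and the linear model of color intensity on phenotypic,
# environmental, genetic and temporal predictors with its single-term
# deletion (Type II) ANOVA and AIC table.

suppressMessages(library(ryecolor))

tab <- utils::read.csv("results/plant_table_scored.csv")
for (f in c("variety", "water_status", "treatment")) tab[[f]] <- factor(tab[[f]])
tab$harvest <- factor(tab$harvest, levels = c("DAS72", "DAS101"))

sw <- vapply(c("PC1", "PC2", "PC3"),
             function(ax) unlist(shapiro_wilk(tab[[ax]])), numeric(2))
cat("Shapiro-Wilk screen (W, p):\n")
print(round(t(sw), 4))

harvest_cmp <- do.call(rbind, lapply(levels(tab$water_status), function(w) {
  cbind(water_status = w,
        compare_groups(tab[tab$water_status == w, ], "harvest", "plant_id"))
}))
water_cmp <- do.call(rbind, lapply(levels(tab$harvest), function(h) {
  cbind(harvest = h,
        compare_groups(tab[tab$harvest == h, ], "water_status", "stratum"))
}))
utils::write.csv(harvest_cmp, "results/comparisons_harvest.csv",
                 row.names = FALSE)
utils::write.csv(water_cmp, "results/comparisons_water.csv",
                 row.names = FALSE)

cat("\nHarvest comparisons (within water status):\n")
print(harvest_cmp[harvest_cmp$axis == "PC1",
                  c("water_status", "z", "tau", "p_tau", "V", "p_V")],
      digits = 3)

fit <- fit_color_model(tab)
dt <- drop1_anova(fit)
utils::write.csv(dt, "results/model_drop1.csv", row.names = FALSE)
jsonlite::write_json(list(
  adj_r2_pct = 100 * fit$adj_r_squared,
  residual_df = fit$residual_df, rss = fit$rss,
  coefficients = as.data.frame(fit$coefficients)),
  "results/model_summary.json", digits = NA, force = TRUE)

cat(sprintf("\nColor-intensity model: %d records, %d residual df, adjusted R^2 %.1f%%\n",
            nrow(fit$data), fit$residual_df, 100 * fit$adj_r_squared))
cat("Single-term deletions (Type II ANOVA + AIC):\n")
print(dt, digits = 4)
cat("Tables: results/comparisons_{harvest,water}.csv, results/model_drop1.csv,",
    "results/model_summary.json\n")
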