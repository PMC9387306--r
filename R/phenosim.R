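VARIETY_LEVELS <- c("Aberchoice", "Abergain", "Carraig", "Dunluce")
WATER_LEVELS <- c("logged", "normal")
TREATMENT_LEVELS <- c("ambient", "climate2050")
HARVEST_LEVELS <- c("DAS72", "DAS101")

#' Ground-truth effect structure for synthetic phenotype tables
#'
#' Defines the linear model that generates the color-intensity response in
#' [generate_phenotype_table()]. The response lives on the scale of the
#' first principal component of 8-bit median RGB (roughly 100-400 units):
#' higher values are lighter leaves. Signs follow the biology of
#' waterlogged ryegrass: heavier, taller, chlorophyll-rich (high SPAD)
#' plants are darker (negative coefficients); wetter soil and the warmer
#' high-CO2 treatment lighten leaves; the diploid reference variety
#' Aberchoice is lightest and the season's second harvest is darker.
#'
#' @param intercept Baseline response for the reference levels.
#' @param beta_biomass,beta_height,beta_spad,beta_moisture Slopes per g,
#'   cm, SPAD unit and soil-moisture percentage point.
#' @param treatment_offsets,variety_offsets,month_offsets Named offsets;
#'   the first (reference) level of each factor must be 0.
#' @param residual_sd Gaussian residual standard deviation (>= 0).
#' @param covariate_ranges List of length-2 ranges for \code{biomass_g},
#'   \code{height_cm}, \code{spad}, \code{soil_moisture_pct}.
#' @return Object of class \code{phenotype_effects}.
#' @export
phenotype_effects <- function(intercept = 200,
                              beta_biomass = -6,
                              beta_height = -0.8,
                              beta_spad = -2.5,
                              beta_moisture = 0.9,
                              treatment_offsets = c(ambient = 0, climate2050 = 10),
                              variety_offsets = c(Aberchoice = 0, Abergain = -8,
                                                  Carraig = -16, Dunluce = -12),
                              month_offsets = c(DAS72 = 0, DAS101 = -5),
                              residual_sd = 11,
                              covariate_ranges = list(
                                biomass_g = c(0.5, 6),
                                height_cm = c(15, 60),
                                spad = c(8, 45),
                                soil_moisture_pct = c(15, 60))) {
  stopifnot(residual_sd >= 0)
  for (off in list(treatment_offsets, variety_offsets, month_offsets)) {
    if (off[[1]] != 0) stop("the first (reference) level of each factor ",
                            "must have offset 0")
  }
  stopifnot(identical(sort(names(variety_offsets)), sort(VARIETY_LEVELS)),
            identical(names(treatment_offsets), TREATMENT_LEVELS),
            identical(names(month_offsets), HARVEST_LEVELS))
  structure(list(intercept = intercept, beta_biomass = beta_biomass,
                 beta_height = beta_height, beta_spad = beta_spad,
                 beta_moisture = beta_moisture,
                 treatment_offsets = treatment_offsets,
                 variety_offsets = variety_offsets,
                 month_offsets = month_offsets,
                 residual_sd = residual_sd,
                 covariate_ranges = covariate_ranges),
            class = "phenotype_effects")
}

#' Generate a factorial phenotype table with known effects
#'
#' Emulates the experiment's design: 4 varieties x 2 water statuses x 2
#' climate treatments x 2 harvests, with \code{n_per_cell} plants per cell
#' of the variety x water x treatment design measured at both harvests
#' (each plant appears once per harvest, so the table has
#' \code{4 * 2 * 2 * 2 * n_per_cell} rows; \code{n_per_cell = 20} gives the
#' study's 320 plants and 640 records). Covariates are drawn uniformly in
#' the effect structure's ranges and the response is the linear predictor
#' plus Gaussian noise.
#'
#' @param n_per_cell Plants per variety x water x treatment cell (>= 1).
#' @param effects A [phenotype_effects()] object.
#' @param seed Integer seed.
#' @return Data frame with columns \code{plant_id}, \code{stratum} (pairs a
#'   logged with a normal plant of the same variety, treatment and
#'   replicate), factor columns, covariates, \code{response}, and
#'   \code{linear_predictor} (the noise-free truth). The generating
#'   [phenotype_effects()] object is attached as attribute \code{"effects"}.
#' @export
generate_phenotype_table <- function(n_per_cell, effects = phenotype_effects(),
                                     seed = 1L) {
  stopifnot(inherits(effects, "phenotype_effects"), n_per_cell >= 1)
  design <- expand.grid(
    harvest = factor(HARVEST_LEVELS, levels = HARVEST_LEVELS),
    rep = seq_len(n_per_cell),
    treatment = factor(TREATMENT_LEVELS, levels = TREATMENT_LEVELS),
    water_status = factor(WATER_LEVELS, levels = WATER_LEVELS),
    variety = factor(VARIETY_LEVELS, levels = VARIETY_LEVELS),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  design$plant_id <- sprintf("%s_%s_%s_r%02d",
                             abbreviate(as.character(design$variety), 5),
                             substr(as.character(design$water_status), 1, 4),
                             substr(as.character(design$treatment), 1, 4),
                             design$rep)
  design$stratum <- sprintf("%s_%s_r%02d",
                            abbreviate(as.character(design$variety), 5),
                            substr(as.character(design$treatment), 1, 4),
                            design$rep)
  n <- nrow(design)
  rng <- effects$covariate_ranges
  local_rng(seed, {
    design$biomass_g <- stats::runif(n, rng$biomass_g[1], rng$biomass_g[2])
    design$height_cm <- stats::runif(n, rng$height_cm[1], rng$height_cm[2])
    design$spad <- stats::runif(n, rng$spad[1], rng$spad[2])
    design$soil_moisture_pct <- stats::runif(n, rng$soil_moisture_pct[1],
                                             rng$soil_moisture_pct[2])
    eta <- effects$intercept +
      effects$beta_biomass * design$biomass_g +
      effects$beta_height * design$height_cm +
      effects$beta_spad * design$spad +
      effects$beta_moisture * design$soil_moisture_pct +
      effects$treatment_offsets[as.character(design$treatment)] +
      effects$variety_offsets[as.character(design$variety)] +
      effects$month_offsets[as.character(design$harvest)]
    design$linear_predictor <- as.numeric(eta)
    design$response <- design$linear_predictor +
      stats::rnorm(n, 0, effects$residual_sd)
  })
  out <- design[, c("plant_id", "stratum", "variety", "water_status",
                    "treatment", "harvest", "biomass_g", "height_cm", "spad",
                    "soil_moisture_pct", "linear_predictor", "response")]
  rownames(out) <- NULL
  attr(out, "effects") <- effects
  out
}
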