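test_that("Shapiro-Wilk wrapper matches the published coefficient approximation", {
  x12 <- c(2.1, 3.4, 1.9, 5.6, 4.4, 3.3, 2.8, 6.1, 0.9, 3.0, 4.8, 2.2)
  got <- shapiro_wilk(x12)
  expect_equal(got$W, shapiro_w_oracle(x12), tolerance = 1e-6)
  expect_gt(got$W, 0); expect_lte(got$W, 1)

  set.seed(61)
  for (n in c(8, 30, 200)) {
    x <- rlnorm(n)
    w <- shapiro_wilk(x)$W
    expect_gt(w, 0); expect_lte(w, 1)
  }
  expect_error(shapiro_wilk(rep(1, 10)), "constant")
  expect_error(shapiro_wilk(c(1, 2)), "3 <= n")
})

test_that("Kendall test hits the exact bounds and the tie-adjusted oracle", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(kendall_tau_test(x, x * 2 + 1)$tau, 1)
  expect_equal(kendall_tau_test(x, rev(x))$tau, -1)

  # fixture with a tie in each vector
  xt <- c(1.0, 2.0, 2.0, 3.0, 4.0)
  yt <- c(2.1, 1.4, 3.3, 3.3, 4.0)
  got <- kendall_tau_test(xt, yt)
  orc <- kendall_oracle(xt, yt)
  expect_equal(got$tau, orc$tau, tolerance = 1e-12)
  expect_equal(got$z, orc$z, tolerance = 1e-10)
  expect_equal(got$p, orc$p, tolerance = 1e-10)

  set.seed(62)
  for (k in 1:5) {
    a <- sample(1:8, 12, replace = TRUE)
    b <- sample(1:8, 12, replace = TRUE)
    got <- kendall_tau_test(a, b)
    orc <- kendall_oracle(a, b)
    expect_equal(got$tau, orc$tau, tolerance = 1e-12)
    expect_equal(got$z, orc$z, tolerance = 1e-8)
  }
  expect_error(kendall_tau_test(1:3, 1:4), "paired")
})

test_that("rank tests are invariant under strictly monotone transforms", {
  set.seed(63)
  x <- rnorm(30); y <- x + rnorm(30)
  f <- function(v) exp(v / 2)
  k1 <- kendall_tau_test(x, y); k2 <- kendall_tau_test(f(x), f(y))
  expect_equal(k1$tau, k2$tau, tolerance = 1e-12)
  expect_equal(k1$p, k2$p, tolerance = 1e-12)
})

test_that("Wilcoxon signed-rank matches closed forms and exact enumeration", {
  x <- c(5, 6, 7, 8, 9); y <- c(1, 2, 3, 4, 5)
  expect_equal(wilcoxon_signed_rank(x, y)$V, 15)
  expect_equal(wilcoxon_signed_rank(y, x)$V, 0)

  set.seed(64)
  d8 <- c(1.3, -0.4, 2.2, 0.7, -1.8, 0.2, 3.1, -0.9)
  got <- wilcoxon_signed_rank(d8 + 10, rep(10, 8))
  orc <- wilcoxon_oracle(d8)
  expect_true(got$exact)
  expect_equal(got$V, orc$V)
  expect_equal(got$p, orc$p, tolerance = 1e-12)

  # zeros dropped, large n switches to the corrected normal approximation
  xz <- c(0, 0, rnorm(40)); yz <- rep(0, 42)
  gz <- wilcoxon_signed_rank(xz, yz)
  expect_equal(gz$n_nonzero, 40L)
  expect_false(gz$exact)
  expect_error(wilcoxon_signed_rank(1:5, 1:5), "zero")
})

test_that("group comparisons recover a constructed harvest shift", {
  tab <- generate_phenotype_table(5, seed = 65)
  tab$PC1 <- rnorm(nrow(tab))
  tab$PC1[tab$harvest == "DAS101"] <-
    tab$PC1[tab$harvest == "DAS72"] - 2      # uniform darkening
  tab$PC2 <- rnorm(nrow(tab)); tab$PC3 <- rnorm(nrow(tab))
  res <- compare_groups(tab, "harvest", "plant_id")
  pc1 <- res[res$axis == "PC1", ]
  expect_equal(pc1$tau, 1)
  expect_lt(pc1$p_V, 0.001)
  expect_equal(pc1$stars_V, "***")
  expect_equal(pc1$V, pc1$n_pairs * (pc1$n_pairs + 1) / 2)  # all positive

  # orphaned pairing keys are an error, not a silent drop
  broken <- tab[-1, ]
  expect_error(compare_groups(broken, "harvest", "plant_id"), "bijection")
})

test_that("the color model recovers exact coefficients at zero noise", {
  eff <- phenotype_effects(residual_sd = 0)
  tab <- generate_phenotype_table(3, effects = eff, seed = 66)
  tab$PC1 <- tab$response
  fit <- fit_color_model(tab)
  cf <- coef(fit$fit)
  expect_equal(unname(cf["biomass_g"]), eff$beta_biomass, tolerance = 1e-8)
  expect_equal(unname(cf["height_cm"]), eff$beta_height, tolerance = 1e-8)
  expect_equal(unname(cf["spad"]), eff$beta_spad, tolerance = 1e-8)
  expect_equal(unname(cf["soil_moisture_pct"]), eff$beta_moisture,
               tolerance = 1e-8)
  expect_equal(unname(cf["treatmentclimate2050"]),
               eff$treatment_offsets[["climate2050"]], tolerance = 1e-8)
  expect_equal(unname(cf["varietyCarraig"]),
               eff$variety_offsets[["Carraig"]], tolerance = 1e-8)
  expect_equal(unname(cf["harvestDAS101"]),
               eff$month_offsets[["DAS101"]], tolerance = 1e-8)
  expect_equal(fit$adj_r_squared, 1, tolerance = 1e-8)
})

test_that("the study-sized design leaves 630 residual degrees of freedom", {
  tab <- generate_phenotype_table(20, seed = 67)
  tab$PC1 <- tab$response
  fit <- fit_color_model(tab)
  expect_equal(nrow(fit$data), 640L)
  expect_equal(fit$residual_df, 630L)
  expect_equal(nrow(fit$coefficients), 10L)
})

test_that("single-term deletion equals the independent refit oracle", {
  set.seed(68)
  tab <- generate_phenotype_table(2, seed = 68)   # n = 64, keeps refits light
  tab$PC1 <- tab$response
  fit <- fit_color_model(tab)
  mine <- drop1_anova(fit)
  orc <- drop1_oracle(
    PC1 ~ biomass_g + height_cm + spad + soil_moisture_pct +
      treatment + variety + harvest, fit$data)
  expect_equal(mine$term, orc$term)
  expect_equal(mine$sum_sq, orc$sum_sq, tolerance = 1e-8)
  expect_equal(mine$rss, orc$rss, tolerance = 1e-8)
  expect_equal(mine$aic, orc$aic, tolerance = 1e-8)
  expect_equal(mine$d_aic, orc$d_aic, tolerance = 1e-8)
  expect_equal(mine$F, orc$F, tolerance = 1e-8)
  expect_equal(mine$p, orc$p, tolerance = 1e-8)

  # nesting: every reduced model fits no better than the full one
  expect_true(all(mine$rss >= mine$rss[1] - 1e-9))
})

test_that("a term with no true effect contributes (near) zero sum of squares", {
  eff <- phenotype_effects(beta_height = 0, residual_sd = 0)
  tab <- generate_phenotype_table(2, effects = eff, seed = 69)
  tab$PC1 <- tab$response
  dt <- drop1_anova(fit_color_model(tab))
  height_row <- dt[dt$term == "height_cm", ]
  expect_lt(height_row$sum_sq, 1e-12)
})

test_that("adjusted R-squared follows its algebraic definition", {
  set.seed(70)
  n <- 50
  d <- data.frame(x = rnorm(n))
  d$y <- 2 * d$x + rnorm(n)
  fit <- lm(y ~ x, data = d)
  expect_equal(adjusted_r2(fit), summary(fit)$adj.r.squared, tolerance = 1e-12)
  expect_lte(adjusted_r2(fit), summary(fit)$r.squared)

  perfect <- lm(y ~ x, data = data.frame(x = 1:10, y = 2 * (1:10)))
  expect_equal(adjusted_r2(perfect), 1, tolerance = 1e-10)
})
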