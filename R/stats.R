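#' Shapiro-Wilk normality screen
#'
#' Thin wrapper around the standard Shapiro-Wilk test, used to screen PC
#' axes before the rank-based comparisons. The result never gates any
#' downstream computation; it is reported alongside.
#'
#' @param x Numeric vector, 3 <= n <= 5000, not all equal.
#' @return List with \code{W} and \code{p}.
#' @export
shapiro_wilk <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 3L || length(x) > 5000L) {
    stop("Shapiro-Wilk requires 3 <= n <= 5000")
  }
  if (diff(range(x)) == 0) stop("Shapiro-Wilk is undefined for a constant vector")
  res <- stats::shapiro.test(x)
  list(W = unname(res$statistic), p = res$p.value)
}

#' Kendall rank correlation with tie-adjusted normal test
#'
#' Tau-b (tie-corrected) with the tie-adjusted normal approximation for the
#' test statistic, so a z value is always reported even in the presence of
#' ties (the exact null distribution is unavailable with ties).
#'
#' @param x,y Paired numeric vectors of equal length >= 2.
#' @return List with \code{tau}, \code{z}, \code{p} (two-sided) and \code{n}.
#' @export
kendall_tau_test <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired (equal length)")
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2L) stop("need at least 2 pairs")
  res <- suppressWarnings(
    stats::cor.test(x, y, method = "kendall", exact = FALSE, correct = FALSE))
  list(tau = unname(res$estimate), z = unname(res$statistic),
       p = res$p.value, n = length(x))
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Zero differences are dropped, tied absolute differences are mid-ranked,
#' and V is the sum of the ranks of the positive differences. The exact
#' null distribution is used for 25 or fewer (untied) nonzero differences;
#' otherwise the normal approximation with tie correction and continuity
#' correction.
#'
#' @param x,y Paired numeric vectors; at least one nonzero difference.
#' @return List with \code{V}, \code{p} (two-sided), \code{n_nonzero} and
#'   \code{exact} (whether the exact distribution was used).
#' @export
wilcoxon_signed_rank <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired (equal length)")
  ok <- stats::complete.cases(x, y)
  d <- x[ok] - y[ok]
  d <- d[d != 0]
  if (length(d) == 0L) {
    stop("all paired differences are zero; the signed-rank test is undefined")
  }
  has_ties <- anyDuplicated(abs(d)) > 0L
  use_exact <- length(d) <= 25L && !has_ties
  res <- suppressWarnings(
    stats::wilcox.test(d, exact = use_exact, correct = TRUE))
  list(V = unname(res$statistic), p = res$p.value,
       n_nonzero = length(d), exact = use_exact)
}

significance_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
    ifelse(p < 0.05, "*", "NS")))
}

#' Paired group comparisons of PC axes
#'
#' For every PC axis, compares two groups of records with Kendall's tau
#' rank correlation and Wilcoxon's signed-rank test. Records are paired
#' explicitly by a key column that must define a bijection between the two
#' groups (e.g. \code{plant_id} for the same plants across harvests, or a
#' design stratum pairing a waterlogged with a control plant); no silent
#' positional pairing is performed.
#'
#' @param table Scored plant table (see [score_color_table()]).
#' @param group_col Factor column naming the two compared groups.
#' @param pairing_col Key column defining the pairing.
#' @param levels Optional two group levels, in (first, second) order;
#'   defaults to the first two levels of \code{group_col}.
#' @param axes PC axis columns to compare.
#' @return Data frame, one row per axis: group labels, n_pairs, z, tau,
#'   p_tau, V, p_V and significance stars for each test.
#' @export
compare_groups <- function(table, group_col, pairing_col,
                           levels = NULL, axes = c("PC1", "PC2", "PC3")) {
  g <- table[[group_col]]
  if (is.null(levels)) levels <- if (is.factor(g)) base::levels(g) else unique(g)
  levels <- levels[1:2]
  a <- table[g == levels[1], , drop = FALSE]
  b <- table[g == levels[2], , drop = FALSE]
  orphans <- c(setdiff(a[[pairing_col]], b[[pairing_col]]),
               setdiff(b[[pairing_col]], a[[pairing_col]]))
  if (length(orphans) || anyDuplicated(a[[pairing_col]]) ||
      anyDuplicated(b[[pairing_col]])) {
    stop("pairing key '", pairing_col, "' is not a bijection between ",
         levels[1], " and ", levels[2],
         if (length(orphans)) paste0("; orphans: ",
                                     paste(utils::head(orphans, 5), collapse = ", ")))
  }
  b <- b[match(a[[pairing_col]], b[[pairing_col]]), , drop = FALSE]
  out <- lapply(axes, function(ax) {
    keep <- stats::complete.cases(a[[ax]], b[[ax]])
    kt <- kendall_tau_test(a[[ax]][keep], b[[ax]][keep])
    wx <- wilcoxon_signed_rank(a[[ax]][keep], b[[ax]][keep])
    data.frame(axis = ax, group1 = levels[1], group2 = levels[2],
               n_pairs = sum(keep), z = kt$z, tau = kt$tau, p_tau = kt$p,
               stars_tau = significance_stars(kt$p),
               V = wx$V, p_V = wx$p, stars_V = significance_stars(wx$p),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Linear model of color intensity
#'
#' Ordinary least squares of the first principal component (color
#' intensity) on dried biomass, maximum height, SPAD, soil moisture,
#' climate treatment (2 levels), variety (4 levels) and harvest month
#' (2 levels), with treatment contrasts and each factor's first level as
#' reference.
#'
#' @param table Scored plant table with complete cases on the model
#'   columns; incomplete rows are dropped with a message.
#' @param response Response column, default \code{"PC1"}.
#' @return Object of class \code{color_model_fit}: the \code{lm} fit plus
#'   extracted \code{coefficients} table, \code{residual_df}, \code{rss},
#'   \code{adj_r_squared} and \code{aic} (on the
#'   \code{n log(RSS/n) + 2 edf} scale used for deletion comparisons).
#' @export
fit_color_model <- function(table, response = "PC1") {
  vars <- c(response, "biomass_g", "height_cm", "spad", "soil_moisture_pct",
            "treatment", "variety", "harvest")
  missing_cols <- setdiff(vars, names(table))
  if (length(missing_cols)) {
    stop("table lacks model columns: ", paste(missing_cols, collapse = ", "))
  }
  dat <- table[stats::complete.cases(table[, vars]), vars]
  if (nrow(dat) < nrow(table)) {
    message(nrow(table) - nrow(dat), " incomplete rows dropped before fitting")
  }
  for (fcol in c("treatment", "variety", "harvest")) {
    dat[[fcol]] <- droplevels(as.factor(dat[[fcol]]))
    if (nlevels(dat[[fcol]]) < 2L) {
      stop("factor '", fcol, "' has fewer than 2 observed levels")
    }
  }
  form <- stats::as.formula(paste(
    response, "~ biomass_g + height_cm + spad + soil_moisture_pct",
    "+ treatment + variety + harvest"))
  fit <- stats::lm(form, data = dat,
                   contrasts = list(treatment = "contr.treatment",
                                    variety = "contr.treatment",
                                    harvest = "contr.treatment"))
  if (any(is.na(stats::coef(fit)))) {
    stop("rank-deficient design; aliased terms: ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))], collapse = ", "))
  }
  sm <- summary(fit)
  structure(list(fit = fit, data = dat,
                 coefficients = stats::coef(sm),
                 residual_df = fit$df.residual,
                 rss = sum(stats::residuals(fit)^2),
                 r_squared = sm$r.squared,
                 adj_r_squared = sm$adj.r.squared,
                 aic = stats::extractAIC(fit)[2]),
            class = "color_model_fit")
}

#' @export
print.color_model_fit <- function(x, ...) {
  cat("Color-intensity linear model:",
      nrow(x$data), "records,", x$residual_df, "residual df\n")
  cat(sprintf("RSS %.1f, adjusted R^2 %.1f%%, AIC %.1f\n",
              x$rss, 100 * x$adj_r_squared, x$aic))
  stats::printCoefmat(x$coefficients, ...)
  invisible(x)
}

#' Single-term-deletion Type II ANOVA with AIC deltas
#'
#' For every term of the full model, refits without that term (factors
#' dropped whole), and reports the term's degrees of freedom, its sum of
#' squares (reduced-model RSS minus full-model RSS), the reduced model's
#' RSS and AIC, the AIC change (full minus reduced, negative when removal
#' worsens the model), the Type II F statistic and its p value, plus the
#' \code{"<none>"} full-model row.
#'
#' @param fit A [fit_color_model()] object (or plain \code{lm}).
#' @return Data frame with columns term, df, sum_sq, rss, aic, d_aic, F,
#'   p, stars.
#' @export
drop1_anova <- function(fit) {
  lmfit <- if (inherits(fit, "color_model_fit")) fit$fit else fit
  dr <- stats::drop1(lmfit, test = "F")
  full_aic <- dr[["AIC"]][1]
  out <- data.frame(term = rownames(dr),
                    df = dr$Df,
                    sum_sq = dr[["Sum of Sq"]],
                    rss = dr$RSS,
                    aic = dr$AIC,
                    d_aic = full_aic - dr$AIC,
                    F = dr[["F value"]],
                    p = dr[["Pr(>F)"]],
                    stringsAsFactors = FALSE)
  out$stars <- ifelse(is.na(out$p), "", significance_stars(out$p))
  out$d_aic[1] <- NA_real_
  rownames(out) <- NULL
  out
}

#' Adjusted R-squared
#'
#' \eqn{1 - (1 - R^2)(n - 1)/(n - p)} with p the number of estimated
#' coefficients including the intercept.
#'
#' @param fit A [fit_color_model()] or \code{lm} object.
#' @return Proportion (multiply by 100 for the percent scale used in
#'   summaries).
#' @export
adjusted_r2 <- function(fit) {
  lmfit <- if (inherits(fit, "color_model_fit")) fit$fit else fit
  n <- length(stats::residuals(lmfit))
  p <- lmfit$rank
  if (n <= p) stop("adjusted R-squared requires more observations than parameters")
  r2 <- summary(lmfit)$r.squared
  1 - (1 - r2) * (n - 1) / (n - p)
}
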