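# Shared fixtures and independent oracles. Every oracle here recomputes the
# quantity under test by a different route (nested loops, enumeration,
# normal equations) so that implementation and check never share code.

# The synthetic study's default camera, noise-free unless asked otherwise.
study_camera <- function(seed = 1L, noise_sd = 0) {
  cfg <- default_config()
  camera_model(bayer_pattern = cfg$camera$bayer_pattern,
               black_level = cfg$camera$black_level,
               white_level = cfg$camera$white_level,
               wb_gains = cfg$camera$wb_gains,
               camera_matrix = cfg$camera$camera_matrix,
               color_distortion = affine_color_map(cfg$camera$distortion_M,
                                                   cfg$camera$distortion_b),
               noise_sd = noise_sd, seed = seed)
}

# Direct per-pixel 5x5 convolution with reflective padding: the brute-force
# counterpart of the shift-and-add implementation.
conv5_oracle <- function(x, kern) {
  nr <- nrow(x); nc <- ncol(x)
  reflect <- function(i, n) {
    i <- ifelse(i < 1L, 1L - i, i)
    ifelse(i > n, 2L * n + 1L - i, i)
  }
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    acc <- 0
    for (di in -2:2) for (dj in -2:2) {
      acc <- acc + kern[di + 3L, dj + 3L] *
        x[reflect(i + di, nr), reflect(j + dj, nc)]
    }
    out[i, j] <- acc
  }
  out
}

# Demosaic oracle: assembles the three channels by direct convolution and
# an independently written Bayer site classification.
demosaic_oracle <- function(x, pattern) {
  kerns <- ryecolor:::mhc_kernels()
  nr <- nrow(x); nc <- ncol(x)
  block <- matrix(strsplit(pattern, "")[[1]], 2, 2, byrow = TRUE)
  site <- function(i, j) block[(i - 1L) %% 2L + 1L, (j - 1L) %% 2L + 1L]
  gc <- conv5_oracle(x, kerns$cross)
  cr <- conv5_oracle(x, kerns$row)
  cc <- conv5_oracle(x, kerns$col)
  cd <- conv5_oracle(x, kerns$diag)
  out <- array(NA_real_, c(nr, nc, 3))
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    s <- site(i, j)
    if (s == "R") {
      out[i, j, ] <- c(x[i, j], gc[i, j], cd[i, j])
    } else if (s == "B") {
      out[i, j, ] <- c(cd[i, j], gc[i, j], x[i, j])
    } else {
      # G site: is red in this row (look left/right) or this column?
      r_in_row <- site(i, j + 1L) == "R" || site(i, j - 1L) == "R"
      if (r_in_row) out[i, j, ] <- c(cr[i, j], x[i, j], cc[i, j])
      else out[i, j, ] <- c(cc[i, j], x[i, j], cr[i, j])
    }
  }
  out
}

# Queue-based flood fill, the independent counterpart of the graph-based
# component labelling.
floodfill_labels <- function(mask, connectivity = 8L) {
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  offs <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  if (connectivity == 8L) {
    offs <- rbind(offs, c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  }
  lab <- 0L
  for (start in which(mask & labels == 0L)) {
    if (labels[start] > 0L) next
    lab <- lab + 1L
    queue <- start
    labels[start] <- lab
    while (length(queue)) {
      p <- queue[1]; queue <- queue[-1]
      pi <- (p - 1L) %% nr + 1L; pj <- (p - 1L) %/% nr + 1L
      for (k in seq_len(nrow(offs))) {
        qi <- pi + offs[k, 1]; qj <- pj + offs[k, 2]
        if (qi >= 1 && qi <= nr && qj >= 1 && qj <= nc &&
            mask[qi, qj] && labels[qi, qj] == 0L) {
          q <- (qj - 1L) * nr + qi
          labels[q] <- lab
          queue <- c(queue, q)
        }
      }
    }
  }
  labels
}

# Affine color fit by explicit normal equations.
affine_fit_oracle <- function(measured, reference) {
  X <- cbind(measured, 1)
  solve(t(X) %*% X, t(X) %*% reference)   # 4 x 3
}

# Kendall tau-b and tie-adjusted z by O(n^2) pair counting and the
# published variance formula.
kendall_oracle <- function(x, y) {
  n <- length(x)
  S <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    S <- S + sign(x[j] - x[i]) * sign(y[j] - y[i])
  }
  tie_terms <- function(v) {
    t <- table(v)
    c(t0 = sum(t * (t - 1) / 2),
      v1 = sum(t * (t - 1) * (2 * t + 5)),
      a = sum(t * (t - 1) * (t - 2)),
      b = sum(t * (t - 1)))
  }
  tx <- tie_terms(x); ty <- tie_terms(y)
  n0 <- n * (n - 1) / 2
  tau <- S / sqrt((n0 - tx["t0"]) * (n0 - ty["t0"]))
  v0 <- n * (n - 1) * (2 * n + 5)
  var_S <- (v0 - tx["v1"] - ty["v1"]) / 18 +
    tx["a"] * ty["a"] / (9 * n * (n - 1) * (n - 2)) +
    tx["b"] * ty["b"] / (2 * n * (n - 1))
  z <- S / sqrt(var_S)
  list(tau = unname(tau), z = unname(z),
       p = 2 * stats::pnorm(-abs(unname(z))))
}

# Exact Wilcoxon signed-rank by full sign-flip enumeration (distinct
# absolute differences assumed).
wilcoxon_oracle <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Vs <- as.vector(signs %*% r)
  p <- mean(abs(Vs - n * (n + 1) / 4) >= abs(V - n * (n + 1) / 4) - 1e-12)
  list(V = V, p = p)
}

# Shapiro-Wilk W via the published polynomial approximation to the optimal
# linear coefficients (Blom scores rescaled, tail terms corrected).
shapiro_w_oracle <- function(x) {
  x <- sort(x)
  n <- length(x)
  m <- stats::qnorm((seq_len(n) - 0.375) / (n + 0.25))
  c_vec <- m / sqrt(sum(m^2))
  u <- 1 / sqrt(n)
  a <- numeric(n)
  a[n] <- c_vec[n] + 0.221157 * u - 0.147981 * u^2 - 2.071190 * u^3 +
    4.434685 * u^4 - 2.706056 * u^5
  a[n - 1] <- c_vec[n - 1] + 0.042981 * u - 0.293762 * u^2 -
    1.752461 * u^3 + 5.682633 * u^4 - 3.582633 * u^5
  a[1] <- -a[n]; a[2] <- -a[n - 1]
  phi <- (sum(m^2) - 2 * m[n]^2 - 2 * m[n - 1]^2) /
    (1 - 2 * a[n]^2 - 2 * a[n - 1]^2)
  mid <- 3:(n - 2)
  a[mid] <- m[mid] / sqrt(phi)
  sum(a * x)^2 / sum((x - mean(x))^2)
}

# Single-term deletion table by refitting every reduced model from scratch.
drop1_oracle <- function(formula, data) {
  full <- stats::lm(formula, data = data)
  rss_full <- sum(stats::residuals(full)^2)
  df_full <- full$df.residual
  n <- nrow(data)
  aic_of <- function(fit) {
    n * log(sum(stats::residuals(fit)^2) / n) + 2 * fit$rank
  }
  terms_all <- attr(stats::terms(full), "term.labels")
  rows <- lapply(terms_all, function(tm) {
    red <- stats::lm(stats::update(stats::formula(full),
                                   paste(". ~ . -", tm)), data = data)
    rss_red <- sum(stats::residuals(red)^2)
    ddf <- red$df.residual - df_full
    Fv <- ((rss_red - rss_full) / ddf) / (rss_full / df_full)
    data.frame(term = tm, df = ddf, sum_sq = rss_red - rss_full,
               rss = rss_red, aic = aic_of(red),
               d_aic = aic_of(full) - aic_of(red),
               F = Fv, p = stats::pf(Fv, ddf, df_full, lower.tail = FALSE))
  })
  rbind(data.frame(term = "<none>", df = NA, sum_sq = NA, rss = rss_full,
                   aic = aic_of(full), d_aic = NA, F = NA, p = NA),
        do.call(rbind, rows))
}
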