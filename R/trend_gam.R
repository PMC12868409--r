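#' Penalized additive trend model over exposure years
#'
#' Fits, via [mgcv::gam()], the trend-model structure used throughout the
#' analysis: a tree-species fixed effect (baseline differences), one
#' smooth of exposure year per tree species (`s(exposure_year,
#' by = tree_species)`, year treated as numeric so a missing sampling year
#' needs no imputation), and an isotropic thin-plate smooth of the log
#' coordinates (`s(E, N, bs = "tp")`) absorbing repeated-measure and
#' spatial structure. Counts use a negative binomial family with log link
#' (dispersion estimated alongside the smoothing parameters); continuous
#' responses (e.g. SES of mean pairwise distance) use a Gaussian identity
#' link. Smoothing parameters are selected by REML.
#'
#' The adjusted R-squared reported is computed on the response scale as
#' `1 - [sum((y - mu)^2) / (n - edf_tot)] / [sum((y - ybar)^2) / (n - 1)]`
#' with `edf_tot` the total effective degrees of freedom, so it is
#' comparable across families.
#'
#' @param data Data frame with the response column plus `tree_species`
#'   (factor), `exposure_year`, `E`, `N` (and `abundance` when
#'   `log_abundance = TRUE`).
#' @param response Name of the response column.
#' @param family `"nb"` (negative binomial, log link) or `"gaussian"`.
#' @param log_abundance Add `log(abundance)` as a fixed covariate (the
#'   species-richness model, which asks whether species number is driven
#'   by abundance alone).
#' @param k_year Basis size of each year smooth (capped at the number of
#'   distinct years per tree species).
#' @param k_space Basis size of the spatial smooth (capped below the
#'   number of distinct coordinates).
#' @param spatial Include the spatial smooth (dropped with a message when
#'   fewer than 5 distinct coordinates exist).
#' @param sp Optional smoothing-parameter vector passed to [mgcv::gam()]
#'   (e.g. to force maximal penalization).
#' @return Object of class `trend_gam`: list with the `mgcv` fit (`fit`),
#'   `adj_r2`, `smooths` (edf / F / p per smooth with significance marks),
#'   `theta` (NB dispersion, if applicable), `family`, `formula`.
#' @export
fit_trend_gam <- function(data, response, family = c("nb", "gaussian"),
                          log_abundance = FALSE, k_year = 10, k_space = 30,
                          spatial = TRUE, sp = NULL) {
  family <- match.arg(family)
  needed <- c(response, "tree_species", "exposure_year", "E", "N")
  stop_if_not(all(needed %in% names(data)),
              paste("data is missing columns:",
                    paste(setdiff(needed, names(data)), collapse = ", ")))
  data$tree_species <- factor(data$tree_species)
  data$tree_species <- droplevels(data$tree_species)
  y <- data[[response]]
  if (family == "nb") {
    stop_if_not(all(y >= 0) && all(abs(y - round(y)) < 1e-8),
                "negative binomial family requires non-negative integer counts")
  }
  if (log_abundance) {
    stop_if_not("abundance" %in% names(data), "abundance column required")
    nz <- data$abundance > 0
    if (any(!nz)) {
      message("dropping ", sum(!nz), " zero-abundance row(s) from richness model")
      data <- data[nz, , drop = FALSE]
    }
    data$log_abundance <- log(data$abundance)
  }
  ky <- min(k_year,
            min(tapply(data$exposure_year, data$tree_species,
                       function(v) length(unique(v)))))
  stop_if_not(ky >= 3, "need at least 3 distinct years per tree species")
  terms <- c("tree_species",
             sprintf("s(exposure_year, by = tree_species, k = %d)", ky))
  if (log_abundance) terms <- c("log_abundance", terms)
  n_coord <- nrow(unique(data[c("E", "N")]))
  if (spatial && n_coord >= 5) {
    ks <- min(k_space, n_coord - 1)
    terms <- c(terms, sprintf("s(E, N, bs = 'tp', k = %d)", ks))
  } else if (spatial) {
    message("fewer than 5 distinct coordinates; spatial smooth dropped")
  }
  form <- stats::reformulate(terms, response = response)
  fam <- if (family == "nb") mgcv::nb() else gaussian()
  fit <- tryCatch(
    mgcv::gam(form, family = fam, data = data, method = "REML", sp = sp),
    error = function(e) {
      # REML can fail on degenerate responses (e.g. zero variance);
      # fall back to GCV smoothing selection
      mgcv::gam(form, family = fam, data = data, method = "GCV.Cp", sp = sp)
    })
  mu <- fitted(fit)
  yy <- fit$y
  edf_tot <- sum(fit$edf)
  n <- length(yy)
  ss_tot <- sum((yy - mean(yy))^2)
  adj_r2 <- if (ss_tot == 0) 0 else {
    1 - (sum((yy - mu)^2) / (n - edf_tot)) / (ss_tot / (n - 1))
  }
  s_tab <- summary(fit)$s.table
  smooths <- data.frame(term = rownames(s_tab), edf = s_tab[, "edf"],
                        p = s_tab[, ncol(s_tab)], row.names = NULL)
  smooths$signif <- p_stars(smooths$p)
  theta <- if (family == "nb") fit$family$getTheta(TRUE) else NA_real_
  structure(list(fit = fit, adj_r2 = adj_r2, smooths = smooths,
                 theta = theta, family = family, formula = form,
                 data = data, response = response),
            class = "trend_gam")
}

#' @export
print.trend_gam <- function(x, ...) {
  cat("Additive trend model:", deparse(x$formula), "\n")
  cat("Family:", if (x$family == "nb")
    sprintf("negative binomial (theta = %.3f)", x$theta) else "gaussian",
    "| adjusted R-squared:", round(x$adj_r2, 3), "\n")
  print(transform(x$smooths, edf = round(edf, 2), p = signif(p, 3)),
        row.names = FALSE)
  invisible(x)
}

#' Species-richness trend model (number of species controlled for abundance)
#'
#' Number of species as response (negative binomial) with log abundance as
#' a fixed covariate plus the standard term set. Flat, non-significant
#' year smooths indicate that species number is explained by abundance
#' alone (the more-individuals hypothesis); residual year effects point to
#' changing niche availability (habitat heterogeneity).
#'
#' @param data As in [fit_trend_gam()], with columns `n_species` and
#'   `abundance`; zero-abundance rows are dropped (log undefined).
#' @param ... Passed to [fit_trend_gam()].
#' @return A `trend_gam`.
#' @export
fit_richness_model <- function(data, ...) {
  fit_trend_gam(data, response = "n_species", family = "nb",
                log_abundance = TRUE, ...)
}

#' Predicted trend curves with 95% bands
#'
#' Predictions over a year grid per tree species, holding the spatial
#' smooth at the centroid coordinate (and log abundance, when present, at
#' its mean). Standard-error bands are formed on the link scale and
#' back-transformed, so count-response bands stay positive.
#'
#' @param x A `trend_gam`.
#' @param years Numeric grid of exposure years (default: 100 points over
#'   the observed range).
#' @param level Coverage of the band (default 0.95).
#' @return Data frame with `tree_species`, `exposure_year`, `mean`,
#'   `lower`, `upper`.
#' @export
predict_trend <- function(x, years = NULL, level = 0.95) {
  d <- x$data
  if (is.null(years)) {
    years <- seq(min(d$exposure_year), max(d$exposure_year),
                 length.out = 100)
  }
  nd <- expand.grid(exposure_year = years,
                    tree_species = levels(d$tree_species))
  nd$E <- mean(d$E)
  nd$N <- mean(d$N)
  if ("log_abundance" %in% names(d)) nd$log_abundance <- mean(d$log_abundance)
  pr <- predict(x$fit, newdata = nd, type = "link", se.fit = TRUE)
  z <- stats::qnorm(1 - (1 - level) / 2)
  inv <- x$fit$family$linkinv
  data.frame(tree_species = nd$tree_species,
             exposure_year = nd$exposure_year,
             mean = inv(pr$fit),
             lower = inv(pr$fit - z * pr$se.fit),
             upper = inv(pr$fit + z * pr$se.fit))
}

#' Moran's I test for residual spatial autocorrelation
#'
#' Deviance residuals are averaged per unique coordinate (logs are
#' repeatedly measured), spatial weights are inverse distances
#' (`w_ij = 1 / d_ij`, zero diagonal) row-standardized, and Moran's I is
#' tested against its analytic mean `-1/(n-1)` and variance under
#' normality ([ape::Moran.I()]), two-sided.
#'
#' @param x A `trend_gam` (or any object with `residuals()` and matching
#'   coordinates).
#' @param coords Optional data frame with columns `E`, `N`, one row per
#'   observation; defaults to the model data.
#' @return List of class `spatial_autocorr`: `observed`, `expected`, `sd`,
#'   `p_value`, `n_locations`.
#' @export
morans_i_residuals <- function(x, coords = NULL) {
  if (inherits(x, "trend_gam")) {
    res <- residuals(x$fit, type = "deviance")
    coords <- coords %||% x$data[c("E", "N")]
  } else {
    res <- x
    stop_if_not(!is.null(coords), "coords required")
  }
  stop_if_not(length(res) == nrow(coords),
              "one residual per observation required")
  key <- paste(coords$E, coords$N)
  agg <- tapply(res, key, mean)
  uq <- !duplicated(key)
  xy <- coords[uq, , drop = FALSE]
  agg <- agg[paste(xy$E, xy$N)]
  n <- length(agg)
  stop_if_not(n >= 3, "need at least 3 unique locations")
  dm <- as.matrix(dist(xy))
  w <- 1 / dm
  diag(w) <- 0
  w <- w / rowSums(w)
  mi <- ape::Moran.I(as.numeric(agg), w, scaled = FALSE,
                     alternative = "two.sided")
  structure(list(observed = mi$observed, expected = mi$expected,
                 sd = mi$sd, p_value = mi$p.value, n_locations = n),
            class = "spatial_autocorr")
}

#' @export
print.spatial_autocorr <- function(x, ...) {
  cat(sprintf(
    "Moran's I on residuals: I = %.4f (expected %.4f, sd %.4f), p = %.4g (n = %d locations)\n",
    x$observed, x$expected, x$sd, x$p_value, x$n_locations))
  invisible(x)
}
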