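# Draw-based inference: Gaussian location-scale, negative-binomial and
# beta regressions, and the posterior-summary machinery (MAP, HDI, pd,
# ROPE, contrasts, averaged elevation effect, difference-of-differences).
#
# Models are fitted by maximum likelihood (glmmTMB) and coefficient
# uncertainty is represented by multivariate-normal draws from the joint
# estimate/covariance — a normal approximation to the posterior under
# flat priors. All summary operations consume only the draws, so any
# sampler producing a named draw matrix can stand behind them.

#' z-transform a numeric vector
#'
#' Centre to mean 0 and scale to sample SD 1, keeping the transform
#' record so model predictions can be made on the original scale.
#'
#' @param x Numeric vector without missing values.
#' @return List with `z` (standardized vector), `mean`, `sd`.
#' @export
zscore <- function(x) {
  stopifnot(is.numeric(x), !anyNA(x))
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    stop("cannot z-transform a constant vector", call. = FALSE)
  }
  m <- mean(x)
  list(z = (x - m) / s, mean = m, sd = s)
}

#' Construct a draws object
#'
#' @param draws Numeric matrix, rows = draws, columns = named
#'   coefficients.
#' @param response_sd SD of the modelled response on the model's link
#'   scale; defines the default ROPE half-width (0.1 * `response_sd`).
#' @param meta List of fit metadata (family, standardization records,
#'   response-scale SD, ...).
#' @return A `stagespec_draws` object.
#' @export
new_draws <- function(draws, response_sd, meta = list()) {
  stopifnot(is.matrix(draws), !is.null(colnames(draws)),
            !anyDuplicated(colnames(draws)), response_sd >= 0)
  structure(list(draws = draws, response_sd = response_sd, meta = meta),
            class = "stagespec_draws")
}

#' @export
print.stagespec_draws <- function(x, ...) {
  cat("Draws:", nrow(x$draws), "draws x", ncol(x$draws),
      "coefficients (", paste(utils::head(colnames(x$draws), 4),
                              collapse = ", "),
      if (ncol(x$draws) > 4) ", ..." else "", ")\n", sep = " ")
  invisible(x)
}

# multivariate-normal draws via eigen decomposition (robust to
# near-singular covariance)
mvn_draws <- function(n, mu, sigma) {
  p <- length(mu)
  e <- eigen(sigma, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  z <- matrix(stats::rnorm(n * p), n, p)
  out <- z %*% (t(e$vectors) * sqrt(ev))
  sweep(out, 2, mu, "+")
}

# joint MVN draws of the conditional-model (and optionally
# dispersion-model) coefficients of a glmmTMB fit
draws_from_glmmTMB <- function(fit, n_draws, include_disp = FALSE) {
  v <- stats::vcov(fit, full = TRUE)
  est <- c(glmmTMB::fixef(fit)$cond,
           if (include_disp)
             stats::setNames(glmmTMB::fixef(fit)$disp,
                             paste0("d~", names(glmmTMB::fixef(fit)$disp))))
  keep <- match(names(est), rownames(v))
  if (anyNA(keep)) {
    # full vcov labels dispersion terms "d~<name>" already; cond terms as-is
    rn <- rownames(v)
    keep <- c(match(names(glmmTMB::fixef(fit)$cond), rn),
              if (include_disp) grep("^d~", rn))
    est <- stats::setNames(
      c(glmmTMB::fixef(fit)$cond,
        if (include_disp) glmmTMB::fixef(fit)$disp),
      rn[keep])
  }
  vv <- v[keep, keep, drop = FALSE]
  if (!all(is.finite(vv))) {
    stop("coefficient covariance is not finite (boundary or singular ",
         "fit); revisit the model specification", call. = FALSE)
  }
  d <- mvn_draws(n_draws, est, vv)
  colnames(d) <- names(est)
  d
}

#' Fit the specialization (SES) location-scale model
#'
#' Gaussian model of plot-level mean SES with elevational zone predicting
#' both the mean and (on the log scale) the dispersion, optionally with a
#' spatial-group random intercept. Zone enters as cell means (no
#' intercept) so zone contrasts are direct coefficient differences.
#'
#' @param plot_ses Output of [plot_mean_ses()] (rows with missing
#'   `mean_ses` are dropped).
#' @param design A `stagespec_design` (provides `spatial_group`).
#' @param random_intercept Include `(1 | spatial_group)`?
#' @param n_draws Number of coefficient draws (>= 1000 for summaries).
#' @param seed Integer seed for the draws.
#' @return A `stagespec_draws` with zone means (`zone<level>`) and zone
#'   log-dispersions (`d~zone<level>`).
#' @export
fit_ses_model <- function(plot_ses, design, random_intercept = TRUE,
                          n_draws = 4000, seed = 1L) {
  df <- merge(plot_ses, as.data.frame(design)[, c("plot_id",
                                                  "spatial_group")],
              by = "plot_id")
  df <- df[!is.na(df$mean_ses), , drop = FALSE]
  df$zone <- factor(df$zone, levels = zone_levels())
  if (length(unique(df$zone)) < 2) {
    stop("need data from at least two zones", call. = FALSE)
  }
  form <- if (random_intercept) {
    mean_ses ~ 0 + zone + (1 | spatial_group)
  } else {
    mean_ses ~ 0 + zone
  }
  fit <- glmmTMB::glmmTMB(form, dispformula = ~ 0 + zone, data = df,
                          family = stats::gaussian())
  set.seed(seed)
  d <- draws_from_glmmTMB(fit, n_draws, include_disp = TRUE)
  new_draws(d, response_sd = stats::sd(df$mean_ses),
            meta = list(family = "gaussian_location_scale",
                        n_obs = nrow(df), fit = fit))
}

#' Fit the richness model
#'
#' Negative-binomial regression of per-plot species richness on the
#' stage-by-elevation interaction (gap is the baseline stage), optionally
#' a day-of-year covariate, and a spatial-group random intercept.
#' Continuous predictors are z-transformed; the transform records are
#' kept in `meta$elev` / `meta$day` for prediction.
#'
#' @param richness Output of [species_richness()].
#' @param design A `stagespec_design`.
#' @param day_covariate Add z-scored day of year as a covariate?
#' @param random_intercept Include `(1 | spatial_group)`?
#' @param n_draws,seed As in [fit_ses_model()].
#' @return A `stagespec_draws`; `response_sd` is the SD of
#'   `log1p(richness)` (the link-comparable scale used for coefficient
#'   ROPEs), `meta$response_sd_raw` the raw-count SD used for
#'   prediction-scale ROPEs.
#' @export
fit_richness_model <- function(richness, design, day_covariate = FALSE,
                               random_intercept = TRUE, n_draws = 4000,
                               seed = 1L) {
  df <- merge(richness, as.data.frame(design), by = "plot_id")
  if (all(df$richness == 0)) stop("all-zero richness", call. = FALSE)
  df$stage <- factor(df$stage, levels = stage_levels())
  elev <- zscore(df$elevation_m)
  df$elev_z <- elev$z
  day <- NULL
  if (day_covariate) {
    if (anyNA(df$day_of_year)) {
      stop("day_covariate requested but day_of_year has missing values",
           call. = FALSE)
    }
    day <- zscore(as.numeric(df$day_of_year))
    df$day_z <- day$z
  }
  rhs <- "stage * elev_z"
  if (day_covariate) rhs <- paste(rhs, "+ day_z")
  if (random_intercept) rhs <- paste(rhs, "+ (1 | spatial_group)")
  form <- stats::as.formula(paste("richness ~", rhs))
  fit <- glmmTMB::glmmTMB(form, data = df, family = glmmTMB::nbinom2())
  set.seed(seed)
  d <- draws_from_glmmTMB(fit, n_draws)
  new_draws(d, response_sd = stats::sd(log1p(df$richness)),
            meta = list(family = "negative_binomial",
                        elev = elev[c("mean", "sd")],
                        day = if (day_covariate) day[c("mean", "sd")],
                        response_sd_raw = stats::sd(df$richness),
                        n_obs = nrow(df), fit = fit))
}

#' Fit the beta-diversity model
#'
#' Beta regression of cross-stage pairwise Jaccard dissimilarity on
#' elevational zone (cell means), with z-scored spatial and elevational
#' distance covariates, optionally day-difference and quadratic distance
#' terms. Responses exactly 0 or 1 are shrunk by
#' `(y * (n - 1) + 0.5) / n` before fitting.
#'
#' @param pairs Output of [dissimilarity_table()].
#' @param day_covariate Add the z-scored day difference?
#' @param quadratic Character vector among
#'   `c("spatial_distance_m", "elevational_distance_m")`: covariates also
#'   entering squared.
#' @param n_draws,seed As in [fit_ses_model()].
#' @return A `stagespec_draws` with zone means on the logit scale and
#'   covariate coefficients; `response_sd` is the SD of the logit-shrunk
#'   response.
#' @export
fit_beta_model <- function(pairs, day_covariate = FALSE,
                           quadratic = character(0), n_draws = 4000,
                           seed = 1L) {
  if (nrow(pairs) < 10) {
    stop("need at least 10 plot pairs to fit the beta model",
         call. = FALSE)
  }
  df <- as.data.frame(pairs)
  df$zone <- factor(df$zone, levels = zone_levels())
  n <- nrow(df)
  y <- df$jaccard
  if (any(y <= 0 | y >= 1)) y <- (y * (n - 1) + 0.5) / n
  df$y <- y
  sp <- zscore(df$spatial_distance_m)
  el <- zscore(df$elevational_distance_m)
  df$spatial_z <- sp$z
  df$elev_dist_z <- el$z
  rhs <- "0 + zone + spatial_z + elev_dist_z"
  if ("spatial_distance_m" %in% quadratic) {
    df$spatial_z2 <- df$spatial_z^2
    rhs <- paste(rhs, "+ spatial_z2")
  }
  if ("elevational_distance_m" %in% quadratic) {
    df$elev_dist_z2 <- df$elev_dist_z^2
    rhs <- paste(rhs, "+ elev_dist_z2")
  }
  day <- NULL
  if (day_covariate) {
    if (anyNA(df$day_difference)) {
      stop("day_covariate requested but day_difference has missing values",
           call. = FALSE)
    }
    day <- zscore(as.numeric(df$day_difference))
    df$day_diff_z <- day$z
    rhs <- paste(rhs, "+ day_diff_z")
  }
  form <- stats::as.formula(paste("y ~", rhs))
  fit <- glmmTMB::glmmTMB(form, data = df, family = glmmTMB::beta_family())
  set.seed(seed)
  d <- draws_from_glmmTMB(fit, n_draws)
  new_draws(d, response_sd = stats::sd(stats::qlogis(df$y)),
            meta = list(family = "beta",
                        response_sd_raw = stats::sd(df$y),
                        n_obs = n, fit = fit))
}

# ---- posterior summaries --------------------------------------------------

#' Maximum a posteriori point estimate of a draw vector
#'
#' Mode of a Gaussian-kernel density estimate (Silverman's rule-of-thumb
#' bandwidth) over the draws.
#'
#' @param x Numeric draw vector.
#' @return The density mode.
#' @export
map_estimate <- function(x) {
  if (stats::sd(x) < 1e-12) return(x[1])
  dens <- stats::density(x, bw = "nrd0", n = 1024)
  dens$x[which.max(dens$y)]
}

#' Highest density interval of a draw vector
#'
#' Shortest interval containing `level` of the draws.
#'
#' @param x Numeric draw vector.
#' @param level Interval mass (default 0.95).
#' @return Numeric `c(low, high)`.
#' @export
hdi_interval <- function(x, level = 0.95) {
  xs <- sort(x)
  n <- length(xs)
  k <- max(1L, ceiling(level * n))
  if (k >= n) return(c(xs[1], xs[n]))
  widths <- xs[(k + 1):n] - xs[1:(n - k)]
  i <- which.min(widths)
  c(xs[i], xs[i + k])
}

#' Probability of direction of a draw vector
#'
#' The larger of `P(x > 0)` and `P(x < 0)`; 0.5 (no directional
#' information) to 1 (certain sign).
#'
#' @param x Numeric draw vector.
#' @return Value in `[0.5, 1]`.
#' @export
prob_direction <- function(x) {
  max(mean(x > 0), mean(x < 0))
}

#' Summarize draws into MAP / HDI / pd / ROPE
#'
#' The region of practical equivalence (ROPE) spans
#' `c(-1, 1) * rope_mult * response_sd`; `rope_pct` is the percentage of
#' the draws inside the 95% HDI that fall within the ROPE (set
#' `rope_full = TRUE` to use all draws instead).
#'
#' @param draws A `stagespec_draws`, or a numeric vector/matrix of draws.
#' @param names Coefficients to summarize (default: all columns).
#' @param hdi_level HDI mass, default 0.95.
#' @param rope_mult ROPE half-width as a multiple of `response_sd`,
#'   default 0.1.
#' @param response_sd Required when `draws` is not a `stagespec_draws`.
#' @param rope_full Compute the ROPE percentage over all draws rather
#'   than the draws inside the HDI.
#' @return Data frame with one row per coefficient: `name`, `map`,
#'   `hdi_low`, `hdi_high`, `pd`, `rope_low`, `rope_high`, `rope_pct`.
#' @export
summarize_draws <- function(draws, names = NULL, hdi_level = 0.95,
                            rope_mult = 0.1, response_sd = NULL,
                            rope_full = FALSE) {
  if (inherits(draws, "stagespec_draws")) {
    if (is.null(response_sd)) response_sd <- draws$response_sd
    mat <- draws$draws
  } else if (is.matrix(draws)) {
    mat <- draws
  } else {
    mat <- matrix(draws, ncol = 1,
                  dimnames = list(NULL, "draws"))
  }
  if (is.null(response_sd)) {
    stop("response_sd required for raw draw input", call. = FALSE)
  }
  if (nrow(mat) < 1000) {
    stop("at least 1000 draws required for reported summaries",
         call. = FALSE)
  }
  if (is.null(names)) names <- colnames(mat)
  rope <- c(-1, 1) * rope_mult * response_sd
  out <- lapply(names, function(nm) {
    x <- mat[, nm]
    h <- hdi_interval(x, hdi_level)
    m <- min(max(map_estimate(x), h[1]), h[2])
    xin <- if (rope_full) x else x[x >= h[1] & x <= h[2]]
    data.frame(name = nm, map = m, hdi_low = h[1], hdi_high = h[2],
               pd = prob_direction(x), rope_low = rope[1],
               rope_high = rope[2],
               rope_pct = 100 * mean(xin >= rope[1] & xin <= rope[2]),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Summarize a linear combination of coefficients
#'
#' Forms the per-draw linear combination `sum(weights * draws)` — e.g. a
#' pairwise zone contrast `c(zonesubmontane = 1, zonesubalpine = -1)` —
#' and summarizes it.
#'
#' @param draws A `stagespec_draws`.
#' @param weights Named numeric vector; names must be coefficients of
#'   `draws`.
#' @param name Label for the output row.
#' @param ... Passed to [summarize_draws()].
#' @return One-row summary data frame with `attr(, "draws")` carrying the
#'   combined draw vector.
#' @export
contrast <- function(draws, weights, name = NULL, ...) {
  stopifnot(inherits(draws, "stagespec_draws"))
  missing_coef <- setdiff(names(weights), colnames(draws$draws))
  if (length(missing_coef) > 0) {
    stop("unknown coefficient(s): ",
         paste(missing_coef, collapse = ", "), call. = FALSE)
  }
  x <- as.numeric(draws$draws[, names(weights), drop = FALSE] %*% weights)
  if (is.null(name)) {
    name <- paste(names(weights), collapse = " vs ")
  }
  res <- summarize_draws(matrix(x, ncol = 1, dimnames = list(NULL, name)),
                         response_sd = draws$response_sd, ...)
  attr(res, "draws") <- x
  res
}

#' All pairwise zone contrasts of a cell-means model
#'
#' @param draws A `stagespec_draws` from [fit_ses_model()] or
#'   [fit_beta_model()] (zone cell means named `zone<level>`).
#' @param prefix Coefficient prefix, default `"zone"`.
#' @param ... Passed to [summarize_draws()].
#' @return Data frame with one row per ordered pair low-minus-high zone.
#' @export
zone_contrasts <- function(draws, prefix = "zone", ...) {
  zs <- zone_levels()
  combos <- utils::combn(zs, 2)
  out <- lapply(seq_len(ncol(combos)), function(i) {
    a <- combos[1, i]; b <- combos[2, i]
    w <- stats::setNames(c(1, -1), paste0(prefix, c(a, b)))
    contrast(draws, w, name = paste0(a, " - ", b), ...)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Averaged elevation effect of the richness model
#'
#' Per draw, the mean over the five stages of the stage-specific
#' elevation slope: the baseline slope (gap) plus each
#' stage-by-elevation interaction (the gap term being the baseline slope
#' alone).
#'
#' @param draws A `stagespec_draws` from [fit_richness_model()].
#' @param ... Passed to [summarize_draws()].
#' @return One-row summary with `attr(, "draws")`.
#' @export
averaged_elevation_effect <- function(draws, ...) {
  stopifnot(inherits(draws, "stagespec_draws"))
  cn <- colnames(draws$draws)
  if (!"elev_z" %in% cn) stop("no elevation slope in draws", call. = FALSE)
  base <- draws$draws[, "elev_z"]
  ints <- grep(":elev_z$", cn, value = TRUE)
  slopes <- vapply(stage_levels(), function(s) {
    term <- paste0("stage", s, ":elev_z")
    if (term %in% ints) base + draws$draws[, term] else base
  }, numeric(nrow(draws$draws)))
  x <- rowMeans(slopes)
  res <- summarize_draws(
    matrix(x, ncol = 1, dimnames = list(NULL, "averaged_elevation")),
    response_sd = draws$response_sd, ...)
  attr(res, "draws") <- x
  res
}

#' Percent change per SD of a log-link coefficient
#'
#' Converts a log-scale slope to the percent change of the expected
#' response per one-SD increase of the predictor: `(exp(b) - 1) * 100`.
#'
#' @param draws A `stagespec_draws` (log-link model), or a numeric draw
#'   vector (e.g. `attr(averaged_elevation_effect(d), "draws")`).
#' @param coefficient Coefficient name when `draws` is a
#'   `stagespec_draws`.
#' @param response_sd Link-scale response SD used for the ROPE; taken
#'   from `draws` when it is a `stagespec_draws`. The default link-scale
#'   ROPE half-width `0.1 * response_sd` is mapped through the same
#'   exp-transform onto the percent scale.
#' @param ... Passed to [summarize_draws()].
#' @return One-row summary with `attr(, "draws")` (percent scale).
#' @export
percent_change_per_sd <- function(draws, coefficient = "elev_z",
                                  response_sd = NULL, ...) {
  if (inherits(draws, "stagespec_draws")) {
    x <- draws$draws[, coefficient]
    if (is.null(response_sd)) response_sd <- draws$response_sd
  } else {
    x <- as.numeric(draws)
  }
  if (is.null(response_sd)) {
    stop("response_sd required for raw draw input", call. = FALSE)
  }
  pc <- (exp(x) - 1) * 100
  rope_halfwidth_pct <- (exp(0.1 * response_sd) - 1) * 100
  res <- summarize_draws(
    matrix(pc, ncol = 1, dimnames = list(NULL, "percent_change_per_sd")),
    response_sd = rope_halfwidth_pct / 0.1, ...)
  attr(res, "draws") <- pc
  res
}

#' Stage-by-elevation richness predictions
#'
#' Expected richness (response scale, random intercepts marginalized at
#' zero, day covariate at its mean) for every stage at each requested
#' elevation.
#'
#' @param draws A `stagespec_draws` from [fit_richness_model()].
#' @param elevations Numeric elevations in metres (e.g. the central
#'   elevation of each zone); standardized internally with the transform
#'   stored at fit time.
#' @return 3-d array `[draw, stage, elevation]` of expected richness;
#'   class `richness_predictions`.
#' @export
predict_richness <- function(draws, elevations) {
  stopifnot(inherits(draws, "stagespec_draws"))
  if (is.null(draws$meta$elev)) {
    stop("draws do not come from the richness model", call. = FALSE)
  }
  ez <- (elevations - draws$meta$elev$mean) / draws$meta$elev$sd
  cn <- colnames(draws$draws)
  nd <- nrow(draws$draws)
  out <- array(NA_real_, c(nd, 5, length(elevations)),
               dimnames = list(NULL, stage_levels(),
                               as.character(elevations)))
  for (si in seq_along(stage_levels())) {
    s <- stage_levels()[si]
    b_stage <- if (si == 1) 0 else draws$draws[, paste0("stage", s)]
    b_int_name <- paste0("stage", s, ":elev_z")
    b_int <- if (b_int_name %in% cn) draws$draws[, b_int_name] else 0
    for (ei in seq_along(ez)) {
      eta <- draws$draws[, "(Intercept)"] + b_stage +
        (draws$draws[, "elev_z"] + b_int) * ez[ei]
      out[, si, ei] <- exp(eta)
    }
  }
  structure(out, class = c("richness_predictions", "array"),
            response_sd_raw = draws$meta$response_sd_raw)
}

#' Min-max normalization
#'
#' Rescale to `[0, 1]` by the vector's own minimum and maximum (used to
#' show all taxa's richness predictions on one scale).
#'
#' @param x Numeric vector with `max(x) > min(x)`.
#' @return Rescaled vector.
#' @export
normalize_minmax <- function(x) {
  r <- range(x)
  if (r[2] == r[1]) stop("constant vector cannot be min-max normalized",
                         call. = FALSE)
  (x - r[1]) / (r[2] - r[1])
}

#' Difference-of-differences of stage contrasts across zones
#'
#' For each non-optimum stage `s` and zone `z`, the within-zone gap
#' `d_z(s) = |pred_z(s) - pred_z(optimum)|` measures how much richness at
#' stage `s` departs from the optimum stage. The difference-of-
#' differences `d_submontane(s) - d_montane(s)` and
#' `d_submontane(s) - d_subalpine(s)` tests whether stage differences are
#' stronger at low elevation.
#'
#' @param pred A `richness_predictions` array whose third dimension holds
#'   the three zones' central elevations in zone order (submontane,
#'   montane, subalpine).
#' @param ... Passed to [summarize_draws()].
#' @return Data frame with one summary row per stage and comparison.
#' @export
difference_of_differences <- function(pred, ...) {
  stopifnot(inherits(pred, "richness_predictions"), dim(pred)[3] == 3)
  sd_raw <- attr(pred, "response_sd_raw")
  stages <- setdiff(stage_levels(), "optimum")
  rows <- list()
  for (s in stages) {
    d <- vapply(1:3, function(z) abs(pred[, s, z] - pred[, "optimum", z]),
                numeric(dim(pred)[1]))
    for (cmp in c(2, 3)) {
      x <- d[, 1] - d[, cmp]
      nm <- paste0(s, ": submontane - ", zone_levels()[cmp])
      res <- summarize_draws(
        matrix(x, ncol = 1, dimnames = list(NULL, nm)),
        response_sd = sd_raw, ...)
      attr(res, "draws") <- x
      rows[[nm]] <- res
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
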