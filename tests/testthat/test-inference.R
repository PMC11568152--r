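test_that("z-transform is exact, idempotent and guards constants", {
  z <- zscore(c(1, 2, 3))
  expect_equal(z$z, c(-1, 0, 1))
  expect_equal(z$mean, 2)
  expect_equal(z$sd, 1)
  x <- rnorm(50)
  z1 <- zscore(x)
  expect_equal(zscore(z1$z)$z, z1$z, tolerance = 1e-12)
  expect_equal(z1$z * z1$sd + z1$mean, x)          # exact inverse
  expect_error(zscore(rep(2, 10)), "constant")
})

test_that("summary engine matches closed-form normal quantities", {
  set.seed(1)
  x <- rnorm(1e5)
  s <- summarize_draws(matrix(x, dimnames = list(NULL, "x")),
                       response_sd = 1)
  expect_lt(abs(s$hdi_low - (-1.96)), 0.05)
  expect_lt(abs(s$hdi_high - 1.96), 0.05)
  expect_lt(abs(s$pd - 0.5), 0.01)
  mass <- mean(x >= s$hdi_low & x <= s$hdi_high)
  expect_gte(mass, 0.945)
  expect_lte(mass, 0.955)

  # pd tracks the one-sided tail of the z-test: pd = 1 - p/2
  for (shift in c(0.5, 1, 2)) {
    pdv <- prob_direction(x + shift)
    expect_lt(abs(pdv - stats::pnorm(shift)), 0.01)
  }

  # degenerate draws: all inside ROPE, certain direction
  s0 <- summarize_draws(matrix(rep(0.001, 2000),
                               dimnames = list(NULL, "c")),
                        response_sd = 1)
  expect_equal(s0$rope_pct, 100)
  expect_equal(s0$pd, 1)
  s5 <- summarize_draws(matrix(rnorm(2000, 5),
                               dimnames = list(NULL, "c")),
                        response_sd = 1)
  expect_equal(s5$rope_pct, 0)
  expect_equal(s5$pd, 1)
  expect_error(summarize_draws(matrix(rnorm(500),
                                      dimnames = list(NULL, "c")),
                               response_sd = 1), "1000 draws")
})

test_that("contrasts are linear and self-contrasts collapse to zero", {
  set.seed(2)
  d <- new_draws(cbind(A = rnorm(2000, 1), B = rnorm(2000),
                       C = rnorm(2000, -1)), response_sd = 1)
  ab <- contrast(d, c(A = 1, B = -1))
  bc <- contrast(d, c(B = 1, C = -1))
  ac <- contrast(d, c(A = 1, C = -1))
  expect_equal(attr(ab, "draws") + attr(bc, "draws"), attr(ac, "draws"))
  self <- contrast(d, c(A = 1, A = -1), name = "self")
  expect_true(all(attr(self, "draws") == 0))
  expect_equal(self$rope_pct, 100)
  expect_error(contrast(d, c(Z = 1)), "unknown coefficient")
})

test_that("averaged elevation effect is the stage mean of injected slopes", {
  n <- 2000
  ints <- c(establishment = 0.1, optimum = 0.2, plenter = -0.1,
            terminal = -0.2)
  cols <- cbind(`(Intercept)` = rep(1, n), elev_z = rep(0.3, n))
  for (s in names(ints)) {
    cols <- cbind(cols, rep(ints[[s]], n))
    colnames(cols)[ncol(cols)] <- paste0("stage", s, ":elev_z")
  }
  d <- new_draws(cols, response_sd = 1)
  avg <- averaged_elevation_effect(d)
  expect_equal(unique(attr(avg, "draws")), 0.3)   # interactions average out

  # zero interactions: equals the baseline slope draws
  d0 <- new_draws(cbind(`(Intercept)` = rnorm(n),
                        elev_z = rnorm(n, 0.2, 0.01)),
                  response_sd = 1)
  expect_equal(attr(averaged_elevation_effect(d0), "draws"),
               unname(d0$draws[, "elev_z"]))
})

test_that("percent change inverts the log-scale convention exactly", {
  b <- rep(log(0.839), 2000)
  pc <- percent_change_per_sd(b, response_sd = 1)
  expect_equal(unique(attr(pc, "draws")), -16.1, tolerance = 1e-10)
  z <- percent_change_per_sd(rep(0, 2000), response_sd = 1)
  expect_equal(unique(attr(z, "draws")), 0)
  # monotone in the coefficient
  pcs <- vapply(c(-0.2, 0, 0.2), function(bb)
    attr(percent_change_per_sd(rep(bb, 1000), response_sd = 1),
         "draws")[1], numeric(1))
  expect_true(all(diff(pcs) > 0))
})

test_that("difference-of-differences reproduces hand-computed fixtures", {
  n <- 1000
  build_pred <- function(gap_by_zone, opt = 4) {
    a <- array(opt, c(n, 5, 3),
               dimnames = list(NULL, stage_levels(), zone_levels()))
    for (z in 1:3) a[, "gap", z] <- gap_by_zone[z]
    structure(a, class = c("richness_predictions", "array"),
              response_sd_raw = 1)
  }
  # gap (10, 6, 6) vs optimum (4, 4, 4): |10-4| - |6-4| = 4
  dod <- difference_of_differences(build_pred(c(10, 6, 6)))
  gap_rows <- dod[grepl("^gap", dod$name), ]
  expect_equal(gap_rows$map, c(4, 4))
  # all other stages are zone-homogeneous: exactly 0
  other <- dod[!grepl("^gap", dod$name), ]
  expect_true(all(other$map == 0))
  expect_true(all(other$rope_pct == 100))
  # adding a constant to every stage of one zone leaves its gaps unchanged
  shifted <- build_pred(c(10, 6, 6))
  shifted[, , 2] <- shifted[, , 2] + 7
  expect_equal(difference_of_differences(shifted)$map, dod$map)
})

test_that("the SES location-scale model recovers means and dispersion", {
  d <- mini_design(17)  # 17 plots per cell -> 85 per zone
  truth <- c(submontane = 1, montane = 0, subalpine = -1)
  sds <- c(submontane = 0.3, montane = 0.3, subalpine = 0.3)
  set.seed(30)
  ps <- data.frame(plot_id = d$plot_id, zone = as.character(d$zone),
                   mean_ses = rnorm(nrow(d), truth[as.character(d$zone)],
                                    sds[as.character(d$zone)]),
                   n_species = 10L)
  dr <- fit_ses_model(ps, d, n_draws = 2000, seed = 31)
  s <- summarize_draws(dr, names = paste0("zone", zone_levels()))
  expect_lt(max(abs(s$map - truth)), 0.15)
  ct <- contrast(dr, c(zonesubmontane = 1, zonesubalpine = -1))
  expect_lt(abs(ct$map - 2), 0.3)
  expect_gt(ct$pd, 0.99)

  # heteroscedastic data: dispersion contrast detected
  set.seed(32)
  ps2 <- ps
  sds2 <- c(submontane = 0.2, montane = 0.2, subalpine = 0.8)
  ps2$mean_ses <- rnorm(nrow(d), truth[ps$zone], sds2[ps$zone])
  dr2 <- fit_ses_model(ps2, d, n_draws = 2000, seed = 33)
  dct <- contrast(dr2, stats::setNames(c(1, -1),
                                       paste0("d~zone",
                                              c("subalpine", "submontane"))))
  expect_gt(dct$pd, 0.99)
})

test_that("richness model recovers an injected elevation slope", {
  d <- generate_design(design_config(seed = 40))
  elev_z <- as.numeric(scale(d$elevation_m))
  maps <- vapply(1:5, function(seed) {
    set.seed(seed)
    mu <- exp(3 + 0.2 * elev_z)
    rich <- data.frame(plot_id = d$plot_id, taxon = "sim",
                       richness = rpois(nrow(d), mu))
    dr <- fit_richness_model(rich, d, n_draws = 2000, seed = seed)
    summarize_draws(dr, names = "elev_z")$map
  }, numeric(1))
  expect_lt(abs(mean(maps) - 0.2), 0.05)

  # zero-interaction simulation at a size where negligibility is
  # estimable; averaged over realizations because a single draw can
  # materialize a spurious trend that all interactions inherit
  d_big <- mini_design(200)
  int_names <- NULL
  reps <- lapply(1:5, function(seed) {
    set.seed(50 + seed)
    rich <- data.frame(plot_id = d_big$plot_id, taxon = "sim",
                       richness = rnbinom(nrow(d_big), mu = exp(3),
                                          size = 10))
    dr <- fit_richness_model(rich, d_big, n_draws = 2000, seed = seed)
    int_names <<- grep(":elev_z$", colnames(dr$draws), value = TRUE)
    summarize_draws(dr, names = int_names)
  })
  maps <- sapply(reps, `[[`, "map")
  ropes <- sapply(reps, `[[`, "rope_pct")
  expect_true(all(abs(rowMeans(maps)) < 0.03))
  expect_true(all(rowMeans(ropes) > 50))
})

test_that("richness predictions follow the closed form and normalize", {
  d <- generate_design(design_config(seed = 41))
  set.seed(42)
  rich <- data.frame(plot_id = d$plot_id, taxon = "sim",
                     richness = rpois(nrow(d),
                                      exp(2 + 0.5 * (d$stage == "gap"))))
  dr <- fit_richness_model(rich, d, n_draws = 2000, seed = 43)
  pred <- predict_richness(dr, mean(d$elevation_m))
  # at the training mean elevation, elev_z = 0: exp(intercept + offset)
  expected_gap <- exp(dr$draws[, "(Intercept)"])
  expect_equal(unname(pred[, "gap", 1]), unname(expected_gap),
               tolerance = 1e-10)
  expected_opt <- exp(dr$draws[, "(Intercept)"] +
                        dr$draws[, "stageoptimum"])
  expect_equal(unname(pred[, "optimum", 1]), unname(expected_opt),
               tolerance = 1e-10)

  m <- apply(pred[, , 1], 2, mean)
  nm <- normalize_minmax(m)
  expect_equal(min(nm), 0)
  expect_equal(max(nm), 1)
  expect_error(normalize_minmax(rep(1, 4)), "constant")
})

test_that("beta model separates zone means and shrinks boundary values", {
  d <- generate_design(design_config(seed = 60))
  pairs <- cross_stage_pairs(d, "all")
  da <- match(pairs$plot_a, d$plot_id)
  db <- match(pairs$plot_b, d$plot_id)
  pairs$spatial_distance_m <- sqrt((d$x_m[da] - d$x_m[db])^2 +
                                     (d$y_m[da] - d$y_m[db])^2)
  pairs$elevational_distance_m <- abs(d$elevation_m[da] -
                                        d$elevation_m[db])
  pairs$day_difference <- abs(d$day_of_year[da] - d$day_of_year[db])
  mu <- c(submontane = 0.8, montane = 0.4, subalpine = 0.4)[pairs$zone]
  set.seed(61)
  pairs$jaccard <- rbeta(nrow(pairs), mu * 30, (1 - mu) * 30)
  dr <- fit_beta_model(pairs, n_draws = 2000, seed = 62)
  ct <- contrast(dr, c(zonesubmontane = 1, zonemontane = -1))
  expect_gt(ct$pd, 0.99)
  expect_lt(abs(plogis(summarize_draws(dr, "zonesubmontane")$map) - 0.8),
            0.05)

  # exact boundary responses are shrunk, not fatal
  pairs$jaccard[1:5] <- 1
  expect_silent(fit_beta_model(pairs, n_draws = 1000, seed = 63))
  expect_error(fit_beta_model(pairs[1:5, ], seed = 1), "at least 10")
})

test_that("a backend refit on simulated responses agrees with the draws", {
  # cross-check of the normal-approximation draws against a small
  # parametric bootstrap: refit on responses simulated from the ML fit
  d <- mini_design(17)
  set.seed(70)
  truth <- c(submontane = 0.8, montane = 0.2, subalpine = -0.4)
  ps <- data.frame(plot_id = d$plot_id, zone = as.character(d$zone),
                   mean_ses = rnorm(nrow(d), truth[as.character(d$zone)],
                                    0.4),
                   n_species = 10L)
  dr <- fit_ses_model(ps, d, random_intercept = FALSE, n_draws = 2000,
                      seed = 71)
  fit <- dr$meta$fit
  boot <- replicate(60, {
    ps2 <- ps
    ps2$mean_ses <- stats::simulate(fit)[[1]]
    glmmTMB::fixef(glmmTMB::glmmTMB(
      mean_ses ~ 0 + zone, dispformula = ~ 0 + zone,
      data = merge(ps2, as.data.frame(d)[, c("plot_id", "spatial_group")],
                   by = "plot_id"),
      family = stats::gaussian()))$cond
  })
  zn <- paste0("zone", zone_levels())
  approx_map <- summarize_draws(dr, names = zn)$map
  boot_mean <- rowMeans(boot)[zn]
  post_sd <- apply(dr$draws[, zn], 2, sd)
  expect_true(all(abs(approx_map - boot_mean) < 0.5 * post_sd + 1e-8))
})
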