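# End-to-end orchestration: simulate -> specialize -> diversity -> infer.

#' Pipeline run configuration
#'
#' Either a named scenario from [scenario_suite()] or paths to a plot
#' table and incidence files. The master seed is mandatory; every
#' downstream random stage uses a seed derived deterministically from it
#' and the stage/taxon labels, so adding a taxon never perturbs another
#' taxon's results.
#'
#' @param scenario Scenario name (see [scenario_suite()]), or `NULL` when
#'   reading data from files.
#' @param plots_path,incidence_paths File inputs used when `scenario` is
#'   `NULL`; `incidence_paths` is a named (by taxon) vector of wide-CSV
#'   paths.
#' @param day_covariate Named logical per taxon (or single logical):
#'   include the day-of-year covariate in the richness and beta models.
#' @param n_null Null communities per zone for the SES.
#' @param n_draws Coefficient draws per model.
#' @param seed Master integer seed (mandatory).
#' @param out_dir Optional directory: intermediate CSV tables and
#'   `report.json` are written there.
#' @return A `run_config` list.
#' @export
run_config <- function(scenario = NULL, plots_path = NULL,
                       incidence_paths = NULL, day_covariate = FALSE,
                       n_null = 500, n_draws = 4000, seed = NULL,
                       out_dir = NULL) {
  if (is.null(seed)) stop("a master seed is mandatory", call. = FALSE)
  if (is.null(scenario) &&
      (is.null(plots_path) || is.null(incidence_paths))) {
    stop("either a scenario name or input paths must be given",
         call. = FALSE)
  }
  structure(list(scenario = scenario, plots_path = plots_path,
                 incidence_paths = incidence_paths,
                 day_covariate = day_covariate,
                 n_null = as.integer(n_null),
                 n_draws = as.integer(n_draws),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

# deterministic sub-seed below 2^31 from the master seed and labels
derive_seed <- function(seed, ...) {
  labels <- paste(c(...), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(labels)) h <- (h * 131 + ch) %% 1000003
  as.integer((as.numeric(seed) * 1009 + h) %% .Machine$integer.max)
}

#' Run the full analysis pipeline
#'
#' Generates (or reads) the design and incidence tables, computes the
#' specialization SES and its plot means, per-plot richness, the
#' cross-stage dissimilarity table, fits the three model families, and
#' assembles the four hypothesis tables:
#' \describe{
#'   \item{H1}{pairwise zone contrasts of mean plot SES (does
#'     specialization decrease with elevation?).}
#'   \item{H2}{averaged elevation effect on richness and its percent
#'     change per SD of elevation.}
#'   \item{H3}{pairwise zone contrasts of cross-stage Jaccard
#'     dissimilarity.}
#'   \item{H4}{difference-of-differences of stage richness gaps across
#'     zones, predicted at each zone's central elevation.}
#' }
#'
#' @param config A [run_config()].
#' @return A `stagespec_report`: list with `descriptives`, per-taxon
#'   `h1`--`h4` tables, and a `provenance` block (seed, sizes, exclusion
#'   counts). Identical configs give identical reports.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (!is.null(config$scenario)) {
    suite <- scenario_suite(config$scenario, seed = config$seed)
    design <- generate_design(suite$design_config)
    incs <- lapply(suite$scenarios, function(sc) {
      sc$seed <- derive_seed(config$seed, "communities", sc$taxon)
      generate_communities(design, sc)
    })
    names(incs) <- vapply(suite$scenarios, `[[`, "", "taxon")
  } else {
    design <- read_plots(config$plots_path)
    incs <- lapply(names(config$incidence_paths), function(tx)
      read_incidence(config$incidence_paths[[tx]], "wide_csv",
                     taxon = tx, design = design))
    names(incs) <- names(config$incidence_paths)
  }
  day_flags <- config$day_covariate
  if (length(day_flags) == 1 && is.null(names(day_flags))) {
    day_flags <- stats::setNames(rep(day_flags, length(incs)), names(incs))
  }

  taxa <- names(incs)
  report <- list(descriptives = summarize_descriptives(incs, design),
                 taxa = list(),
                 provenance = list(
                   seed = config$seed, n_null = config$n_null,
                   n_draws = config$n_draws,
                   scenario = config$scenario,
                   n_plots = nrow(design),
                   package_version =
                     as.character(utils::packageVersion("stagespec"))))
  for (tx in taxa) {
    inc <- incs[[tx]]

    set.seed(derive_seed(config$seed, "ses", tx))
    ses <- ses_specialization(inc, design, "all", n_null = config$n_null)
    pses <- plot_mean_ses(ses, inc, design)
    ses_draws <- fit_ses_model(
      pses, design, n_draws = config$n_draws,
      seed = derive_seed(config$seed, "ses_model", tx))
    h1 <- zone_contrasts(ses_draws)

    rich <- species_richness(inc)
    rich_draws <- fit_richness_model(
      rich, design, day_covariate = isTRUE(day_flags[[tx]]),
      n_draws = config$n_draws,
      seed = derive_seed(config$seed, "richness_model", tx))
    avg <- averaged_elevation_effect(rich_draws)
    pct <- percent_change_per_sd(attr(avg, "draws"),
                                 response_sd = rich_draws$response_sd)
    h2 <- rbind(avg, pct)

    pairs <- withCallingHandlers(
      dissimilarity_table(inc, design),
      warning = function(w) invokeRestart("muffleWarning"))
    beta_draws <- fit_beta_model(
      pairs, day_covariate = isTRUE(day_flags[[tx]]),
      n_draws = config$n_draws,
      seed = derive_seed(config$seed, "beta_model", tx))
    h3 <- zone_contrasts(beta_draws)

    central <- vapply(zone_levels(), function(z)
      mean(design$elevation_m[design$zone == z]), numeric(1))
    pred <- predict_richness(rich_draws, central)
    h4 <- difference_of_differences(pred)

    report$taxa[[tx]] <- list(
      h1 = h1, h2 = h2, h3 = h3, h4 = h4,
      exclusions = list(
        ses_excluded_species = sum(ses$excluded),
        ses_species = nrow(ses),
        empty_union_pairs_dropped = attr(pairs, "n_dropped")))
  }
  class(report) <- "stagespec_report"
  if (!is.null(config$out_dir)) {
    write_report(report, design, incs, config$out_dir)
  }
  report
}

#' @export
print.stagespec_report <- function(x, ...) {
  cat("stagespec report —", length(x$taxa), "taxon/taxa, seed",
      x$provenance$seed, "\n")
  for (tx in names(x$taxa)) {
    cat("\n==", tx, "==\n")
    cat("H I  zone SES contrasts:\n")
    print(x$taxa[[tx]]$h1, digits = 3)
    cat("H II averaged elevation effect on richness:\n")
    print(x$taxa[[tx]]$h2, digits = 3)
  }
  invisible(x)
}

# strip non-serializable attributes and write the machine-readable report
write_report <- function(report, design, incs, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_plots(design, file.path(out_dir, "plots.csv"))
  for (tx in names(incs)) {
    write_incidence(incs[[tx]], file.path(out_dir,
                                          paste0("incidence_", tx, ".csv")))
  }
  clean <- rapply(unclass(report), function(x) {
    attributes(x)[setdiff(names(attributes(x)),
                          c("names", "row.names", "class"))] <- NULL
    x
  }, how = "replace")
  jsonlite::write_json(clean, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(out_dir)
}

#' Descriptive community statistics
#'
#' Per taxon: the mean number of developmental stages used per species
#' (over the whole design), the mean per-plot species richness, and the
#' mean cross-stage Jaccard dissimilarity.
#'
#' @param incs Named list of `incidence_table`s.
#' @param design A `stagespec_design`.
#' @return Data frame with one row per taxon.
#' @export
summarize_descriptives <- function(incs, design) {
  if (inherits(incs, "incidence_table")) incs <- list(incs)
  out <- lapply(incs, function(inc) {
    m <- t(inc$matrix)          # species x plots
    m <- m[rowSums(m) > 0, , drop = FALSE]
    counts <- stage_counts(m, design)
    stages_used <- rowSums(counts > 0)
    pairs <- withCallingHandlers(
      dissimilarity_table(inc, design),
      warning = function(w) invokeRestart("muffleWarning"))
    data.frame(taxon = inc$taxon,
               n_species = nrow(m),
               mean_stages_used = mean(stages_used),
               mean_plot_richness = mean(rowSums(inc$matrix)),
               mean_cross_stage_jaccard = mean(pairs$jaccard),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
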