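# Per-plot species richness and cross-stage Jaccard dissimilarity.

#' Per-plot species richness
#'
#' @param inc An `incidence_table`.
#' @return Data frame `plot_id`, `taxon`, `richness` (number of species
#'   recorded at the plot).
#' @export
species_richness <- function(inc) {
  data.frame(plot_id = rownames(inc$matrix), taxon = inc$taxon,
             richness = as.integer(rowSums(inc$matrix)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Jaccard dissimilarity of two species sets
#'
#' `1 - |intersection| / |union|`; undefined (error) when both sets are
#' empty — such plot pairs are dropped upstream with a warning.
#'
#' @param a,b Character vectors of species identifiers.
#' @return Dissimilarity in `[0, 1]`.
#' @export
jaccard_dissimilarity <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0) stop("Jaccard undefined for two empty sets", call. = FALSE)
  1 - length(intersect(a, b)) / u
}

#' All same-zone, cross-stage plot pairs
#'
#' Unordered pairs of plots from the same elevational zone but different
#' developmental stages — the comparisons over which beta diversity is
#' assessed.
#'
#' @param design A `stagespec_design`.
#' @param zone One of [zone_levels()], or `"all"`.
#' @return Data frame `plot_a`, `plot_b`, `zone`, `stage_a`, `stage_b`.
#' @export
cross_stage_pairs <- function(design, zone = "all") {
  if (identical(zone, "all")) {
    out <- lapply(zone_levels(), function(z) cross_stage_pairs(design, z))
    return(do.call(rbind, out))
  }
  zone <- match.arg(zone, zone_levels())
  d <- design[design$zone == zone, , drop = FALSE]
  n <- nrow(d)
  if (n < 2) {
    return(data.frame(plot_a = character(0), plot_b = character(0),
                      zone = character(0), stage_a = character(0),
                      stage_b = character(0)))
  }
  idx <- utils::combn(n, 2)
  keep <- d$stage[idx[1, ]] != d$stage[idx[2, ]]
  data.frame(plot_a = d$plot_id[idx[1, keep]],
             plot_b = d$plot_id[idx[2, keep]],
             zone = rep(zone, sum(keep)),
             stage_a = as.character(d$stage[idx[1, keep]]),
             stage_b = as.character(d$stage[idx[2, keep]]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Cross-stage pairwise dissimilarity table
#'
#' Jaccard dissimilarity for every same-zone cross-stage plot pair,
#' together with the covariates of the beta-diversity model: planar
#' Euclidean distance, absolute elevation difference and (when sampling
#' days are recorded) absolute day-of-year difference. Pairs whose two
#' plots both host no species (empty union) are excluded with a warning,
#' because the downstream beta regression needs a defined response;
#' their count is recorded in `attr(, "n_dropped")`.
#'
#' Jaccard values of exactly 0 or 1 are kept as is here; boundary
#' shrinkage happens only inside the model fit.
#'
#' @param inc An `incidence_table`.
#' @param design A `stagespec_design`.
#' @param zone One of [zone_levels()], or `"all"`.
#' @return Data frame `plot_a`, `plot_b`, `zone`, `stage_a`, `stage_b`,
#'   `jaccard`, `spatial_distance_m`, `elevational_distance_m`,
#'   `day_difference`.
#' @export
dissimilarity_table <- function(inc, design, zone = "all") {
  check_incidence_against_design(inc, design)
  pairs <- cross_stage_pairs(design, zone)
  if (nrow(pairs) == 0) {
    pairs$jaccard <- numeric(0)
    pairs$spatial_distance_m <- numeric(0)
    pairs$elevational_distance_m <- numeric(0)
    pairs$day_difference <- integer(0)
    return(pairs)
  }
  m <- inc$matrix
  ia <- match(pairs$plot_a, rownames(m))
  ib <- match(pairs$plot_b, rownames(m))
  if (anyNA(ia) || anyNA(ib)) {
    stop("design contains plots missing from the incidence table",
         call. = FALSE)
  }
  inter <- rowSums(m[ia, , drop = FALSE] * m[ib, , drop = FALSE])
  uni <- rowSums((m[ia, , drop = FALSE] + m[ib, , drop = FALSE]) > 0)
  da <- match(pairs$plot_a, design$plot_id)
  db <- match(pairs$plot_b, design$plot_id)
  pairs$jaccard <- ifelse(uni > 0, 1 - inter / uni, NA_real_)
  pairs$spatial_distance_m <- sqrt(
    (design$x_m[da] - design$x_m[db])^2 +
      (design$y_m[da] - design$y_m[db])^2)
  pairs$elevational_distance_m <-
    abs(design$elevation_m[da] - design$elevation_m[db])
  pairs$day_difference <-
    abs(design$day_of_year[da] - design$day_of_year[db])
  n_dropped <- sum(uni == 0)
  if (n_dropped > 0) {
    warning(n_dropped, " pair(s) with empty species union dropped")
    pairs <- pairs[uni > 0, , drop = FALSE]
    rownames(pairs) <- NULL
  }
  attr(pairs, "n_dropped") <- n_dropped
  pairs
}
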