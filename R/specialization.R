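# Habitat specialization: niche breadth B, fixed-margin null model, SES.

#' Niche breadth (reciprocal Simpson index)
#'
#' `B = 1 / sum(p_i^2)` of a proportional-use vector over habitat
#' categories; 1 for a perfect specialist, `k` for perfectly even use of
#' `k` categories.
#'
#' @param p Non-negative proportions summing to 1.
#' @return Breadth `B` in `[1, length(p)]`.
#' @export
niche_breadth <- function(p) {
  stopifnot(is.numeric(p), all(p >= 0))
  s <- sum(p)
  if (s == 0) stop("all-zero proportional-use vector", call. = FALSE)
  if (abs(s - 1) > 1e-8) stop("proportions must sum to 1", call. = FALSE)
  1 / sum(p^2)
}

#' Proportional use of developmental stages within a zone
#'
#' For each species occurring in the zone, the fraction of its occupied
#' plots falling in each of the five stages, and the resulting breadth
#' `B`. Species with zero occupancy in the zone are dropped.
#'
#' @param inc An `incidence_table`.
#' @param design A `stagespec_design`.
#' @param zone One of [zone_levels()].
#' @return Data frame with columns `species_id`, `zone`, `n_occupied`,
#'   `p_gap` ... `p_terminal`, `B`.
#' @export
proportional_use <- function(inc, design, zone) {
  zone <- match.arg(zone, zone_levels())
  check_incidence_against_design(inc, design)
  sub <- zone_submatrix(inc, design, zone)
  if (nrow(sub) == 0) stop("zone '", zone, "' has no plots", call. = FALSE)
  counts <- stage_counts(sub, design)          # species x 5
  n_occ <- rowSums(counts)
  p <- counts / n_occ
  out <- data.frame(species_id = rownames(counts), zone = zone,
                    n_occupied = as.integer(n_occ),
                    stringsAsFactors = FALSE)
  colnames(p) <- paste0("p_", stage_levels())
  out <- cbind(out, as.data.frame(p))
  out$B <- 1 / rowSums(p^2)
  rownames(out) <- NULL
  out
}

# zone submatrix in null-model orientation: rows = species occurring in
# the zone, columns = plots of the zone
zone_submatrix <- function(inc, design, zone) {
  plots <- design$plot_id[design$zone == zone]
  m <- t(inc$matrix[rownames(inc$matrix) %in% plots, , drop = FALSE])
  m[rowSums(m) > 0, , drop = FALSE]
}

# per-species occupied-plot counts by stage; m is species x plots
stage_counts <- function(m, design) {
  st <- as.character(design$stage[match(colnames(m), design$plot_id)])
  ind <- outer(st, stage_levels(), "==") * 1
  counts <- m %*% ind
  colnames(counts) <- stage_levels()
  counts
}

# breadth of every row of a species x plots matrix
breadth_from_matrix <- function(m, design) {
  counts <- stage_counts(m, design)
  n <- rowSums(counts)
  n^2 / rowSums(counts^2)
}

#' Fixed-margin permutation of a binary matrix
#'
#' Returns an independent null matrix with the same row sums, column sums
#' and total fill as the input. Each call restarts from the observed
#' matrix and performs `n_steps` trades (non-sequential null draws, not a
#' continuing Markov chain). `curveball` trades the symmetric difference
#' of two random rows; `trialswap` performs classical checkerboard swaps
#' and typically needs more steps to mix.
#'
#' @param m Binary matrix (rows = species, columns = plots).
#' @param method `"curveball"` (default) or `"trialswap"`.
#' @param n_steps Number of trades; default `max(1000, 5 * nrow(m))`
#'   (curveball) or ten times that (trialswap).
#' @return Binary matrix with identical margins.
#' @export
permute_fixed_margins <- function(m, method = c("curveball", "trialswap"),
                                  n_steps = NULL) {
  method <- match.arg(method)
  if (!is.matrix(m) || !all(m %in% c(0, 1))) {
    stop("input must be a binary matrix", call. = FALSE)
  }
  storage.mode(m) <- "integer"
  if (is.null(n_steps)) {
    n_steps <- max(1000L, 5L * nrow(m))
    if (method == "trialswap") n_steps <- 10L * n_steps
  }
  if (method == "curveball") {
    .curveball_cpp(m, as.integer(n_steps))
  } else {
    .trialswap_cpp(m, as.integer(n_steps))
  }
}

#' Standardized effect size of habitat specialization
#'
#' For one elevational zone, builds the species-by-plot submatrix
#' (species occurring in the zone, plots of the zone), simulates `n_null`
#' independent fixed-margin random communities, recomputes the breadth
#' `B` of every species under each, and standardizes:
#' `ses = -(B_obs - mean(B_null)) / sd(B_null)`. The sign flip turns the
#' index into a specialization measure (larger = more specialized). The
#' fixed margins remove the confound that species with more occurrences
#' use more stages by chance. Species whose null breadths have zero
#' standard deviation (e.g. species occupying every plot of the zone)
#' carry no information and are flagged `excluded`.
#'
#' @param inc An `incidence_table`.
#' @param design A `stagespec_design`.
#' @param zone One of [zone_levels()], or `"all"` to stack all three.
#' @param n_null Number of null communities (>= 2), default 500.
#' @param method Permutation algorithm, see [permute_fixed_margins()].
#' @param n_steps Trades per null draw; `NULL` for the method default.
#' @param matrix_scope `"zone"` (default) randomizes the per-zone
#'   submatrix, preserving per-zone occupancies — the scope under which
#'   the occupancy confound is corrected exactly. `"global"` randomizes
#'   the full design-wide matrix and restricts each null draw to the
#'   zone's plots afterwards, letting occurrences migrate between zones;
#'   a species can then miss the zone entirely in a draw (such draws are
#'   dropped from its null distribution).
#' @return Data frame with columns `species_id`, `zone`, `n_occupied`,
#'   `B_obs`, `null_mean`, `null_sd`, `ses`, `excluded`.
#' @export
ses_specialization <- function(inc, design, zone = "all", n_null = 500,
                               method = "curveball", n_steps = NULL,
                               matrix_scope = c("zone", "global")) {
  matrix_scope <- match.arg(matrix_scope)
  if (identical(zone, "all")) {
    out <- lapply(zone_levels(), function(z)
      ses_specialization(inc, design, z, n_null, method, n_steps,
                         matrix_scope))
    return(do.call(rbind, out))
  }
  zone <- match.arg(zone, zone_levels())
  if (n_null < 2) stop("n_null must be at least 2", call. = FALSE)
  check_incidence_against_design(inc, design)
  m <- zone_submatrix(inc, design, zone)
  if (nrow(m) == 0) {
    return(data.frame(species_id = character(0), zone = character(0),
                      n_occupied = integer(0), B_obs = numeric(0),
                      null_mean = numeric(0), null_sd = numeric(0),
                      ses = numeric(0), excluded = logical(0)))
  }
  b_obs <- breadth_from_matrix(m, design)
  b_null <- matrix(NA_real_, nrow(m), n_null)
  if (matrix_scope == "zone") {
    for (k in seq_len(n_null)) {
      b_null[, k] <- breadth_from_matrix(
        permute_fixed_margins(m, method, n_steps), design)
    }
  } else {
    g <- t(inc$matrix)
    g <- g[rowSums(g) > 0, , drop = FALSE]
    zone_cols <- colnames(g) %in% design$plot_id[design$zone == zone]
    ridx <- match(rownames(m), rownames(g))
    for (k in seq_len(n_null)) {
      pg <- permute_fixed_margins(g, method, n_steps)
      bz <- breadth_from_matrix(pg[ridx, zone_cols, drop = FALSE], design)
      b_null[, k] <- ifelse(is.finite(bz), bz, NA_real_)
    }
  }
  null_mean <- rowMeans(b_null, na.rm = TRUE)
  null_sd <- apply(b_null, 1, stats::sd, na.rm = TRUE)
  n_used <- rowSums(is.finite(b_null))
  excluded <- !is.finite(null_sd) | null_sd < 1e-12 | n_used < 2
  ses <- ifelse(excluded, NA_real_, -(b_obs - null_mean) / null_sd)
  data.frame(species_id = rownames(m), zone = zone,
             n_occupied = as.integer(rowSums(m)),
             B_obs = as.numeric(b_obs), null_mean = null_mean,
             null_sd = null_sd, ses = ses, excluded = excluded,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Plot-level mean specialization
#'
#' Averages the sign-flipped SES over the non-excluded species present at
#' each plot of the zone(s) covered by `ses`. Plots hosting no usable
#' species get `NA` with `n_species = 0`.
#'
#' @param ses Output of [ses_specialization()].
#' @param inc The `incidence_table` the SES was computed from.
#' @param design The `stagespec_design`.
#' @return Data frame `plot_id`, `zone`, `mean_ses`, `n_species`.
#' @export
plot_mean_ses <- function(ses, inc, design) {
  zones <- unique(ses$zone)
  out <- lapply(zones, function(z) {
    sz <- ses[ses$zone == z & !ses$excluded, , drop = FALSE]
    plots <- design$plot_id[design$zone == z]
    plots <- plots[plots %in% rownames(inc$matrix)]
    res <- data.frame(plot_id = plots, zone = z,
                      mean_ses = NA_real_, n_species = 0L,
                      stringsAsFactors = FALSE)
    if (nrow(sz) == 0) return(res)
    sub <- inc$matrix[plots, sz$species_id, drop = FALSE]
    n_sp <- rowSums(sub)
    res$n_species <- as.integer(n_sp)
    has <- n_sp > 0
    res$mean_ses[has] <- as.numeric((sub %*% sz$ses)[has] / n_sp[has])
    res
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
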