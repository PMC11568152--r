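# In-code fixtures: a small deterministic design on a grid (no rejection
# sampling) and hand-built incidence tables.

mini_design <- function(n_per_cell = 2) {
  stages <- stage_levels()
  zones <- zone_levels()
  grid <- expand.grid(rep = seq_len(n_per_cell), stage = stages,
                      zone = zones, stringsAsFactors = FALSE)
  n <- nrow(grid)
  mid <- c(submontane = 720, montane = 1150, subalpine = 1560)
  new_design(data.frame(
    plot_id = sprintf("p%03d", seq_len(n)),
    stage = grid$stage,
    zone = grid$zone,
    elevation_m = mid[grid$zone] + 10 * grid$rep,
    x_m = 200 * seq_len(n),          # 200 m grid: spacing trivially holds
    y_m = rep(0, n),
    spatial_group = paste0(substr(grid$zone, 1, 3), (grid$rep %% 2) + 1),
    day_of_year = 150L + (seq_len(n) %% 80L)
  ))
}

# incidence table from a named presence list: list(plot_id = c(species...))
incidence_from_list <- function(presences, design, taxon = "fix") {
  species <- sort(unique(unlist(presences)))
  mat <- matrix(0L, nrow(design), length(species),
                dimnames = list(design$plot_id, species))
  for (p in names(presences)) mat[p, presences[[p]]] <- 1L
  new_incidence(mat, taxon = taxon)
}

# brute-force Jaccard via explicit set construction (independent oracle
# for the vectorized table computation)
jaccard_brute <- function(mat, a, b) {
  sa <- colnames(mat)[mat[a, ] == 1]
  sb <- colnames(mat)[mat[b, ] == 1]
  both <- 0
  for (s in union(sa, sb)) if (s %in% sa && s %in% sb) both <- both + 1
  1 - both / length(union(sa, sb))
}
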