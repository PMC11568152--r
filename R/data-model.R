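# Domain types: study designs (plot metadata) and binary incidence tables.

#' Forest developmental stage levels
#'
#' The five successional classes used as habitat categories, in their
#' canonical order along forest development.
#'
#' @return Character vector of length 5.
#' @export
stage_levels <- function() {
  c("gap", "establishment", "optimum", "plenter", "terminal")
}

#' Elevational zone levels
#'
#' The three climatic elevation bands, ordered from low to high.
#'
#' @return Character vector of length 3.
#' @export
zone_levels <- function() {
  c("submontane", "montane", "subalpine")
}

#' Nominal elevation bands per zone (m a.s.l.)
#'
#' Band endpoints used for consistency reporting: submontane below 850 m,
#' montane 850--1400 m, subalpine 1400 m and above. Zone membership is an
#' explicit design column and never derived from elevation, because real
#' plots can fall slightly outside their nominal band.
#'
#' @return Named list of `c(lo, hi)` vectors.
#' @export
zone_bands <- function() {
  list(
    submontane = c(-Inf, 850),
    montane = c(850, 1400),
    subalpine = c(1400, Inf)
  )
}

#' Construct a study design from plot metadata
#'
#' A design is a data frame of plot records: one row per plot with its
#' developmental stage, elevational zone, elevation, planar coordinates,
#' spatial grouping (for random intercepts) and optional sampling day of
#' year. Stage and zone labels are case-folded to lower case before
#' validation.
#'
#' @param plots Data frame with columns `plot_id`, `stage`, `zone`,
#'   `elevation_m`, `x_m`, `y_m`, and optionally `spatial_group` and
#'   `day_of_year`.
#' @param strict Logical; if `TRUE`, elevations outside \[600, 1800\] m are an
#'   error. Zone-band consistency is always reported via
#'   [validate_design()], never enforced.
#' @return A `stagespec_design` data frame.
#' @export
new_design <- function(plots, strict = FALSE) {
  stopifnot(is.data.frame(plots))
  required <- c("plot_id", "stage", "zone", "elevation_m", "x_m", "y_m")
  missing_cols <- setdiff(required, names(plots))
  if (length(missing_cols) > 0) {
    stop("design is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  plots <- as.data.frame(plots, stringsAsFactors = FALSE)
  plots$plot_id <- as.character(plots$plot_id)
  if (anyDuplicated(plots$plot_id)) {
    dup <- unique(plots$plot_id[duplicated(plots$plot_id)])
    stop("duplicated plot_id: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  plots$stage <- tolower(trimws(as.character(plots$stage)))
  plots$zone <- tolower(trimws(as.character(plots$zone)))
  bad_stage <- which(!plots$stage %in% stage_levels())
  if (length(bad_stage) > 0) {
    stop("unknown stage label '", plots$stage[bad_stage[1]], "' in row ",
         bad_stage[1], call. = FALSE)
  }
  bad_zone <- which(!plots$zone %in% zone_levels())
  if (length(bad_zone) > 0) {
    stop("unknown zone label '", plots$zone[bad_zone[1]], "' in row ",
         bad_zone[1], call. = FALSE)
  }
  plots$stage <- factor(plots$stage, levels = stage_levels())
  plots$zone <- factor(plots$zone, levels = zone_levels())
  for (col in c("elevation_m", "x_m", "y_m")) {
    plots[[col]] <- as.numeric(plots[[col]])
    if (anyNA(plots[[col]])) {
      stop("non-numeric or missing values in column '", col, "'",
           call. = FALSE)
    }
  }
  if (strict &&
      any(plots$elevation_m < 600 | plots$elevation_m > 1800)) {
    stop("elevation_m outside [600, 1800] under strict validation",
         call. = FALSE)
  }
  if (is.null(plots$spatial_group)) {
    plots$spatial_group <- as.character(plots$zone)
  }
  plots$spatial_group <- as.character(plots$spatial_group)
  if (is.null(plots$day_of_year)) {
    plots$day_of_year <- NA_integer_
  } else {
    plots$day_of_year <- as.integer(plots$day_of_year)
    bad_day <- !is.na(plots$day_of_year) &
      (plots$day_of_year < 1 | plots$day_of_year > 366)
    if (any(bad_day)) {
      stop("day_of_year outside 1..366 in row ", which(bad_day)[1],
           call. = FALSE)
    }
  }
  plots <- plots[, c("plot_id", "stage", "zone", "elevation_m", "x_m", "y_m",
                     "spatial_group", "day_of_year")]
  rownames(plots) <- NULL
  class(plots) <- c("stagespec_design", "data.frame")
  plots
}

#' Report (without enforcing) design consistency checks
#'
#' @param design A `stagespec_design`.
#' @return Data frame with one row per check: plots per stage-by-zone cell
#'   versus the canonical 10, and zone-band mismatches. Validation never
#'   mutates the design.
#' @export
validate_design <- function(design) {
  stopifnot(inherits(design, "stagespec_design"))
  bands <- zone_bands()
  zb <- vapply(seq_len(nrow(design)), function(i) {
    b <- bands[[as.character(design$zone[i])]]
    design$elevation_m[i] >= b[1] && design$elevation_m[i] < b[2]
  }, logical(1))
  cell <- table(design$stage, design$zone)
  data.frame(
    check = c("n_plots", "cells_with_10_replicates", "zone_band_mismatches"),
    value = c(nrow(design), sum(cell == 10), sum(!zb)),
    expected = c(150, 15, 0)
  )
}

#' @export
print.stagespec_design <- function(x, ...) {
  cat("Study design:", nrow(x), "plots,",
      nlevels(droplevels(x$stage)), "stages x",
      nlevels(droplevels(x$zone)), "zones\n")
  NextMethod()
}

#' Construct a binary incidence table
#'
#' Plots-by-species presence/absence matrix for one taxonomic group.
#' Abundance-like inputs (values greater than 1) are thresholded to
#' presence with a warning: every statistic in this package is
#' incidence-based.
#'
#' @param mat Matrix with plots as rows and species as columns; dimnames
#'   give plot and species identifiers.
#' @param taxon Label for the taxonomic group.
#' @return An `incidence_table` object.
#' @export
new_incidence <- function(mat, taxon = "taxon") {
  stopifnot(is.matrix(mat))
  if (is.null(rownames(mat)) || (ncol(mat) > 0 && is.null(colnames(mat)))) {
    stop("incidence matrix needs plot (row) and species (column) names",
         call. = FALSE)
  }
  if (ncol(mat) == 0 && is.null(colnames(mat))) {
    colnames(mat) <- character(0)
  }
  if (anyDuplicated(rownames(mat)) || anyDuplicated(colnames(mat))) {
    stop("duplicated plot or species identifiers", call. = FALSE)
  }
  storage.mode(mat) <- "double"
  if (anyNA(mat) || any(mat < 0)) {
    stop("incidence entries must be non-negative and non-missing",
         call. = FALSE)
  }
  if (any(mat > 1)) {
    warning("abundance-like entries > 1 thresholded to presence (1)")
    mat[mat > 1] <- 1
  }
  if (!all(mat %in% c(0, 1))) {
    stop("incidence entries must be binary 0/1", call. = FALSE)
  }
  storage.mode(mat) <- "integer"
  structure(list(taxon = taxon, matrix = mat), class = "incidence_table")
}

#' @export
print.incidence_table <- function(x, ...) {
  cat("Incidence table [", x$taxon, "]: ", nrow(x$matrix), " plots x ",
      ncol(x$matrix), " species, fill ", sum(x$matrix), "\n", sep = "")
  invisible(x)
}

#' Plot identifiers of an incidence table
#' @param inc An `incidence_table`.
#' @return Character vector.
#' @export
incidence_plots <- function(inc) rownames(inc$matrix)

#' Species identifiers of an incidence table
#' @param inc An `incidence_table`.
#' @return Character vector.
#' @export
incidence_species <- function(inc) colnames(inc$matrix)

#' Check that an incidence table refers only to plots of a design
#'
#' @param inc An `incidence_table`.
#' @param design A `stagespec_design`.
#' @return Invisibly `TRUE`; errors if a plot is unknown to the design.
#' @export
check_incidence_against_design <- function(inc, design) {
  unknown <- setdiff(incidence_plots(inc), design$plot_id)
  if (length(unknown) > 0) {
    stop("incidence table refers to plot(s) absent from the design: ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

# ---- readers / writers ----------------------------------------------------

#' Read a plot metadata table
#'
#' Expects a UTF-8 CSV with header
#' `plot_id,stage,zone,elevation_m,x_m,y_m,spatial_group,day_of_year`
#' (the last two optional) and "." as decimal separator.
#'
#' @param path CSV file path.
#' @param strict Passed to [new_design()].
#' @return A `stagespec_design`.
#' @export
read_plots <- function(path, strict = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  new_design(df, strict = strict)
}

#' Write a plot metadata table
#'
#' @param design A `stagespec_design`.
#' @param path Output CSV path. Missing `day_of_year` is written as an
#'   empty field and read back as missing.
#' @return Invisibly `path`.
#' @export
write_plots <- function(design, path) {
  stopifnot(inherits(design, "stagespec_design"))
  out <- as.data.frame(design)
  out$stage <- as.character(out$stage)
  out$zone <- as.character(out$zone)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a binary incidence table
#'
#' Three plain-text layouts are supported:
#' \describe{
#'   \item{`wide_csv`}{first column `plot_id`, one 0/1 column per species;
#'     row and column order of the file is kept.}
#'   \item{`long_csv`}{columns `plot_id,species_id`, each row one presence;
#'     repeated records collapse to a single 1; plots and species are
#'     ordered lexicographically.}
#'   \item{`sparse_triplets`}{columns `row_index,col_index,value` (value
#'     must be 1) with sidecar files `<path>.plots` and `<path>.species`
#'     listing identifiers one per line; lexicographic ordering.}
#' }
#'
#' @param path Input file path.
#' @param format One of `"wide_csv"`, `"long_csv"`, `"sparse_triplets"`.
#' @param taxon Taxon label attached to the result.
#' @param design Optional `stagespec_design`; if given, plot ids are
#'   cross-validated against it.
#' @return An `incidence_table`.
#' @export
read_incidence <- function(path, format = c("wide_csv", "long_csv",
                                            "sparse_triplets"),
                           taxon = "taxon", design = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "wide_csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
    if (names(df)[1] != "plot_id") {
      stop("wide incidence CSV must start with a plot_id column",
           call. = FALSE)
    }
    plot_ids <- as.character(df$plot_id)
    mat <- as.matrix(df[, -1, drop = FALSE])
    if (length(mat) > 0 && !all(mat %in% c(0, 1))) {
      stop("non-binary cell in wide incidence table", call. = FALSE)
    }
    storage.mode(mat) <- "integer"
    dimnames(mat) <- list(plot_ids, names(df)[-1])
  } else if (format == "long_csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("plot_id", "species_id") %in% names(df))) {
      stop("long incidence CSV needs columns plot_id, species_id",
           call. = FALSE)
    }
    plot_ids <- sort(unique(as.character(df$plot_id)))
    species_ids <- sort(unique(as.character(df$species_id)))
    mat <- matrix(0L, length(plot_ids), length(species_ids),
                  dimnames = list(plot_ids, species_ids))
    mat[cbind(match(df$plot_id, plot_ids),
              match(df$species_id, species_ids))] <- 1L
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!all(df[[3]] == 1)) {
      stop("sparse triplet values must all be 1", call. = FALSE)
    }
    plot_ids <- sort(readLines(paste0(path, ".plots")))
    species_ids <- sort(readLines(paste0(path, ".species")))
    mat <- matrix(0L, length(plot_ids), length(species_ids),
                  dimnames = list(plot_ids, species_ids))
    mat[cbind(df[[1]], df[[2]])] <- 1L
  }
  inc <- new_incidence(mat, taxon = taxon)
  if (!is.null(design)) check_incidence_against_design(inc, design)
  inc
}

#' Write a binary incidence table
#'
#' @param inc An `incidence_table`.
#' @param path Output path.
#' @param format See [read_incidence()]. `sparse_triplets` writes sidecar
#'   `<path>.plots` / `<path>.species` identifier lists.
#' @return Invisibly `path`.
#' @export
write_incidence <- function(inc, path, format = c("wide_csv", "long_csv",
                                                  "sparse_triplets")) {
  format <- match.arg(format)
  mat <- inc$matrix
  if (format == "wide_csv") {
    df <- data.frame(plot_id = rownames(mat), check.names = FALSE)
    df <- cbind(df, as.data.frame(mat, check.names = FALSE))
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else if (format == "long_csv") {
    idx <- which(mat == 1L, arr.ind = TRUE)
    df <- data.frame(plot_id = rownames(mat)[idx[, 1]],
                     species_id = colnames(mat)[idx[, 2]])
    df <- df[order(df$plot_id, df$species_id), , drop = FALSE]
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    # sidecars are written sorted so read(write(x)) preserves indices
    mat <- mat[order(rownames(mat)), order(colnames(mat)), drop = FALSE]
    idx <- which(mat == 1L, arr.ind = TRUE)
    df <- data.frame(row_index = idx[, 1], col_index = idx[, 2], value = 1L)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    writeLines(rownames(mat), paste0(path, ".plots"))
    writeLines(colnames(mat), paste0(path, ".species"))
  }
  invisible(path)
}
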