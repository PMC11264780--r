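#' @useDynLib ecoassembly, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cmdscale cor.test lm coef median na.omit p.adjust
#'   quantile rbinom rlnorm rmultinom rnorm runif sd setNames var wilcox.test
#' @importFrom utils read.delim write.table modifyList
NULL

# Internal validators shared by every module. All user-facing readers and
# generators funnel through these so that downstream code can assume the
# invariants (unique ids, non-negative integer counts, symmetric distances).

ea_stop <- function(..., class = "ecoassembly_error") {
  stop(errorCondition(paste0(...), class = c(class, "error", "condition")))
}

ea_warn <- function(...) warning(paste0(...), call. = FALSE)

check_ids <- function(ids, what) {
  ids <- trimws(ids)
  if (anyNA(ids) || any(ids == ""))
    ea_stop(what, " ids contain empty values", class = "ecoassembly_format_error")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    ea_stop("duplicate ", what, " id(s): ", paste(dup, collapse = ", "),
            class = "ecoassembly_format_error")
  ids
}

#' Validate a count table
#'
#' A count table is a base matrix of non-negative integer counts with taxa
#' as rows and samples as columns; row and column names are the unique,
#' non-empty taxon and sample ids. This is the orientation every function
#' in the package consumes.
#'
#' @param x matrix to validate.
#' @return `x`, invisibly, after passing all checks.
#' @export
validate_count_table <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    ea_stop("count table must be a numeric matrix")
  check_ids(rownames(x), "taxon")
  check_ids(colnames(x), "sample")
  if (anyNA(x) || any(x < 0))
    ea_stop("count table has missing or negative entries",
            class = "ecoassembly_format_error")
  if (any(x != round(x)))
    ea_stop("count table has non-integer entries",
            class = "ecoassembly_format_error")
  invisible(x)
}

#' Validate a distance matrix
#'
#' Checks symmetry (within `tol`), a zero diagonal, non-negative entries and
#' matching id dimnames.
#'
#' @param d square numeric matrix with dimnames.
#' @param tol symmetry tolerance.
#' @return `d`, invisibly.
#' @export
validate_distance_matrix <- function(d, tol = 1e-9) {
  if (!is.matrix(d) || nrow(d) != ncol(d))
    ea_stop("distance matrix must be square")
  if (is.null(rownames(d)) || !identical(rownames(d), colnames(d)))
    ea_stop("distance matrix must carry matching row/column ids")
  if (any(abs(d - t(d)) > tol)) ea_stop("distance matrix is not symmetric")
  if (any(abs(diag(d)) > tol)) ea_stop("distance matrix diagonal is not zero")
  if (any(d < -tol)) ea_stop("distance matrix has negative entries")
  invisible(d)
}

# Coerce a validated distance matrix to `dist` for vegan.
as_dist_obj <- function(d) stats::as.dist(d)

# Square symmetric matrix from a `dist`, preserving labels.
dist_to_matrix <- function(d) {
  m <- as.matrix(d)
  diag(m) <- 0
  m
}

niche_levels <- c("bulk_soil", "rhizosphere_soil", "root", "shoot")
health_levels <- c("healthy", "unhealthy")
chemistry_vars <- c("pH", "P2O5", "Mg", "K2O", "organic_carbon")

#' Validate a sample metadata table
#'
#' Required columns: `sample_id`, `farm_id`, `niche`, `health`, `latitude`,
#' `longitude`, and the soil chemistry variables `pH`, `P2O5`, `Mg`, `K2O`,
#' `organic_carbon`. `niche` must come from
#' `bulk_soil/rhizosphere_soil/root/shoot`, `health` from
#' `healthy/unhealthy`. Chemistry and coordinates may be missing (`NA`);
#' they are carried through and pairwise-dropped by downstream
#' correlation/regression functions.
#'
#' @param meta data.frame of per-sample metadata.
#' @return `meta`, invisibly.
#' @export
validate_metadata <- function(meta) {
  req <- c("sample_id", "farm_id", "niche", "health",
           "latitude", "longitude", chemistry_vars)
  missing_cols <- setdiff(req, names(meta))
  if (length(missing_cols))
    ea_stop("metadata is missing column(s): ", paste(missing_cols, collapse = ", "),
            class = "ecoassembly_format_error")
  check_ids(meta$sample_id, "sample")
  bad_niche <- setdiff(unique(meta$niche), niche_levels)
  if (length(bad_niche))
    ea_stop("unknown niche value(s): ", paste(bad_niche, collapse = ", "),
            class = "ecoassembly_vocabulary_error")
  bad_health <- setdiff(unique(meta$health), health_levels)
  if (length(bad_health))
    ea_stop("unknown health value(s): ", paste(bad_health, collapse = ", "),
            class = "ecoassembly_vocabulary_error")
  lat <- meta$latitude[!is.na(meta$latitude)]
  lon <- meta$longitude[!is.na(meta$longitude)]
  if (any(lat < -90 | lat > 90))
    ea_stop("latitude outside [-90, 90]", class = "ecoassembly_range_error")
  if (any(lon < -180 | lon > 180))
    ea_stop("longitude outside [-180, 180]", class = "ecoassembly_range_error")
  invisible(meta)
}

# Run `expr` with a fixed RNG seed without disturbing the caller's RNG
# stream; all stochastic functions in the package route through this.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}
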