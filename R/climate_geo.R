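#' Read a climate/geography table
#'
#' Expected columns: `group_id`, `LAT`, `LON` (decimal degrees), `TMN`, `TMX`
#' (degrees C: average minimum temperature of the coldest month, average
#' maximum of the hottest month), `HMN`, `HMX` (hPa vapour pressure of the
#' least / most humid month). Extra columns are carried along.
#'
#' @param path CSV file path.
#' @return validated data frame.
#' @export
read_climate_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_climate(df)
}

climate_vars <- function() c("TMN", "TMX", "HMN", "HMX")

validate_climate <- function(df) {
  needed <- c("group_id", "LAT", "LON", climate_vars())
  miss <- setdiff(needed, names(df))
  if (length(miss))
    stop("climate table lacks column(s): ", paste(miss, collapse = ", "))
  if (any(df$LAT < -90 | df$LAT > 90)) stop("LAT out of [-90, 90]")
  if (any(df$LON <= -180 | df$LON > 180)) stop("LON out of (-180, 180]")
  if (any(df$TMN > df$TMX)) stop("TMN exceeds TMX for some group")
  if (any(df$HMN > df$HMX)) stop("HMN exceeds HMX for some group")
  if (anyDuplicated(df$group_id)) stop("duplicate group_id")
  df
}

#' z-score the columns of a design table
#'
#' Each column is centered by its mean and divided by its sample standard
#' deviation (denominator `n - 1`). Means and sds are retained for reporting
#' and for mapping new observations into the standardized design.
#'
#' @param table numeric matrix or data frame (`g x p`, `g >= 2`).
#' @return list with `X` (standardized matrix), `means`, `sds`.
#' @export
zscore_columns <- function(table) {
  X <- as.matrix(table)
  if (nrow(X) < 2) stop("need at least two rows to standardize")
  mu <- colMeans(X)
  sd_ <- apply(X, 2, stats::sd)
  const <- sd_ == 0 | !is.finite(sd_)
  if (any(const))
    stop("constant column(s): ",
         paste(colnames(X)[const], collapse = ", "))
  Z <- sweep(sweep(X, 2, mu), 2, sd_, "/")
  list(X = Z, means = mu, sds = sd_)
}

#' Great-circle distance matrix between groups
#'
#' Haversine distances on a sphere of radius 6371.0088 km. This is the
#' default stand-in for route-aware geographic distances; a user-supplied
#' matrix (see [read_distance_csv()]) overrides it in the pipeline.
#'
#' @param records data frame with `group_id`, `LAT`, `LON`.
#' @return symmetric `g x g` matrix of distances in km, zero diagonal,
#'   dimnames = group ids.
#' @export
haversine_matrix <- function(records) {
  validate_climate_coords(records)
  xy <- cbind(records$LON, records$LAT)
  D <- geosphere::distm(xy, xy,
                        fun = function(a, b)
                          geosphere::distHaversine(a, b, r = 6371.0088))
  D <- (D + t(D)) / 2
  diag(D) <- 0
  dimnames(D) <- list(records$group_id, records$group_id)
  D
}

validate_climate_coords <- function(df) {
  if (!all(c("group_id", "LAT", "LON") %in% names(df)))
    stop("records need group_id, LAT, LON")
  if (any(df$LAT < -90 | df$LAT > 90) || any(df$LON <= -180 | df$LON > 180))
    stop("coordinates out of range")
  invisible(df)
}

#' Read / write a square distance matrix CSV
#'
#' Format: a square matrix with a `group_id` header row and first column.
#'
#' @param path CSV path.
#' @return symmetric numeric matrix (km) with group-id dimnames.
#' @export
read_distance_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  ids <- df[[1]]
  D <- as.matrix(df[, -1, drop = FALSE])
  rownames(D) <- ids
  if (!identical(rownames(D), colnames(D)))
    stop("distance CSV row and column ids disagree")
  if (any(D < 0) || any(abs(D - t(D)) > 1e-8) || any(abs(diag(D)) > 1e-8))
    stop("distance matrix must be symmetric, nonnegative, zero-diagonal")
  D <- (D + t(D)) / 2
  diag(D) <- 0
  D
}

#' @rdname read_distance_csv
#' @param D distance matrix.
#' @export
write_distance_csv <- function(D, path) {
  df <- data.frame(group_id = rownames(D), D, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Geographic similarity weights from pairwise distances
#'
#' Each distance is subtracted from the maximum pairwise distance and divided
#' by that maximum: `W_ij = (d_max - d_ij) / d_max`. Entries range from 0 to
#' 1, with 1 for pairs at the same location (diagonal included) and 0 exactly
#' at the maximal pair. The matrix enters the reduced rank regression as a
#' generalized-least-squares error structure discounting spatially
#' autocorrelated groups.
#'
#' @param D symmetric nonnegative distance matrix with zero diagonal.
#' @return symmetric weight matrix with unit diagonal, entries in `[0, 1]`.
#' @export
weights_from_distances <- function(D) {
  D <- as.matrix(D)
  if (any(abs(D - t(D)) > 1e-8) || any(D < 0))
    stop("distance matrix must be symmetric and nonnegative")
  dmax <- max(D)
  if (dmax <= 0) stop("all distances zero: weight scaling undefined")
  W <- (dmax - D) / dmax
  diag(W) <- 1
  W
}

#' Empirical variogram-style diagnostic of shape vs geographic distance
#'
#' Bins group pairs by geographic distance and reports the mean squared
#' Euclidean distance between the flattened shape rows within each bin,
#' together with a straight-line fit through the non-empty binned means —
#' a quick check of whether shape dissimilarity grows roughly linearly with
#' distance (the rationale for the linear distance-to-weight transformation).
#'
#' @param D `g x g` distance matrix (km).
#' @param Y `g x q` matrix of group shapes, same group order as `D`.
#' @param bins number of equal-width distance bins (>= 2).
#' @return list with `table` (bin midpoint km, mean squared shape distance,
#'   pair count; empty bins reported with count 0 and `NA` mean), `slope`,
#'   `r_squared` of the line through the non-empty bin means.
#' @export
variogram_diagnostic <- function(D, Y, bins = 8L) {
  D <- as.matrix(D); Y <- as.matrix(Y)
  if (nrow(D) != nrow(Y)) stop("D and Y must share group order")
  if (bins < 2) stop("need at least 2 bins")
  ut <- upper.tri(D)
  d <- D[ut]
  sq <- as.matrix(stats::dist(Y))^2
  s <- sq[ut]
  brk <- seq(0, max(d), length.out = bins + 1)
  idx <- pmin(pmax(findInterval(d, brk, rightmost.closed = TRUE), 1L), bins)
  mids <- (brk[-1] + brk[-length(brk)]) / 2
  tab <- data.frame(
    midpoint_km = mids,
    mean_sq_shape_dist = vapply(seq_len(bins), function(b)
      if (any(idx == b)) mean(s[idx == b]) else NA_real_, 0),
    n_pairs = vapply(seq_len(bins), function(b) sum(idx == b), 0L))
  ok <- !is.na(tab$mean_sq_shape_dist)
  slope <- r2 <- NA_real_
  if (sum(ok) >= 2) {
    fit <- stats::lm(mean_sq_shape_dist ~ midpoint_km, data = tab[ok, ])
    slope <- unname(stats::coef(fit)[2])
    r2 <- summary(fit)$r.squared
  }
  list(table = tab, slope = slope, r_squared = r2)
}
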