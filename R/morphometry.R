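#' Centroid size of a landmark configuration
#'
#' The square root of the summed squared Euclidean distances of the landmarks
#' from their centroid; the standard size measure in geometric morphometrics.
#' Scale-equivariant (`centroid_size(c * x) == |c| * centroid_size(x)`) and
#' invariant to rotation and translation.
#'
#' @param coords `L x 3` numeric matrix.
#' @return nonnegative scalar.
#' @export
centroid_size <- function(coords) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 1 || any(!is.finite(coords)))
    stop("invalid input: coordinates must be finite")
  cc <- sweep(coords, 2, colMeans(coords))
  sqrt(sum(cc^2))
}

center_coords <- function(coords) sweep(coords, 2, colMeans(coords))

#' Absolute and relative centroid size of anatomical regions
#'
#' Region centroid sizes are computed on each region's landmark subset in the
#' configuration's original (unscaled) units; relative size divides by the
#' centroid size of the full configuration.
#'
#' @param config a complete [specimen_config()] (no missing landmarks).
#' @param scheme a [landmark_scheme()].
#' @return data frame with columns `region`, `absolute_cs`, `relative_cs`,
#'   one row per region in the scheme (full configuration CS as attribute
#'   `full_cs`).
#' @export
region_sizes <- function(config, scheme) {
  if (any(config$missing))
    stop("config has missing landmarks; impute before computing sizes")
  full <- centroid_size(config$coords)
  regs <- unique(scheme$regions)
  res <- lapply(regs, function(r) {
    idx <- which(scheme$regions == r)
    if (length(idx) < 2)
      stop("degenerate region '", r, "': fewer than 2 landmarks")
    cs <- centroid_size(config$coords[idx, , drop = FALSE])
    data.frame(region = r, absolute_cs = cs, relative_cs = cs / full,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  attr(out, "full_cs") <- full
  out
}

# ---- thin-plate spline -----------------------------------------------------

# 3D TPS with kernel phi(r) = r and full affine part. Maps src -> dst,
# evaluated at query points.
tps_warp <- function(src, dst, query) {
  k <- nrow(src)
  K <- as.matrix(stats::dist(src))
  P <- cbind(1, src)
  Lmat <- rbind(cbind(K, P), cbind(t(P), matrix(0, 4, 4)))
  sol <- tryCatch(solve(Lmat, rbind(dst, matrix(0, 4, 3))),
                  error = function(e)
                    stop("degenerate geometry: thin-plate spline system is singular ",
                         "(coincident source landmarks?)"))
  Wc <- sol[seq_len(k), , drop = FALSE]
  Ac <- sol[k + 1:4, , drop = FALSE]
  d2 <- outer(rowSums(query^2), rep(1, k)) +
    outer(rep(1, nrow(query)), rowSums(src^2)) - 2 * query %*% t(src)
  Uq <- sqrt(pmax(d2, 0))
  Uq %*% Wc + cbind(1, query) %*% Ac
}

#' Impute missing landmarks by thin-plate-spline warping
#'
#' Fits a 3D thin-plate spline (kernel `phi(r) = r`, affine part included)
#' mapping a complete reference configuration onto the specimen's present
#' landmarks; missing landmarks are estimated as the warp images of the
#' corresponding reference landmarks. Specimens missing more than
#' `max_missing` landmarks are not imputed: an exclusion condition (class
#' `climorph_exclusion`) is signalled instead.
#'
#' @param config a [specimen_config()] with at least one missing landmark.
#' @param reference complete `L x 3` reference configuration (typically the
#'   sample consensus from [gpa_align()], rescaled to the specimen's units if
#'   desired; the TPS affine part absorbs scale).
#' @param scheme a [landmark_scheme()] (validates dimensions).
#' @param max_missing exclusion threshold (default 4).
#' @return the completed [specimen_config()], missing mask cleared; present
#'   coordinates are unchanged.
#' @export
impute_missing <- function(config, reference, scheme, max_missing = 4L) {
  if (n_landmarks(scheme) != nrow(config$coords) ||
      nrow(reference) != nrow(config$coords))
    stop("scheme, reference and config disagree on landmark count")
  nm <- n_missing(config)
  if (nm == 0) return(config)
  if (nm > max_missing)
    stop(errorCondition(
      sprintf("specimen %s missing %d landmarks (> %d): excluded",
              config$specimen_id, nm, max_missing),
      class = c("climorph_exclusion", "error", "condition")))
  present <- !config$missing
  est <- tps_warp(reference[present, , drop = FALSE],
                  config$coords[present, , drop = FALSE],
                  reference[config$missing, , drop = FALSE])
  out <- config
  out$coords[config$missing, ] <- est
  out$missing[] <- FALSE
  out
}

# ---- Procrustes superimposition -------------------------------------------

# Optimal proper rotation R (det +1) minimising ||A %*% R - B||_F.
optimal_rotation <- function(A, B) {
  s <- svd(crossprod(A, B))
  d <- diag(c(1, 1, sign(det(s$u %*% t(s$v)))))
  s$u %*% d %*% t(s$v)
}

#' Partial Procrustes distance between two configurations
#'
#' Both configurations are centered, scaled to unit centroid size, and one is
#' rotated (proper rotation) onto the other; the root summed squared
#' difference is returned. Used throughout the test suites as the
#' registration-free comparison metric.
#'
#' @param a,b `L x 3` matrices.
#' @return nonnegative scalar.
#' @export
procrustes_distance <- function(a, b) {
  a <- center_coords(a); a <- a / sqrt(sum(a^2))
  b <- center_coords(b); b <- b / sqrt(sum(b^2))
  sqrt(sum((a %*% optimal_rotation(a, b) - b)^2))
}

#' Generalized Procrustes alignment
#'
#' Iterative generalized Procrustes superimposition: each configuration is
#' translated to the origin, scaled to unit centroid size, and rotated (proper
#' rotation only) to the running consensus; the consensus is re-estimated
#' until its change falls below `tol` or `max_iter` iterations. The
#' pre-scaling centroid size of every specimen is retained for size analyses.
#'
#' @param configs list of complete [specimen_config()] objects (n >= 2).
#' @param tol consensus convergence tolerance (Frobenius norm of change).
#' @param max_iter iteration cap; non-convergence yields a warning but the
#'   result is still returned, flagged `converged = FALSE`.
#' @return An object of class `aligned_sample`: list with `shapes`
#'   (`L x 3 x n` array of aligned unit-size shapes), `consensus` (`L x 3`,
#'   unit centroid size), `centroid_sizes` (pre-scaling CS), `meta`
#'   (specimen_id/group_id/sex data frame), `iterations`, `converged`.
#' @export
gpa_align <- function(configs, tol = 1e-10, max_iter = 100L) {
  if (length(configs) < 2) stop("GPA needs at least two configurations")
  arr <- configs_to_array(configs)
  n <- dim(arr)[3]
  cs <- numeric(n)
  for (i in seq_len(n)) {
    x <- center_coords(arr[, , i])
    cs[i] <- sqrt(sum(x^2))
    if (cs[i] <= 0 || qr(x)$rank < 2)
      stop("degenerate configuration (rank < 2): specimen ",
           dimnames(arr)[[3]][i])
    arr[, , i] <- x / cs[i]
  }
  consensus <- arr[, , 1]
  iter <- 0L
  converged <- FALSE
  while (iter < max_iter) {
    iter <- iter + 1L
    for (i in seq_len(n))
      arr[, , i] <- arr[, , i] %*% optimal_rotation(arr[, , i], consensus)
    new_cons <- apply(arr, c(1, 2), mean)
    new_cons <- new_cons / sqrt(sum(center_coords(new_cons)^2))
    delta <- sqrt(sum((new_cons - consensus)^2))
    consensus <- new_cons
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("GPA did not converge in ", max_iter, " iterations")
  structure(list(shapes = arr, consensus = consensus, centroid_sizes = cs,
                 meta = config_meta(configs), iterations = iter,
                 converged = converged),
            class = "aligned_sample")
}

#' @export
print.aligned_sample <- function(x, ...) {
  cat("GPA-aligned sample:", dim(x$shapes)[3], "specimens,",
      dim(x$shapes)[1], "landmarks;", x$iterations, "iterations",
      if (x$converged) "(converged)\n" else "(NOT converged)\n")
  invisible(x)
}

#' Flattened shape matrix of an aligned sample
#' @param aligned an `aligned_sample` from [gpa_align()].
#' @return `n x 3L` matrix, rows in specimen order, landmark-major columns.
#' @export
aligned_shape_matrix <- function(aligned) {
  t(apply(aligned$shapes, 3, flatten_coords))
}

#' Align a single specimen to an existing consensus
#'
#' Ordinary Procrustes superimposition of one complete configuration onto a
#' fixed consensus: translate, scale to unit centroid size, rotate (proper
#' rotation). Used to place out-of-sample specimens (e.g. fossils) into the
#' shape space of an already-aligned sample.
#'
#' @param config complete [specimen_config()] (or bare `L x 3` matrix).
#' @param consensus `L x 3` consensus from [gpa_align()].
#' @return numeric vector of length `3L` (flattened aligned shape).
#' @export
align_new_specimen <- function(config, consensus) {
  coords <- if (inherits(config, "specimen_config")) config$coords else as.matrix(config)
  x <- center_coords(coords)
  s <- sqrt(sum(x^2))
  if (s <= 0 || qr(x)$rank < 2) stop("degenerate configuration")
  x <- x / s
  flatten_coords(x %*% optimal_rotation(x, consensus))
}

# ---- object symmetry -------------------------------------------------------

#' Express a flattened shape vector in another configuration's frame
#'
#' Aligned shape coordinates are defined only up to the common rotation of
#' their consensus. To compare a shape direction (a loading vector, an
#' effect vector) across superimpositions, rotate it by the optimal rotation
#' taking `from` onto `to`.
#'
#' @param v flattened shape vector (length `3L`) expressed in the frame of
#'   `from`.
#' @param from,to `L x 3` reference configurations (e.g. a generating
#'   template and a sample consensus).
#' @return flattened vector expressed in the frame of `to`.
#' @export
rotate_shape_vector <- function(v, from, to) {
  flatten_coords(unflatten_coords(v) %*% optimal_rotation(from, to))
}

#' Mirror a configuration and relabel bilateral landmarks
#'
#' Negates the first coordinate axis (the internal mirror plane; the pairing
#' in the scheme, not geometry, defines correspondence) and swaps the
#' coordinates within each (left, right) landmark pair. Midline landmarks
#' keep their mirrored positions. The operation is an involution.
#'
#' @param config a complete [specimen_config()] (or bare `L x 3` matrix).
#' @param scheme a [landmark_scheme()].
#' @return object of the same type as `config`.
#' @export
reflect_relabel <- function(config, scheme) {
  is_cfg <- inherits(config, "specimen_config")
  coords <- if (is_cfg) config$coords else as.matrix(config)
  if (nrow(coords) != n_landmarks(scheme))
    stop("config and scheme disagree on landmark count")
  out <- coords
  out[, 1] <- -out[, 1]
  out <- out[pair_permutation(scheme), , drop = FALSE]
  if (is_cfg) { config$coords <- out; config } else out
}

#' Symmetrize configurations by averaging original and reflected copies
#'
#' The standard object-symmetry procedure: every configuration and its
#' reflected-relabeled copy enter one joint generalized Procrustes alignment;
#' each specimen's symmetric shape is the landmark-wise average of its two
#' aligned copies. Outputs are invariant under [reflect_relabel()] up to
#' rotation, and the operation is idempotent (up to alignment tolerance).
#'
#' @param configs list of complete [specimen_config()] objects.
#' @param scheme a [landmark_scheme()].
#' @param tol,max_iter passed to [gpa_align()].
#' @return list of [specimen_config()] objects with symmetrized coordinates
#'   (unit-size shape scale), attribute `consensus` holding the joint
#'   consensus.
#' @export
symmetrize <- function(configs, scheme, tol = 1e-10, max_iter = 100L) {
  n <- length(configs)
  reflected <- lapply(configs, reflect_relabel, scheme = scheme)
  joint <- gpa_align(c(configs, reflected), tol = tol, max_iter = max_iter)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    avg <- (joint$shapes[, , i] + joint$shapes[, , n + i]) / 2
    cf <- configs[[i]]
    cf$coords <- avg
    cf$missing[] <- FALSE
    out[[i]] <- cf
  }
  attr(out, "consensus") <- joint$consensus
  out
}

# ---- nuisance correction and group means ----------------------------------

#' Remove a categorical nuisance effect (e.g. sex dimorphism)
#'
#' Subtracts from each row its label-class mean and adds back the grand mean,
#' so that after correction every class mean equals the grand mean. Applied
#' to shape coordinates (`k = 3L`) and to centroid size (`k = 1`) alike.
#' Rows whose label equals `passthrough` (default `"unknown"`) are returned
#' unchanged, with a warning — out-of-sample specimens of unknown sex are not
#' corrected.
#'
#' @param values `n x k` numeric matrix (a vector is treated as `n x 1`).
#' @param labels character vector of class labels, length `n`.
#' @param passthrough label treated as "no class": rows pass through
#'   unchanged. Set to `NULL` to disable.
#' @return matrix of the same shape as `values`.
#' @export
remove_group_nuisance <- function(values, labels, passthrough = "unknown") {
  values <- as.matrix(values)
  labels <- as.character(labels)
  if (length(labels) != nrow(values))
    stop("labels length must match rows of values")
  skip <- if (is.null(passthrough)) rep(FALSE, length(labels)) else labels == passthrough
  if (any(skip))
    warning(sum(skip), " row(s) with label '", passthrough,
            "' passed through uncorrected")
  known <- !skip
  if (!any(known)) return(values)
  grand <- colMeans(values[known, , drop = FALSE])
  out <- values
  for (cl in unique(labels[known])) {
    idx <- known & labels == cl
    cm <- colMeans(values[idx, , drop = FALSE])
    out[idx, ] <- sweep(values[idx, , drop = FALSE], 2, cm - grand)
  }
  out
}

#' Group mean shapes
#'
#' @param shapes `n x q` matrix of flattened shape coordinates (or any row
#'   observations).
#' @param groups character vector of group labels, length `n`.
#' @return `g x q` matrix, one row per group; rows ordered by first
#'   appearance of each group, recorded in `rownames`.
#' @export
group_means <- function(shapes, groups) {
  shapes <- as.matrix(shapes)
  groups <- as.character(groups)
  if (length(groups) == 0 || length(groups) != nrow(shapes))
    stop("groups must be a non-empty vector matching rows of shapes")
  lev <- unique(groups)
  out <- t(vapply(lev,
                  function(g) colMeans(shapes[groups == g, , drop = FALSE]),
                  numeric(ncol(shapes))))
  rownames(out) <- lev
  out
}
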