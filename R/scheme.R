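#' Landmark scheme: names, regions, bilateral pairing
#'
#' A landmark scheme records the identity of every landmark in a
#' configuration: its name, the anatomical region it belongs to, and the
#' bilateral structure (left/right pairs plus unpaired midline landmarks)
#' needed for object-symmetry analysis.
#'
#' @param labels character vector of landmark names, in configuration order.
#' @param regions named character vector or list mapping every label to one of
#'   the five anatomical regions: `external_face`, `external_nose`,
#'   `internal_nose`, `choanae`, `maxillary_sinus`.
#' @param pairs two-column character matrix (or list of length-2 vectors) of
#'   (left, right) label pairs.
#' @param midline character vector of unpaired (midline) labels.
#'
#' @return An object of class `landmark_scheme`: a list with elements
#'   `labels`, `regions` (named character vector), `pairs` (two-column
#'   character matrix) and `midline`.
#' @export
landmark_scheme <- function(labels, regions, pairs, midline) {
  labels <- as.character(labels)
  if (anyDuplicated(labels)) stop("duplicate landmark labels")
  regions <- unlist(regions)
  if (!setequal(names(regions), labels))
    stop("`regions` must name every label exactly once")
  regions <- regions[labels]
  bad <- setdiff(unique(regions), climorph_regions())
  if (length(bad))
    stop("unknown region(s): ", paste(bad, collapse = ", "))
  if (is.list(pairs)) pairs <- do.call(rbind, pairs)
  pairs <- matrix(as.character(pairs), ncol = 2,
                  dimnames = list(NULL, c("left", "right")))
  midline <- as.character(midline)
  paired <- c(pairs)
  if (any(pairs[, 1] == pairs[, 2]))
    stop("a landmark cannot be paired with itself")
  if (anyDuplicated(paired))
    stop("a landmark occurs in more than one pair")
  if (!setequal(c(paired, midline), labels) ||
      length(paired) + length(midline) != length(labels))
    stop("pairs and midline must partition the labels")
  structure(list(labels = labels, regions = regions,
                 pairs = pairs, midline = midline),
            class = "landmark_scheme")
}

climorph_regions <- function() {
  c("external_face", "external_nose", "internal_nose",
    "choanae", "maxillary_sinus")
}

#' @export
print.landmark_scheme <- function(x, ...) {
  cat("Landmark scheme:", length(x$labels), "landmarks (",
      nrow(x$pairs), "bilateral pairs,", length(x$midline),
      "midline );", length(unique(x$regions)), "regions\n")
  print(table(x$regions))
  invisible(x)
}

#' Number of landmarks in a scheme
#' @param scheme a [landmark_scheme()].
#' @return integer landmark count.
#' @export
n_landmarks <- function(scheme) length(scheme$labels)

#' Names of the flattened shape coordinates
#'
#' Shape matrices flatten an `L x 3` configuration landmark-major, i.e.
#' `x1, y1, z1, x2, y2, z2, ...`, giving `3L` shape coordinates.
#'
#' @param scheme a [landmark_scheme()].
#' @return character vector of length `3 * n_landmarks(scheme)`.
#' @export
coordinate_labels <- function(scheme) {
  as.vector(t(outer(scheme$labels, c("x", "y", "z"), paste, sep = "_")))
}

# Permutation that swaps each (left,right) pair; midline maps to itself.
pair_permutation <- function(scheme) {
  perm <- seq_along(scheme$labels)
  il <- match(scheme$pairs[, 1], scheme$labels)
  ir <- match(scheme$pairs[, 2], scheme$labels)
  perm[il] <- ir
  perm[ir] <- il
  perm
}

#' Read / write a landmark scheme file
#'
#' Scheme files are YAML with fields `labels`, `regions` (label: region map),
#' `pairs` (list of two-element lists) and `midline`.
#'
#' @param path file path.
#' @return `read_scheme()` returns a [landmark_scheme()].
#' @export
read_scheme <- function(path) {
  y <- yaml::read_yaml(path)
  landmark_scheme(y$labels, y$regions, y$pairs, y$midline)
}

#' @rdname read_scheme
#' @param scheme a [landmark_scheme()].
#' @export
write_scheme <- function(scheme, path) {
  y <- list(labels = scheme$labels,
            regions = as.list(scheme$regions),
            pairs = apply(scheme$pairs, 1, as.list),
            midline = scheme$midline)
  yaml::write_yaml(y, path)
  invisible(path)
}
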