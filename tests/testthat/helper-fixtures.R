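# shared fixtures: tiny schemes, rigid motions, small random configurations

# 4-landmark toy scheme: one bilateral pair on the x axis, two midline points
tiny_scheme <- function() {
  landmark_scheme(
    labels = c("top", "pL", "pR", "front"),
    regions = c(top = "external_face", pL = "external_nose",
                pR = "external_nose", front = "external_face"),
    pairs = rbind(c("pL", "pR")),
    midline = c("top", "front"))
}

tiny_config <- function() {
  # symmetric: midline on the x = 0 plane, pair mirror-imaged
  rbind(top = c(0, 0, 1), pL = c(1, 0, 0), pR = c(-1, 0, 0),
        front = c(0, 1, 0))
}

# 8-landmark scheme split into two 4-landmark regions (all midline)
two_region_scheme <- function() {
  labels <- sprintf("p%d", 1:8)
  landmark_scheme(
    labels,
    regions = stats::setNames(rep(c("external_nose", "maxillary_sinus"),
                                  each = 4), labels),
    pairs = matrix(character(), 0, 2),
    midline = labels)
}

random_rotation <- function() {
  R <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# random rigid motion + positive scaling applied to an L x 3 matrix
random_similarity <- function(coords, scale = stats::runif(1, 0.5, 2)) {
  sweep(coords %*% random_rotation() * scale, 2, stats::rnorm(3, sd = 10), "+")
}

random_config <- function(L = 10, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  matrix(stats::rnorm(L * 3), L, 3)
}

# independent haversine evaluation (direct formula, not the package path)
haversine_oracle <- function(lat1, lon1, lat2, lon2, R = 6371.0088) {
  to_rad <- pi / 180
  phi1 <- lat1 * to_rad; phi2 <- lat2 * to_rad
  dphi <- (lat2 - lat1) * to_rad; dlam <- (lon2 - lon1) * to_rad
  a <- sin(dphi / 2)^2 + cos(phi1) * cos(phi2) * sin(dlam / 2)^2
  2 * R * asin(sqrt(pmin(1, a)))
}

# small ready-made truth shared across tests (cheap to build repeatedly)
test_truth <- function(...) synthetic_truth(seed = 11L, ...)

climate_fixture_path <- function() {
  system.file("extdata", "group_climate.csv", package = "climorph")
}
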