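#' Ground-truth parameter set for synthetic landmark data
#'
#' Bundles every generator parameter with the derived ground-truth objects
#' (symmetric template, true coefficient matrix and its singular structure)
#' so that recovery tests can compare estimates against known truth. The
#' defaults mirror the design of the study the package emulates: 16 groups,
#' 4 climate variables, 61 landmarks (24 bilateral pairs + 13 midline) in 5
#' anatomical regions, group sizes 8-32, and a first-dimension-dominant
#' coefficient spectrum with squared-singular-value shares 73/21/4/2 percent.
#' Shape effects live in the template's tangent space at about 2 percent of
#' centroid size; see the methods vignette for the reasoning behind each
#' default.
#'
#' @param n_pairs,n_midline bilateral pairs and midline landmarks
#'   (`2 * n_pairs + n_midline` landmarks total).
#' @param g number of groups.
#' @param p number of climate variables (fixed design: TMN, TMX, HMN, HMX).
#' @param shares squared-singular-value shares of the true coefficient
#'   matrix, length `p`, summing to 1.
#' @param effect_scale Frobenius norm of `B_true` in units of centroid size
#'   (typical per-group shape displacement for a 1-sd climate contrast).
#' @param noise_sd_individual per-coordinate sd of i.i.d. landmark noise
#'   (units of centroid size).
#' @param noise_sd_group per-coordinate sd of the spatially correlated
#'   group-level shape residual.
#' @param sex_effect_norm norm of the additive sex-dimorphism shape vector.
#' @param spatial_decay km scale of the exponential spatial autocorrelation
#'   of climate and of group shape residuals.
#' @param cs_base baseline centroid size in mm.
#' @param cs_beta length-`p` relative effect of the standardized climate
#'   variables on group centroid size.
#' @param cs_sex_ratio male/female centroid-size ratio.
#' @param cs_cv individual coefficient of variation of centroid size.
#' @param seed integer seed; every derived object is a pure function of the
#'   parameters and this seed.
#' @return object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(n_pairs = 24L, n_midline = 13L, g = 16L, p = 4L,
                            shares = c(0.73, 0.21, 0.04, 0.02),
                            effect_scale = 0.02,
                            noise_sd_individual = 0.001,
                            noise_sd_group = 0.00025,
                            sex_effect_norm = 0.01,
                            spatial_decay = 3000,
                            cs_base = 480, cs_beta = c(-0.025, -0.005, 0, -0.01),
                            cs_sex_ratio = 1.05, cs_cv = 0.03,
                            seed = 1L) {
  stopifnot(length(shares) == p, abs(sum(shares) - 1) < 1e-8,
            g >= p + 2, length(cs_beta) == p)
  st <- make_scheme_template(n_pairs, n_midline, seed = seed)
  scheme <- st$scheme; template <- st$template
  q <- 3L * n_landmarks(scheme)
  load <- withr_seed(seed + 1L, make_true_loadings(scheme, template, p))
  d_true <- effect_scale * sqrt(shares)
  B_true <- load$U0 %*% diag(d_true) %*% t(load$V0)
  sex_effect <- withr_seed(seed + 2L, {
    v <- stats::rnorm(q)
    v <- project_out(v, load$nuisance)
    sex_effect_norm * v / sqrt(sum(v^2))
  })
  structure(list(scheme = scheme, template = template,
                 g = g, p = p, q = q,
                 shares = shares, d_true = d_true,
                 B_true = B_true, u_true = load$U0, v_true = load$V0,
                 sex_effect = sex_effect,
                 effect_scale = effect_scale,
                 noise_sd_individual = noise_sd_individual,
                 noise_sd_group = noise_sd_group,
                 sex_effect_norm = sex_effect_norm,
                 spatial_decay = spatial_decay,
                 cs_base = cs_base, cs_beta = cs_beta,
                 cs_sex_ratio = cs_sex_ratio, cs_cv = cs_cv,
                 seed = seed),
            class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("Synthetic ground truth:", x$g, "groups,", n_landmarks(x$scheme),
      "landmarks,", x$p, "climate variables; shares",
      paste(sprintf("%.0f%%", 100 * x$shares), collapse = "/"),
      "; seed", x$seed, "\n")
  invisible(x)
}

# evaluate expr under a local RNG seed, restoring the caller's RNG state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

#' Seeded symmetric landmark scheme and template
#'
#' Builds a landmark scheme (`2 * n_pairs + n_midline` landmarks, five
#' anatomical regions assigned contiguously) and a random-but-seeded
#' template configuration that is exactly symmetric under
#' [reflect_relabel()] (midline landmarks on the internal mirror plane,
#' paired landmarks exact mirror images), centered and scaled to unit
#' centroid size.
#'
#' @inheritParams synthetic_truth
#' @param seed integer seed.
#' @return list with `scheme` and `template` (`L x 3`).
#' @export
make_scheme_template <- function(n_pairs = 24L, n_midline = 13L, seed = 1L) {
  L <- 2L * n_pairs + n_midline
  if (L < 4) stop("need at least 4 landmarks")
  labels <- c(t(outer(sprintf("lm%02d", seq_len(n_pairs)),
                      c("_L", "_R"), paste0)),
              sprintf("mid%02d", seq_len(max(n_midline, 0))))
  regs <- climorph_regions()
  regions <- stats::setNames(regs[pmin(ceiling(seq_len(L) / (L / 5)), 5)], labels)
  pairs <- cbind(sprintf("lm%02d_L", seq_len(n_pairs)),
                 sprintf("lm%02d_R", seq_len(n_pairs)))
  midline <- labels[grepl("^mid", labels)]
  scheme <- landmark_scheme(labels, regions, pairs, midline)
  template <- withr_seed(seed, {
    tpl <- matrix(0, L, 3)
    rownames(tpl) <- labels
    for (i in seq_len(n_pairs)) {
      pt <- c(abs(stats::rnorm(1)) + 0.2, stats::rnorm(2))
      tpl[pairs[i, 1], ] <- pt
      tpl[pairs[i, 2], ] <- c(-pt[1], pt[2:3])
    }
    for (m in midline) tpl[m, ] <- c(0, stats::rnorm(2))
    tpl
  })
  template <- center_coords(template)
  template <- template / centroid_size(template)
  list(scheme = scheme, template = template)
}

# orthonormal basis of the similarity-group tangent directions at a
# configuration: 3 translations, 3 infinitesimal rotations, 1 scaling
similarity_tangent_basis <- function(template) {
  L <- nrow(template)
  tr <- lapply(1:3, function(a) {
    m <- matrix(0, L, 3); m[, a] <- 1; flatten_coords(m)
  })
  skew <- list(rbind(c(0, -1, 0), c(1, 0, 0), c(0, 0, 0)),
               rbind(c(0, 0, -1), c(0, 0, 0), c(1, 0, 0)),
               rbind(c(0, 0, 0), c(0, 0, -1), c(0, 1, 0)))
  rot <- lapply(skew, function(A) flatten_coords(template %*% t(A)))
  sc <- list(flatten_coords(template))
  M <- do.call(cbind, c(tr, rot, sc))
  qr.Q(qr(M))[, seq_len(qr(M)$rank), drop = FALSE]
}

project_out <- function(v, basis) drop(v - basis %*% crossprod(basis, v))

# reflect-relabel as a linear map on flattened coordinates
reflect_flat <- function(v, scheme) {
  flatten_coords(reflect_relabel(unflatten_coords(v), scheme))
}

# true loading structure: V0 columns are orthonormal, symmetric under
# reflect-relabel, and orthogonal to the similarity tangent space, so the
# generated effects survive Procrustes alignment and symmetrization intact
make_true_loadings <- function(scheme, template, p) {
  q <- 3L * n_landmarks(scheme)
  nuis <- similarity_tangent_basis(template)
  raw <- matrix(stats::rnorm(q * p), q, p)
  for (j in seq_len(p)) {
    v <- raw[, j]
    v <- (v + reflect_flat(v, scheme)) / 2
    v <- project_out(v, nuis)
    raw[, j] <- v
  }
  V0 <- qr.Q(qr(raw))[, seq_len(p), drop = FALSE]
  U0 <- qr.Q(qr(matrix(stats::rnorm(p * p), p, p)))
  list(U0 = U0, V0 = V0, nuisance = nuis)
}

# lower-triangular factor of the exponential spatial correlation exp(-D/decay)
spatial_chol <- function(D, decay, ridge = 1e-8) {
  g <- nrow(D)
  S <- if (decay > 0) exp(-D / decay) else diag(g)
  t(chol(S + diag(ridge, g)))
}

#' Simulate group locations and spatially autocorrelated climate
#'
#' Group locations are scattered over a hemisphere-scale domain; the four
#' climate variables are Gaussian-process draws with exponential correlation
#' `exp(-d / spatial_decay)` over great-circle distance, so nearby groups
#' have similar climates — the confound the geographic weighting addresses.
#' `spatial_decay = 0` gives i.i.d. climate across groups.
#'
#' @param truth a [synthetic_truth()].
#' @param seed integer seed.
#' @param g number of groups (defaults to `truth$g`).
#' @return list with `climate` (data frame: group_id, LAT, LON, TMN, TMX,
#'   HMN, HMX) and `D` (great-circle distance matrix, km).
#' @export
simulate_groups <- function(truth, seed = truth$seed, g = truth$g) {
  withr_seed(seed + 10L, {
    loc <- data.frame(group_id = sprintf("G%02d", seq_len(g)),
                      LAT = stats::runif(g, -35, 70),
                      LON = stats::runif(g, -160, 160))
    D <- haversine_matrix(loc)
    Lc <- spatial_chol(D, truth$spatial_decay)
    f <- Lc %*% matrix(stats::rnorm(g * 4), g, 4)
    TMN <- -8 + 14 * f[, 1]
    TMX <- TMN + pmax(18 + 5 * f[, 2], 1)
    HMN <- pmax(6 + 4 * f[, 3], 0.2)
    HMX <- HMN + pmax(7 + 3 * f[, 4], 0.5)
    climate <- cbind(loc, TMN = TMN, TMX = TMX, HMN = HMN, HMX = HMX)
    list(climate = validate_climate(climate), D = D)
  })
}

#' Simulate group mean shapes from the true coefficient structure
#'
#' Group-level generative model used both by [simulate_specimens()] and by
#' lightweight recovery studies: flattened group shape rows are
#' `template + X B_true + G`, with `X` the standardized climate design and
#' `G` a spatially correlated residual (per-coordinate sd `sigma_g`,
#' exponential correlation over distance with scale `decay`).
#'
#' @param truth a [synthetic_truth()].
#' @param climate,D from [simulate_groups()].
#' @param seed integer seed.
#' @param sigma_g group residual sd (default `truth$noise_sd_group`).
#' @param decay residual correlation scale in km (default
#'   `truth$spatial_decay`).
#' @return list with `Y` (`g x q` flattened group shapes), `X`
#'   (standardized design), `G` (the residual draw), `zs` (standardization
#'   from [zscore_columns()]).
#' @export
simulate_group_shapes <- function(truth, climate, D, seed = truth$seed,
                                  sigma_g = truth$noise_sd_group,
                                  decay = truth$spatial_decay) {
  zs <- zscore_columns(climate[, climate_vars()])
  g <- nrow(climate)
  G <- withr_seed(seed + 20L, {
    Lc <- spatial_chol(D, decay)
    sigma_g * (Lc %*% matrix(stats::rnorm(g * truth$q), g, truth$q))
  })
  Y <- matrix(rep(flatten_coords(truth$template), each = g), g) +
    zs$X %*% truth$B_true + G
  rownames(Y) <- climate$group_id
  colnames(Y) <- coordinate_labels(truth$scheme)
  list(Y = Y, X = zs$X, G = G, zs = zs)
}

#' Simulate individual specimens with nuisance transformations
#'
#' Each specimen is its group's true mean shape plus an additive sex effect
#' (half of each group per sex) and i.i.d. landmark noise, then carried out
#' of shape space by a random proper rotation, translation, and positive
#' scale. The target centroid size combines a baseline, a climate effect, a
#' sex ratio and individual variation, so the size analyses have signal to
#' find. Fossils (out-of-sample specimens, assumed male) are generated from
#' their own climate rows and never share the modern groups' labels.
#'
#' @param truth a [synthetic_truth()].
#' @param seed integer seed.
#' @param group_sizes integer vector of specimens per group (default drawn
#'   uniformly from 8..32).
#' @param n_fossils number of held-out fossil specimens.
#' @return list with `configs` (modern specimens), `fossil_configs`,
#'   `climate` (modern groups + one row per fossil), `D` (modern-group
#'   distances), `true_group_shapes` (`g x q`), `true_shapes` (`n x q`
#'   pre-nuisance flattened specimen shapes), `X`, `zs`, `truth`.
#' @export
simulate_specimens <- function(truth, seed = truth$seed,
                               group_sizes = NULL, n_fossils = 2L) {
  gg <- simulate_groups(truth, seed = seed)
  gs <- simulate_group_shapes(truth, gg$climate, gg$D, seed = seed)
  g <- truth$g
  if (is.null(group_sizes))
    group_sizes <- withr_seed(seed + 30L,
                              sample(8:32, g, replace = TRUE))
  stopifnot(length(group_sizes) == g, all(group_sizes >= 1))

  withr_seed(seed + 40L, {
    configs <- list(); true_rows <- list()
    for (i in seq_len(g)) {
      n_i <- group_sizes[i]
      sexes <- rep(c("M", "F"), length.out = n_i)
      for (j in seq_len(n_i)) {
        shp <- gs$Y[i, ] +
          (if (sexes[j] == "M") 0.5 else -0.5) * truth$sex_effect +
          stats::rnorm(truth$q, sd = truth$noise_sd_individual)
        cs_target <- truth$cs_base *
          (1 + sum(truth$cs_beta * gs$X[i, ])) *
          (if (sexes[j] == "M") truth$cs_sex_ratio else 1) *
          (1 + stats::rnorm(1, sd = truth$cs_cv))
        id <- sprintf("%s_s%02d", gg$climate$group_id[i], j)
        configs[[length(configs) + 1L]] <- specimen_config(
          id, gg$climate$group_id[i],
          apply_nuisance(unflatten_coords(shp), cs_target), sex = sexes[j])
        true_rows[[length(true_rows) + 1L]] <- shp
      }
    }
    # fossils: new locations/climates, single specimens, assumed male
    fossil_configs <- list()
    fossil_climate <- NULL
    if (n_fossils > 0) {
      floc <- data.frame(group_id = sprintf("fossil%d", seq_len(n_fossils)),
                         LAT = stats::runif(n_fossils, 35, 60),
                         LON = stats::runif(n_fossils, 10, 60))
      fTMN <- stats::runif(n_fossils, -15, 0)
      fclim <- cbind(floc, TMN = fTMN,
                     TMX = fTMN + stats::runif(n_fossils, 20, 35),
                     HMN = stats::runif(n_fossils, 1, 6),
                     HMX = stats::runif(n_fossils, 10, 16))
      xf <- sweep(sweep(as.matrix(fclim[, climate_vars()]), 2, gs$zs$means),
                  2, gs$zs$sds, "/")
      for (k in seq_len(n_fossils)) {
        shp <- flatten_coords(truth$template) + xf[k, ] %*% truth$B_true +
          0.5 * truth$sex_effect +
          stats::rnorm(truth$q, sd = truth$noise_sd_individual)
        cs_target <- truth$cs_base * truth$cs_sex_ratio *
          (1 + sum(truth$cs_beta * xf[k, ]))
        fossil_configs[[k]] <- specimen_config(
          fclim$group_id[k], fclim$group_id[k],
          apply_nuisance(unflatten_coords(as.numeric(shp)), cs_target),
          sex = "M")
      }
      fossil_climate <- fclim
    }
    list(configs = configs, fossil_configs = fossil_configs,
         climate = rbind(gg$climate, fossil_climate), D = gg$D,
         true_group_shapes = gs$Y,
         true_shapes = do.call(rbind, true_rows),
         X = gs$X, zs = gs$zs, group_sizes = group_sizes, truth = truth)
  })
}

# random proper rotation + translation + scale to a target centroid size
apply_nuisance <- function(coords, cs_target) {
  R <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  sc <- cs_target / centroid_size(coords)
  sweep(coords %*% R * sc, 2, stats::runif(3, -100, 100), "+")
}

#' Delete landmarks at random to exercise imputation and exclusion
#'
#' Each landmark of each specimen goes missing with probability `rate`,
#' capped at `max_missing` per specimen; optionally the first
#' `n_force_exclude` specimens are pushed to `max_missing + 1` missing
#' landmarks so the downstream exclusion path is exercised.
#'
#' @param configs list of [specimen_config()] objects.
#' @param rate per-landmark missingness probability in `[0, 1)`.
#' @param max_missing per-specimen cap.
#' @param seed integer seed.
#' @param n_force_exclude specimens deliberately pushed over the cap.
#' @return list of configs with missing masks set (coordinates at missing
#'   landmarks replaced by `NA`).
#' @export
knockout_landmarks <- function(configs, rate, max_missing = 4L, seed = 1L,
                               n_force_exclude = 0L) {
  stopifnot(rate >= 0, rate < 1)
  withr_seed(seed + 50L, {
    lapply(seq_along(configs), function(i) {
      cf <- configs[[i]]
      L <- nrow(cf$coords)
      miss <- which(stats::runif(L) < rate)
      if (length(miss) > max_missing) miss <- sample(miss, max_missing)
      if (i <= n_force_exclude)
        miss <- sample(L, max_missing + 1L)
      if (length(miss)) {
        cf$coords[miss, ] <- NA_real_
        cf$missing[miss] <- TRUE
      }
      cf
    })
  })
}
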