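ols_oracle <- function(X, Y) {
  # independent normal-equations solve, column by column
  Xc <- X
  Yc <- sweep(Y, 2, colMeans(Y))
  sapply(seq_len(ncol(Yc)), function(j)
    solve(t(Xc) %*% Xc, t(Xc) %*% Yc[, j, drop = FALSE]))
}

test_that("identity-weight fits reduce exactly to multivariate OLS", {
  # identity regression: Y = X, full rank -> B = I, singular values all 1
  set.seed(1)
  X <- scale(matrix(stats::rnorm(40), 10, 4))[, ]
  m <- fit_weighted_rrr(X, X)
  expect_equal(unname(m$B), diag(4), tolerance = 1e-10)
  expect_equal(m$d, rep(1, 4), tolerance = 1e-10)

  # integer fixture g=5, p=2, q=3 against the oracle
  Xi <- scale(matrix(c(1, 2, 3, 4, 5, 2, 1, 4, 3, 5), 5, 2))[, ]
  Yi <- matrix(c(1, 4, 2, 8, 5, 3, 7, 6, 9, 2, 4, 6, 1, 3, 5), 5, 3)
  mi <- fit_weighted_rrr(Xi, Yi)
  expect_equal(unname(mi$B), unname(ols_oracle(Xi, Yi)), tolerance = 1e-10)

  # random small fixtures across seeds
  for (s in 1:20) {
    set.seed(s)
    g <- sample(6:12, 1); p <- sample(2:4, 1); q <- sample(2:6, 1)
    X <- scale(matrix(stats::rnorm(g * p), g, p))[, ]
    Y <- matrix(stats::rnorm(g * q), g, q)
    m <- fit_weighted_rrr(X, Y)
    expect_equal(unname(m$B), unname(ols_oracle(X, Y)), tolerance = 1e-10)
  }
})

test_that("the singular decomposition honours its contract", {
  for (s in 1:5) {
    set.seed(100 + s)
    g <- 12; p <- 4; q <- 7
    X <- scale(matrix(stats::rnorm(g * p), g, p))[, ]
    W <- weights_from_distances(as.matrix(stats::dist(cbind(stats::runif(g), 0))))
    m <- fit_weighted_rrr(X, matrix(stats::rnorm(g * q), g, q), W)
    r <- m$r
    expect_equal(unname(crossprod(m$U)), diag(r), tolerance = 1e-10)
    expect_equal(unname(crossprod(m$V)), diag(r), tolerance = 1e-10)
    expect_equal(unname(m$U %*% diag(m$d) %*% t(m$V)), unname(m$B),
                 tolerance = 1e-10)
    for (k in seq_len(r))
      expect_equal(unname(t(m$U[, k]) %*% m$B %*% m$V[, k])[1, 1], m$d[k],
                   tolerance = 1e-10)
    expect_equal(m$d, sort(m$d, decreasing = TRUE))
    # sign convention: dominant climate loading of each dimension positive
    for (k in seq_len(r)) expect_gt(m$U[which.max(abs(m$U[, k])), k], 0)
  }
})

test_that("dimension shares decompose the summed squared coefficients", {
  set.seed(7)
  p <- 4; q <- 9
  U <- qr.Q(qr(matrix(stats::rnorm(p * p), p)))
  V <- qr.Q(qr(matrix(stats::rnorm(q * p), q)))
  mk <- function(d) {
    B <- U %*% diag(d) %*% t(V)
    g <- 30
    X <- scale(matrix(stats::rnorm(g * p), g, p))[, ]
    fit_weighted_rrr(X, X %*% B)  # exact fit reproduces B
  }
  expect_equal(dimension_shares(mk(c(2, 1, 1e-9, 1e-9))), c(0.8, 0.2, 0, 0),
               tolerance = 1e-6)
  expect_equal(dimension_shares(mk(c(3, 1e-9, 1e-9, 1e-9)))[1], 1,
               tolerance = 1e-6)

  m <- mk(c(1.5, 0.9, 0.4, 0.1))
  # element-summing oracle on B itself
  acc <- 0
  for (i in seq_len(nrow(m$B))) for (j in seq_len(ncol(m$B)))
    acc <- acc + m$B[i, j]^2
  expect_equal(dimension_shares(m), m$d^2 / acc, tolerance = 1e-10)
  expect_equal(sum(dimension_shares(m)), 1, tolerance = 1e-12)

  # shares invariant under orthogonal rotation of Y's columns
  Q <- qr.Q(qr(matrix(stats::rnorm(q * q), q)))
  m2 <- fit_weighted_rrr(m$X, m$Y %*% Q)
  expect_equal(dimension_shares(m2), dimension_shares(m), tolerance = 1e-8)

  # fitted values have rank at most r
  expect_lte(qr(m$X %*% m$B)$rank, m$r)
})

test_that("variance explained spans the exact-fit and null cases and calibrates", {
  set.seed(19)
  g <- 20; p <- 3; q <- 5
  X <- scale(matrix(stats::rnorm(g * p), g, p))[, ]
  B <- matrix(stats::rnorm(p * q), p, q)
  expect_equal(variance_explained(fit_weighted_rrr(X, X %*% B)), 1,
               tolerance = 1e-10)

  # Y orthogonal to X: B = 0, nothing explained
  Yn <- qr.Q(qr(cbind(X, matrix(stats::rnorm(g * q), g, q))))[, p + 1:q]
  m0 <- fit_weighted_rrr(X, Yn)
  expect_lt(max(abs(m0$B)), 1e-10)
  expect_equal(variance_explained(m0), 0, tolerance = 1e-10)

  # population R^2 fixed at 0.5 by construction, g = 500
  set.seed(23)
  g <- 500
  X <- scale(matrix(stats::rnorm(g * p), g, p))[, ]
  S <- sum((X %*% B)^2)
  sigma2 <- S * (1 - 0.5) / (0.5 * (g - 1) * q)
  Y <- X %*% B + matrix(stats::rnorm(g * q, sd = sqrt(sigma2)), g, q)
  expect_equal(variance_explained(fit_weighted_rrr(X, Y)), 0.5,
               tolerance = 0.05)
})

test_that("loading vectors are labelled, unit norm, and recover generating structure", {
  tr <- test_truth()
  set.seed(31)
  g <- 16; q <- 30
  V30 <- qr.Q(qr(matrix(stats::rnorm(q * 4), q, 4)))
  B_true <- tr$u_true %*% diag(sqrt(tr$shares)) %*% t(V30)
  X <- scale(matrix(stats::rnorm(g * 4), g, 4))[, ]
  colnames(X) <- c("TMN", "TMX", "HMN", "HMX")
  Y <- X %*% B_true + matrix(stats::rnorm(g * q, sd = 0.01), g, q)
  m <- fit_weighted_rrr(X, Y)
  expect_equal(names(climate_loadings(m, 1)), c("TMN", "TMX", "HMN", "HMX"))
  for (k in 1:4) {
    expect_equal(sum(climate_loadings(m, k)^2), 1, tolerance = 1e-10)
    expect_equal(sum(shape_loading(m, k)^2), 1, tolerance = 1e-10)
  }
  expect_gt(abs(sum(climate_loadings(m, 1) * tr$u_true[, 1])), 0.99)
  expect_gt(abs(sum(shape_loading(m, 1) * V30[, 1])), 0.99)
  expect_error(climate_loadings(m, 5), "out of range")

  # diagonal B: loadings are coordinate axes ordered by |diagonal|
  Xd <- scale(matrix(stats::rnorm(40), 10, 4))[, ]
  md <- fit_weighted_rrr(Xd, Xd %*% diag(c(0.5, 3, 1, 2)))
  expect_equal(abs(unname(md$U)),
               diag(4)[, c(2, 4, 3, 1)], tolerance = 1e-8)
})

test_that("adaptive scores are orthonormal projections about the mean shape", {
  set.seed(43)
  g <- 14; p <- 4; q <- 12
  X <- scale(matrix(stats::rnorm(g * p), g, p))[, ]
  Y <- X %*% matrix(stats::rnorm(p * q), p, q) +
    matrix(stats::rnorm(g * q, sd = 0.1), g, q)
  m <- fit_weighted_rrr(X, Y)
  expect_equal(as.numeric(adaptive_scores(m, m$y_center)), c(0, 0),
               tolerance = 1e-12)
  v1 <- shape_loading(m, 1)
  expect_equal(as.numeric(adaptive_scores(m, m$y_center + 2.5 * v1)),
               c(2.5, 0), tolerance = 1e-10)
  # group mean scores equal projections of Y's rows
  expect_equal(adaptive_scores(m, m$Y + rep(m$y_center, each = g)),
               m$Y %*% m$V[, 1:2], ignore_attr = TRUE, tolerance = 1e-10)
})

test_that("cold- and warm-adapted groups separate along the first dimension", {
  tr <- test_truth()
  gg <- simulate_groups(tr, seed = 5)
  gs <- simulate_group_shapes(tr, gg$climate, gg$D, seed = 5)
  W <- weights_from_distances(gg$D)
  m <- fit_weighted_rrr(gs$X, gs$Y, W)
  sc <- adaptive_scores(m, gs$Y)[, 1]
  # the first latent climate score orders the groups' shape scores
  latent <- drop(gs$X %*% climate_loadings(m, 1))
  expect_gt(abs(stats::cor(sc, latent)), 0.95)
  # extremes separate: top-4 vs bottom-4 latent-climate groups do not overlap
  hi <- order(latent, decreasing = TRUE)[1:4]
  lo <- order(latent)[1:4]
  s_hi <- sc[hi] * sign(stats::cor(sc, latent))
  s_lo <- sc[lo] * sign(stats::cor(sc, latent))
  expect_gt(min(s_hi), max(s_lo))
})

test_that("mean-shape deformations along a dimension behave like mirror displacements", {
  set.seed(61)
  st <- make_scheme_template(n_pairs = 5, n_midline = 2, seed = 9)
  q <- 3 * n_landmarks(st$scheme)
  g <- 12
  X <- scale(matrix(stats::rnorm(g * 4), g, 4))[, ]
  Y <- matrix(rep(flatten_coords(st$template), each = g), g) +
    X %*% matrix(stats::rnorm(4 * q, sd = 0.05), 4, q)
  m <- fit_weighted_rrr(X, Y)
  expect_equal(shape_along_dimension(m, 1, 0),
               unflatten_coords(m$y_center), tolerance = 1e-12)
  plus <- shape_along_dimension(m, 1, 0.3)
  minus <- shape_along_dimension(m, 1, -0.3)
  expect_equal((plus + minus) / 2, unflatten_coords(m$y_center),
               tolerance = 1e-12)
  # element-wise oracle for the maximum landmark displacement
  c_ <- 3 * stats::sd(adaptive_scores(m, Y)[, 1])
  disp <- shape_along_dimension(m, 1, c_) - unflatten_coords(m$y_center)
  v1 <- shape_loading(m, 1)
  oracle <- max(sqrt(rowSums(unflatten_coords(c_ * v1)^2)))
  expect_equal(max(sqrt(rowSums(disp^2))), oracle, tolerance = 1e-12)
})

test_that("size-on-climate regressions match the normal-equations oracle", {
  set.seed(77)
  g <- 16
  X <- scale(matrix(stats::rnorm(g * 4), g, 4))[, ]
  colnames(X) <- c("TMN", "TMX", "HMN", "HMX")

  # constant size: zero slopes, zero R^2
  r0 <- regress_size_on_climate(rep(480, g), X)
  expect_equal(r0$multiple$slope[-1], rep(0, 4), tolerance = 1e-10)
  expect_equal(r0$r_squared, 0)

  # exact single-variable dependence
  r1 <- regress_size_on_climate(2 * X[, "TMN"], X)
  expect_equal(r1$multiple$slope[r1$multiple$term == "TMN"], 2,
               tolerance = 1e-10)
  expect_equal(r1$r_squared, 1, tolerance = 1e-10)

  # random fixture against a direct solve, unweighted and weighted
  cs <- 480 + as.numeric(X %*% c(-8, -1, 0.5, -3)) + stats::rnorm(g, sd = 2)
  W <- weights_from_distances(as.matrix(stats::dist(cbind(stats::runif(g), 0))))
  for (Wi in list(NULL, W)) {
    r <- regress_size_on_climate(cs, X, Wi)
    Winv <- if (is.null(Wi)) diag(g) else solve(Wi + diag(1e-8, g))
    Dx <- cbind(1, X)
    beta <- solve(t(Dx) %*% Winv %*% Dx, t(Dx) %*% Winv %*% cs)
    expect_equal(r$multiple$slope, as.numeric(beta), tolerance = 1e-8)
  }
  expect_equal(nrow(r1$singles), 4L)
})
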