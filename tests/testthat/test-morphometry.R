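test_that("centroid size matches its definition and transforms correctly", {
  expect_equal(centroid_size(matrix(c(3, 1, 4), 1)), 0)
  expect_equal(centroid_size(rbind(c(0, 0, 0), c(1, 0, 0))), sqrt(0.5))

  # brute-force loop oracle on a random 61 x 3 configuration
  set.seed(41)
  x <- random_config(61)
  ctr <- colMeans(x)
  acc <- 0
  for (i in seq_len(nrow(x))) acc <- acc + sum((x[i, ] - ctr)^2)
  expect_equal(centroid_size(x), sqrt(acc), tolerance = 1e-12)

  # scale equivariance and rigid-motion invariance
  for (s in 1:5) {
    set.seed(s)
    x <- random_config(12)
    c_ <- stats::runif(1, 0.1, 5)
    expect_equal(centroid_size(c_ * x), c_ * centroid_size(x),
                 tolerance = 1e-10)
    moved <- sweep(x %*% random_rotation(), 2, stats::rnorm(3, sd = 100), "+")
    expect_equal(centroid_size(moved), centroid_size(x), tolerance = 1e-10)
  }
  expect_error(centroid_size(rbind(c(1, 2, NA))), "finite")
})

test_that("region sizes are subset centroid sizes in original units", {
  sch <- two_region_scheme()
  set.seed(7)
  coords <- random_config(8)
  cfg <- specimen_config("s1", "g1", coords)
  rs <- region_sizes(cfg, sch)
  # direct subset-formula oracle
  for (i in seq_len(nrow(rs))) {
    idx <- which(sch$regions == rs$region[i])
    expect_equal(rs$absolute_cs[i], centroid_size(coords[idx, ]),
                 tolerance = 1e-12)
    expect_equal(rs$relative_cs[i],
                 centroid_size(coords[idx, ]) / centroid_size(coords),
                 tolerance = 1e-12)
  }
  # doubling the configuration doubles absolute CS, leaves ratios alone
  rs2 <- region_sizes(specimen_config("s1", "g1", 2 * coords), sch)
  expect_equal(rs2$absolute_cs, 2 * rs$absolute_cs, tolerance = 1e-10)
  expect_equal(rs2$relative_cs, rs$relative_cs, tolerance = 1e-12)

  # a region covering all landmarks has relative size 1
  labels <- sch$labels
  one <- landmark_scheme(labels,
                         stats::setNames(rep("external_face", 8), labels),
                         matrix(character(), 0, 2), labels)
  expect_equal(region_sizes(cfg, one)$relative_cs, 1)

  # a one-landmark region is degenerate
  degen <- landmark_scheme(labels,
                           stats::setNames(c(rep("external_face", 7),
                                             "choanae"), labels),
                           matrix(character(), 0, 2), labels)
  expect_error(region_sizes(cfg, degen), "degenerate region")
})

test_that("TPS imputation is affine-exact and recovers generated warps", {
  st <- make_scheme_template(n_pairs = 10, n_midline = 5, seed = 2)
  ref <- st$template
  L <- nrow(ref)

  # exact affine transform with one landmark deleted: recovered exactly
  A <- matrix(c(1.2, 0.1, 0, -0.2, 0.9, 0.05, 0, 0.1, 1.1), 3, 3)
  b <- c(3, -1, 2)
  target <- sweep(ref %*% A, 2, b, "+")
  obs <- target; obs[7, ] <- NA
  cfg <- specimen_config("s", "g", obs)
  out <- impute_missing(cfg, ref, st$scheme)
  expect_false(any(out$missing))
  expect_lt(max(abs(out$coords[7, ] - target[7, ])), 1e-8)
  expect_identical(out$coords[-7, ], cfg$coords[-7, ])

  # generated smooth TPS warp (kernel centers at the surviving landmarks):
  # the minimal interpolant is unique, so the deleted point is recovered
  del <- 13L
  keep <- setdiff(seq_len(L), del)
  set.seed(5)
  src <- ref[keep, ]
  W <- matrix(stats::rnorm(length(keep) * 3, sd = 0.02), length(keep), 3)
  P <- cbind(1, src)
  W <- W - P %*% solve(crossprod(P), crossprod(P, W))  # enforce P'W = 0
  warp <- function(pts) {
    d2 <- outer(rowSums(pts^2), rowSums(src^2), "+") - 2 * pts %*% t(src)
    sqrt(pmax(d2, 0)) %*% W + cbind(1, pts) %*% rbind(c(0, 0, 0), diag(3))
  }
  full <- warp(ref)
  obs2 <- full; obs2[del, ] <- NA
  out2 <- impute_missing(specimen_config("s", "g", obs2), ref, st$scheme)
  expect_lt(max(abs(out2$coords[del, ] - full[del, ])), 1e-6)

  # more than four missing landmarks signals exclusion, not imputation
  obs3 <- target; obs3[1:5, ] <- NA
  expect_error(impute_missing(specimen_config("s", "g", obs3), ref, st$scheme),
               class = "climorph_exclusion")
  # coincident source landmarks make the spline system degenerate
  ref_bad <- ref; ref_bad[2, ] <- ref_bad[1, ]
  obs4 <- target; obs4[7, ] <- NA
  expect_error(impute_missing(specimen_config("s", "g", obs4), ref_bad,
                              st$scheme), "degenerate geometry")
})

test_that("GPA registers exactly registrable configurations and meets its conventions", {
  set.seed(9)
  base <- random_config(15)
  c1 <- specimen_config("a", "g", base)
  c2 <- specimen_config("b", "g", random_similarity(base))
  al <- gpa_align(list(c1, c2))
  expect_lt(procrustes_distance(al$shapes[, , 1], al$shapes[, , 2]), 1e-9)
  expect_true(al$converged)

  # superimposition conventions: centered, unit centroid size
  for (i in 1:2) {
    expect_lt(sqrt(sum(colMeans(al$shapes[, , i])^2)), 1e-9)
    expect_equal(centroid_size(al$shapes[, , i]), 1, tolerance = 1e-9)
  }
  expect_equal(centroid_size(al$consensus), 1, tolerance = 1e-9)
  # pre-scaling centroid sizes retained
  expect_equal(al$centroid_sizes,
               c(centroid_size(base), centroid_size(c2$coords)),
               tolerance = 1e-9)
})

test_that("GPA output is invariant to rigid motions and scalings of the inputs", {
  set.seed(21)
  tpl <- make_scheme_template(n_pairs = 8, n_midline = 4, seed = 3)$template
  configs <- lapply(1:6, function(i)
    specimen_config(paste0("s", i), "g",
                    tpl + matrix(stats::rnorm(nrow(tpl) * 3, sd = 0.02),
                                 nrow(tpl))))
  moved <- lapply(configs, function(cf) {
    cf$coords <- random_similarity(cf$coords); cf
  })
  a1 <- gpa_align(configs)
  a2 <- gpa_align(moved)
  for (i in seq_along(configs))
    expect_lt(procrustes_distance(a1$shapes[, , i], a2$shapes[, , i]), 1e-8)
})

test_that("GPA consensus recovers the generating mean shape", {
  tpl <- make_scheme_template(seed = 4)$template
  set.seed(33)
  n <- 50
  configs <- lapply(seq_len(n), function(i)
    specimen_config(paste0("s", i), "g",
                    random_similarity(tpl + matrix(stats::rnorm(183, sd = 0.01),
                                                   61))))
  al <- gpa_align(configs)
  R <- climorph:::optimal_rotation(al$consensus, tpl)
  diffs <- al$consensus %*% R - tpl
  se <- 0.01 / sqrt(n)
  expect_lt(max(abs(diffs)), 4 * se)
  expect_gt(mean(abs(diffs) < 3 * se), 0.98)
})

test_that("reflect-relabel is an involution matching the hand-computed mirror", {
  sch <- tiny_scheme()
  x <- rbind(top = c(0, 0, 1), pL = c(1, 0.2, 0), pR = c(-0.9, 0.1, 0),
             front = c(0.05, 1, 0))
  r <- reflect_relabel(x, sch)
  # hand computation: negate x, then swap the pL/pR rows
  expect_equal(unname(r),
               unname(rbind(c(0, 0, 1), c(0.9, 0.1, 0), c(-1, 0.2, 0),
                            c(-0.05, 1, 0))))
  expect_identical(reflect_relabel(r, sch), x)

  # a perfectly symmetric configuration is a fixed point up to rotation
  sym <- tiny_config()
  expect_lt(procrustes_distance(reflect_relabel(sym, sch), sym), 1e-9)

  # and on the larger generated template
  st <- make_scheme_template(seed = 8)
  expect_lt(procrustes_distance(reflect_relabel(st$template, st$scheme),
                                st$template), 1e-12)
})

test_that("symmetrization fixes symmetric shapes, is idempotent, and halves asymmetries", {
  st <- make_scheme_template(n_pairs = 6, n_midline = 3, seed = 5)
  sym_cfg <- specimen_config("s", "g", st$template)
  out <- symmetrize(list(sym_cfg), st$scheme)
  expect_lt(procrustes_distance(out[[1]]$coords, st$template), 1e-8)

  # asymmetric sample: outputs reflection-invariant, operation idempotent
  set.seed(14)
  configs <- lapply(1:5, function(i)
    specimen_config(paste0("s", i), "g",
                    st$template + matrix(stats::rnorm(nrow(st$template) * 3,
                                                      sd = 0.03),
                                         nrow(st$template))))
  s1 <- symmetrize(configs, st$scheme)
  for (cf in s1)
    expect_lt(procrustes_distance(reflect_relabel(cf, st$scheme)$coords,
                                  cf$coords), 1e-8)
  s2 <- symmetrize(s1, st$scheme)
  for (i in seq_along(s1))
    expect_lt(procrustes_distance(s2[[i]]$coords, s1[[i]]$coords), 1e-8)

  # single displaced landmark: symmetric output approximates the average of
  # the original with its reflected copy (displacement halved, to first order)
  delta <- 1e-3
  x <- st$template
  j <- match(st$scheme$pairs[1, 1], st$scheme$labels)
  x[j, 2] <- x[j, 2] + delta
  out <- symmetrize(list(specimen_config("s", "g", x)), st$scheme)[[1]]$coords
  naive <- (x + reflect_relabel(x, st$scheme)) / 2
  expect_lt(procrustes_distance(out, naive), 10 * delta^2)
  # the paired landmarks end equidistant from the midline plane
  jr <- match(st$scheme$pairs[1, 2], st$scheme$labels)
  aligned <- out %*% climorph:::optimal_rotation(out, naive / centroid_size(naive))
  expect_equal(abs(aligned[j, 1]), abs(aligned[jr, 1]), tolerance = 1e-6)
})

test_that("categorical nuisance correction equalizes class means and is idempotent", {
  # single class: identity
  v <- matrix(stats::rnorm(12), 4)
  expect_equal(remove_group_nuisance(v, rep("M", 4)), v)

  # two singleton classes hand computation
  out <- remove_group_nuisance(matrix(c(2, 4), 2), c("M", "F"))
  expect_equal(as.numeric(out), c(3, 3))

  # simulated sex vector is removed: corrected class means coincide
  set.seed(6)
  n <- 40
  base <- matrix(stats::rnorm(n * 9), n)
  sexes <- rep(c("M", "F"), each = n / 2)
  svec <- stats::rnorm(9)
  shifted <- base + outer(ifelse(sexes == "M", 0.5, -0.5), svec)
  corr <- remove_group_nuisance(shifted, sexes)
  mM <- colMeans(corr[sexes == "M", ]); mF <- colMeans(corr[sexes == "F", ])
  expect_lt(max(abs(mM - mF)), 1e-10)
  expect_equal(colMeans(corr), colMeans(shifted), tolerance = 1e-10)
  # applied twice = applied once
  expect_equal(remove_group_nuisance(corr, sexes), corr, tolerance = 1e-12)

  # unknown-sex rows pass through with a warning
  sx <- c(sexes[-1], "unknown")
  expect_warning(out2 <- remove_group_nuisance(shifted, sx), "passed through")
  expect_equal(out2[n, ], shifted[n, ])
})

test_that("group means equal the loop-computed means and handle trivial groups", {
  set.seed(3)
  m <- matrix(stats::rnorm(30), 10)
  g <- sample(c("a", "b", "c"), 10, replace = TRUE)
  gm <- group_means(m, g)
  for (lvl in rownames(gm)) {
    acc <- rep(0, 3); k <- 0
    for (i in which(g == lvl)) { acc <- acc + m[i, ]; k <- k + 1 }
    expect_equal(unname(gm[lvl, ]), acc / k, tolerance = 1e-12)
  }
  # one specimen per group: pass-through; duplicated shape: that shape
  expect_equal(unname(group_means(m[1:3, ], c("x", "y", "z"))),
               unname(m[1:3, ]))
  expect_equal(unname(group_means(m[c(1, 1), ], c("x", "x"))[1, ]),
               unname(m[1, ]))
  expect_error(group_means(m[0, , drop = FALSE], character()), "non-empty")
})

test_that("single-specimen alignment matches inclusion in the full GPA", {
  st <- make_scheme_template(seed = 10)
  set.seed(50)
  n <- 200
  configs <- lapply(seq_len(n), function(i)
    specimen_config(paste0("s", i), "g",
                    random_similarity(st$template +
                                        matrix(stats::rnorm(183, sd = 0.01), 61))))
  al <- gpa_align(configs)

  # consensus aligns onto itself exactly
  expect_lt(max(abs(unflatten_coords(
    align_new_specimen(al$consensus, al$consensus)) - al$consensus)), 1e-9)
  # a rigidly transformed copy of the consensus registers exactly
  moved <- random_similarity(al$consensus)
  expect_lt(procrustes_distance(
    unflatten_coords(align_new_specimen(moved, al$consensus)), al$consensus),
    1e-9)

  # held-out specimen lands where full-GPA inclusion would put it
  held <- configs[[n]]
  al_rest <- gpa_align(configs[-n])
  row <- align_new_specimen(held, al_rest$consensus)
  # compare in a common frame: rotate the full-GPA copy to the n-1 consensus
  full_row <- rotate_shape_vector(flatten_coords(al$shapes[, , n]),
                                  al$consensus, al_rest$consensus)
  expect_lt(max(abs(row - full_row)), 1e-3)
})
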