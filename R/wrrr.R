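#' Weighted reduced rank regression of shape on climate
#'
#' Computes the matrix of partial regression coefficients
#' `B = (X' W^-1 X)^-1 X' W^-1 Y` of the group shape block `Y` on the
#' standardized climate block `X`, with the symmetric geographic-similarity
#' matrix `W` acting as a generalized-least-squares error structure, and
#' decomposes `B = U diag(d) V'` by a thin singular value decomposition
#' (`r = min(p, q)` identifiable dimensions). Each singular value `d_k` is
#' the regression slope of the latent shape score `Y v_k` on the latent
#' climate score `X u_k`; successive pairs `(u_k, v_k)` are the climate and
#' shape loading vectors of the k-th dimension.
#'
#' `Y` is centered by unweighted column means (set `weighted_centering =
#' TRUE` for GLS-weighted means instead). `X` is expected standardized
#' upstream (see [zscore_columns()]); a warning is issued if its columns are
#' not centered. All solves go through Cholesky / QR factorizations — no
#' explicit matrix inverse.
#'
#' @param X `g x p` standardized climate design (`g > p`).
#' @param Y `g x q` group mean shapes, rows in the same group order as `X`
#'   and `W`.
#' @param W optional `g x g` symmetric positive-definite weight matrix
#'   (identity when omitted, reducing the fit to ordinary least squares).
#' @param ridge small multiple of the identity added to `W` before
#'   factorization (default `1e-8`) guarding against singular similarity
#'   structures (e.g. coincident group locations). A pure rescaling of `W`
#'   leaves `B` unchanged, so the ridge is inert for well-conditioned `W`.
#' @param weighted_centering center `Y` (and check `X`) by GLS-weighted
#'   rather than unweighted means.
#' @param x_center,x_scale optional standardization vectors (from
#'   [zscore_columns()]) stored for reporting.
#' @return object of class `rrr_model`: list with `X`, `Y` (centered), `W`,
#'   `B`, `U`, `d`, `V`, `x_center`, `x_scale`, `y_center`, `x_labels`,
#'   `y_labels`, `groups`, `r`.
#' @export
fit_weighted_rrr <- function(X, Y, W = NULL, ridge = 1e-8,
                             weighted_centering = FALSE,
                             x_center = NULL, x_scale = NULL) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  g <- nrow(X); p <- ncol(X); q <- ncol(Y)
  if (nrow(Y) != g) stop("X and Y must have the same number of rows")
  if (g <= p) stop("need more groups than climate variables (g > p)")
  if (is.null(W)) W <- diag(g)
  W <- as.matrix(W)
  if (nrow(W) != g || any(abs(W - t(W)) > 1e-8))
    stop("W must be a symmetric g x g matrix")
  Wr <- W + diag(ridge, g)
  cW <- tryCatch(chol(Wr),
                 error = function(e)
                   stop("W is not positive definite even after the ridge; ",
                        "increase `ridge` or inspect the distance matrix"))
  # whitening: t(L^-1 M) where Wr = L L'; chol() returns upper R with R'R = Wr
  whiten <- function(M) backsolve(cW, M, transpose = TRUE)

  if (weighted_centering) {
    one <- whiten(matrix(1, g, 1))
    wmean <- function(M) {
      Mw <- whiten(M)
      as.numeric(crossprod(one, Mw) / sum(one^2))
    }
    y_center <- wmean(Y)
    xc <- wmean(X)
  } else {
    y_center <- colMeans(Y)
    xc <- colMeans(X)
  }
  if (max(abs(xc)) > 1e-6)
    warning("X columns are not centered; pass a standardized design ",
            "(see zscore_columns)")
  Yc <- sweep(Y, 2, y_center)

  Xw <- whiten(X)
  Yw <- whiten(Yc)
  qrx <- qr(Xw)
  if (qrx$rank < p) {
    dep <- colnames(X)[qrx$pivot[(qrx$rank + 1):p]]
    stop("collinear climate design; offending column(s): ",
         paste(dep, collapse = ", "))
  }
  B <- qr.coef(qrx, Yw)

  r <- min(p, q)
  s <- svd(B, nu = r, nv = r)
  U <- s$u; V <- s$v; d <- s$d[seq_len(r)]
  # deterministic sign: largest-|entry| climate loading of each u_k positive
  for (k in seq_len(r)) {
    j <- which.max(abs(U[, k]))
    if (U[j, k] < 0) { U[, k] <- -U[, k]; V[, k] <- -V[, k] }
  }
  if (r > 1 && any(abs(diff(d)) < 1e-8))
    message("near-tied singular values; dimension order follows input columns")

  x_labels <- colnames(X) %||% paste0("x", seq_len(p))
  y_labels <- colnames(Y) %||% paste0("y", seq_len(q))
  dimnames(B) <- list(x_labels, y_labels)
  dimnames(U) <- list(x_labels, paste0("dim", seq_len(r)))
  dimnames(V) <- list(y_labels, paste0("dim", seq_len(r)))
  structure(list(X = X, Y = Yc, W = W, B = B, U = U, d = d, V = V,
                 x_center = x_center, x_scale = x_scale,
                 y_center = y_center, x_labels = x_labels,
                 y_labels = y_labels,
                 groups = rownames(X) %||% rownames(Y), r = r,
                 ridge = ridge, cholW = cW),
            class = "rrr_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.rrr_model <- function(x, ...) {
  cat("Weighted reduced rank regression:", nrow(x$X), "groups,",
      ncol(x$X), "climate variables,", ncol(x$Y), "shape coordinates\n")
  sh <- dimension_shares(x)
  cat("dimension shares:", paste(sprintf("%.1f%%", 100 * sh), collapse = ", "),
      "\n")
  cat(sprintf("variance explained (generalized R^2): %.1f%%\n",
              100 * variance_explained(x)))
  invisible(x)
}

#' Per-dimension shares of the summed squared regression coefficients
#'
#' `share_k = d_k^2 / sum_j d_j^2`; the fraction of the total climate-shape
#' regression effect (squared Frobenius norm of `B`) carried by dimension k.
#'
#' @param model an `rrr_model`.
#' @return numeric vector of length `r`, descending, summing to 1.
#' @export
dimension_shares <- function(model) {
  d2 <- model$d^2
  if (sum(d2) <= 0) stop("B is zero: no climate-shape association to share")
  d2 / sum(d2)
}

#' Generalized R-squared of the weighted regression
#'
#' `1 - tr(E' W^-1 E) / tr(Y' W^-1 Y)` with `E = Y - X B` and `Y` centered;
#' reduces to the ordinary multivariate R-squared when `W` is the identity.
#'
#' @param model an `rrr_model`.
#' @param weighted use the model's `W` (default) or the identity.
#' @return fraction in `[0, 1]`.
#' @export
variance_explained <- function(model, weighted = TRUE) {
  E <- model$Y - model$X %*% model$B
  if (weighted) {
    Ew <- backsolve(model$cholW, E, transpose = TRUE)
    Yw <- backsolve(model$cholW, model$Y, transpose = TRUE)
  } else {
    Ew <- E; Yw <- model$Y
  }
  tot <- sum(Yw^2)
  if (tot <= 0) stop("Y has zero total variance")
  1 - sum(Ew^2) / tot
}

#' Climate and shape loading vectors
#'
#' `climate_loadings()` returns `u_k` (labelled by climate variable);
#' `shape_loading()` returns `v_k` (labelled by shape coordinate). Both are
#' unit-norm with the deterministic sign convention applied at fit time.
#'
#' @param model an `rrr_model`.
#' @param k dimension index (`1 <= k <= r`).
#' @export
climate_loadings <- function(model, k = 1L) {
  if (k < 1 || k > model$r) stop("dimension k out of range 1..", model$r)
  model$U[, k]
}

#' @rdname climate_loadings
#' @export
shape_loading <- function(model, k = 1L) {
  if (k < 1 || k > model$r) stop("dimension k out of range 1..", model$r)
  model$V[, k]
}

#' Project shapes into the adaptive shape space
#'
#' Scores are the projections of (centered) shape rows onto the leading
#' shape loading vectors: `(rows - y_center) V[, 1:k_max]`. The span of the
#' first two loading vectors is the "adaptive shape space" in which
#' individual, group-mean and out-of-sample (fossil) shapes are ordinated by
#' their climate-associated features only.
#'
#' @param model an `rrr_model`.
#' @param rows `m x q` matrix of flattened shapes in the same superimposition
#'   as `Y` (out-of-sample specimens via [align_new_specimen()]); a vector is
#'   treated as one row.
#' @param k_max number of dimensions (`<= r`).
#' @return `m x k_max` score matrix.
#' @export
adaptive_scores <- function(model, rows, k_max = 2L) {
  rows <- if (is.null(dim(rows))) matrix(rows, nrow = 1) else as.matrix(rows)
  if (ncol(rows) != length(model$y_center))
    stop("shape rows have ", ncol(rows), " coordinates; model expects ",
         length(model$y_center))
  if (k_max < 1 || k_max > model$r) stop("k_max out of range 1..", model$r)
  sc <- sweep(rows, 2, model$y_center) %*% model$V[, seq_len(k_max), drop = FALSE]
  colnames(sc) <- paste0("dim", seq_len(k_max))
  sc
}

#' Mean shape displaced along an adaptive dimension
#'
#' Returns the configuration `y_center + c * v_k` reshaped to `L x 3` — the
#' numeric endpoints used to display a dimension as a shape deformation
#' (wireframes at `+c` and `-c` are mirror displacements about the mean).
#'
#' @param model an `rrr_model`.
#' @param k dimension index.
#' @param c displacement in score units (e.g. 3 sd of the dimension's
#'   scores).
#' @return `L x 3` matrix.
#' @export
shape_along_dimension <- function(model, k = 1L, c = 1) {
  v <- shape_loading(model, k)
  unflatten_coords(model$y_center + c * v)
}

#' Linear regressions of centroid size on the climate variables
#'
#' Multiple (all predictors jointly) and single-predictor linear regressions
#' of group mean centroid size on the standardized climate design, optionally
#' generalized-least-squares weighted by the geographic similarity matrix.
#'
#' @param cs numeric vector of group centroid sizes (length g).
#' @param X `g x p` standardized climate design.
#' @param W optional `g x g` weight matrix (GLS when supplied).
#' @param ridge diagonal ridge for `W` factorization.
#' @return list with `multiple` (data frame: term, slope, se, t, p),
#'   `r_squared` (of the joint fit), and `singles` (per-predictor slope, se,
#'   t, p, r_squared).
#' @export
regress_size_on_climate <- function(cs, X, W = NULL, ridge = 1e-8) {
  X <- as.matrix(X)
  g <- length(cs); p <- ncol(X)
  if (nrow(X) != g) stop("cs and X disagree on group count")
  if (g <= p + 1) stop("need g > p + 1 groups")
  if (is.null(W)) W <- diag(g)
  cW <- chol(as.matrix(W) + diag(ridge, g))
  wh <- function(M) backsolve(cW, M, transpose = TRUE)
  labs <- colnames(X) %||% paste0("x", seq_len(p))

  gls <- function(design) {
    Dw <- wh(design); yw <- wh(matrix(cs, ncol = 1))
    fit <- stats::lm.fit(Dw, yw)
    if (fit$rank < ncol(design)) stop("collinear climate design")
    rss <- sum(fit$residuals^2)
    dfres <- g - ncol(design)
    XtXinv <- chol2inv(qr.R(fit$qr))
    se <- sqrt(diag(XtXinv) * rss / dfres)
    # null model: intercept only, same whitening
    null_rss <- sum(stats::lm.fit(wh(matrix(1, g, 1)), yw)$residuals^2)
    tval <- fit$coefficients / se
    list(coef = fit$coefficients, se = se, t = tval,
         p = 2 * stats::pt(-abs(tval), dfres),
         r2 = if (null_rss <= .Machine$double.eps) 0 else 1 - rss / null_rss)
  }

  full <- gls(cbind(`(Intercept)` = 1, X))
  multiple <- data.frame(term = c("(Intercept)", labs),
                         slope = unname(full$coef), se = unname(full$se),
                         t = unname(full$t), p = unname(full$p),
                         stringsAsFactors = FALSE)
  singles <- do.call(rbind, lapply(seq_len(p), function(j) {
    sj <- gls(cbind(1, X[, j]))
    data.frame(term = labs[j], slope = sj$coef[2], se = sj$se[2],
               t = sj$t[2], p = sj$p[2], r_squared = sj$r2,
               stringsAsFactors = FALSE)
  }))
  rownames(singles) <- NULL
  list(multiple = multiple, r_squared = full$r2, singles = singles)
}

#' Serialize / restore a fitted model
#'
#' Structured-text (YAML) round trip of the quantities needed to reuse a
#' fit: centers, `B`, `U`, `d`, `V`, labels and group order.
#'
#' @param model an `rrr_model`.
#' @param path output file.
#' @export
write_rrr_model <- function(model, path) {
  y <- list(x_labels = model$x_labels, y_labels = model$y_labels,
            groups = model$groups,
            x_center = as.numeric(model$x_center),
            x_scale = as.numeric(model$x_scale),
            y_center = as.numeric(model$y_center),
            d = as.numeric(model$d),
            B = apply(unname(model$B), 1, as.numeric, simplify = FALSE),
            U = apply(unname(model$U), 1, as.numeric, simplify = FALSE),
            V = apply(unname(model$V), 1, as.numeric, simplify = FALSE))
  yaml::write_yaml(y, path, precision = 17)
  invisible(path)
}

#' @rdname write_rrr_model
#' @return `read_rrr_model()` returns a list with the stored components
#'   (not a refittable `rrr_model`; scores and deformations can be computed
#'   from it).
#' @export
read_rrr_model <- function(path) {
  y <- yaml::read_yaml(path)
  for (nm in c("B", "U", "V"))
    y[[nm]] <- do.call(rbind, lapply(y[[nm]], as.numeric))
  rownames(y$B) <- rownames(y$U) <- y$x_labels
  colnames(y$B) <- rownames(y$V) <- y$y_labels
  y
}
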