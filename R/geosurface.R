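#' Penalized tensor-product spline surface for the index
#'
#' Smooth pixel-level index surfaces are estimated from cluster-level mean
#' scores with a conjugate Gaussian penalized B-spline model. Writing `B`
#' for the tensor-product B-spline design over (lon, lat), `W` for the
#' diagonal matrix of cluster sizes and `P` for the Kronecker-sum
#' difference penalty, the coefficients solve
#'
#'   (B'WB + lambda P) beta = B'Wy,
#'
#' which is the posterior mean under the Gaussian prior
#' `beta ~ N(0, sigma^2 / lambda * P^-)`; the posterior covariance
#' `sigma^2 (B'WB + lambda P)^-1` yields pointwise prediction standard
#' deviations. `lambda = "auto"` minimizes generalized cross-validation
#' over a log-spaced grid. For an order-2 penalty, the penalty null space
#' is the bilinear sheet span{1, x, y, xy}; as `lambda -> infinity` the fit
#' shrinks to the weighted least-squares fit in that space.
#'
#' @name geosurface
NULL

# Equally spaced B-spline basis over [lo, hi] with n_int interior knots.
bspline_basis <- function(x, lo, hi, n_int, degree) {
  h <- (hi - lo) / (n_int + 1)
  inner <- seq(lo, hi, length.out = n_int + 2)
  inner[1] <- lo          # pin the boundary knots so the evaluable range
  inner[n_int + 2] <- hi  # covers the data extremes exactly
  knots <- c(lo - (degree:1) * h, inner, hi + (1:degree) * h)
  splines::splineDesign(knots, x, ord = degree + 1, outer.ok = FALSE)
}

tensor_design <- function(lon, lat, sp) {
  B1 <- bspline_basis(lon, sp$lon_lo, sp$lon_hi, sp$n_knots, sp$degree)
  B2 <- bspline_basis(lat, sp$lat_lo, sp$lat_hi, sp$n_knots, sp$degree)
  k1 <- ncol(B1)
  k2 <- ncol(B2)
  B1[, rep(seq_len(k1), each = k2), drop = FALSE] *
    B2[, rep(seq_len(k2), times = k1), drop = FALSE]
}

penalty_matrix <- function(k1, k2, order) {
  D1 <- diff(diag(k1), differences = order)
  D2 <- diff(diag(k2), differences = order)
  kronecker(crossprod(D1), diag(k2)) + kronecker(diag(k1), crossprod(D2))
}

#' Fit the index surface
#'
#' @param cluster_points data frame with `lon`, `lat`, `mean_score` and
#'   `n_households` (used as fit weights).
#' @param n_knots number of interior knots per coordinate (default 12).
#' @param degree spline degree (default cubic).
#' @param penalty_order difference-penalty order (default 2).
#' @param lambda positive smoothing parameter, or `"auto"` for GCV
#'   selection over `lambda_grid`.
#' @param lambda_grid candidate grid for `"auto"`.
#' @return object of class `pdi_surface` with the basis specification,
#'   `lambda`, `coefficients`, the Cholesky factor of the penalized normal
#'   matrix (`posterior_cov_factor`), `noise_variance` and `edf`.
#' @export
fit_surface <- function(cluster_points, n_knots = 12L, degree = 3L,
                        penalty_order = 2L, lambda = "auto",
                        lambda_grid = 10^seq(-4, 6, length.out = 31)) {
  stopifnot(is.data.frame(cluster_points),
            all(c("lon", "lat", "mean_score", "n_households") %in%
                  names(cluster_points)))
  n <- nrow(cluster_points)
  if (n < 10) stop("need at least 10 clusters to fit a surface")
  if (length(unique(cluster_points$lon)) < 2 ||
      length(unique(cluster_points$lat)) < 2) {
    stop("clusters are collinear in one coordinate; surface undefined")
  }
  sp <- list(
    lon_lo = min(cluster_points$lon), lon_hi = max(cluster_points$lon),
    lat_lo = min(cluster_points$lat), lat_hi = max(cluster_points$lat),
    n_knots = as.integer(n_knots), degree = as.integer(degree),
    penalty_order = as.integer(penalty_order)
  )
  B <- tensor_design(cluster_points$lon, cluster_points$lat, sp)
  k <- ncol(B)
  k1d <- sp$n_knots + 1L + sp$degree
  P <- penalty_matrix(k1d, k1d, sp$penalty_order)
  w <- cluster_points$n_households
  stopifnot(all(w > 0))
  y <- cluster_points$mean_score
  BtWB <- crossprod(B * w, B)
  BtWy <- drop(crossprod(B, w * y))

  solve_for <- function(lam) {
    A <- BtWB + lam * P
    R <- tryCatch(chol(A), error = function(e) {
      stop("singular penalized system; increase lambda or reduce knots")
    })
    beta <- backsolve(R, forwardsolve(t(R), BtWy))
    list(R = R, beta = beta)
  }

  gcv_score <- function(lam) {
    fit <- solve_for(lam)
    yhat <- drop(B %*% fit$beta)
    # edf = tr[(B'WB + lam P)^-1 B'WB]
    edf <- sum(diag(backsolve(fit$R, forwardsolve(t(fit$R), BtWB))))
    rss <- sum(w * (y - yhat)^2)
    n * rss / (n - edf)^2
  }

  if (identical(lambda, "auto")) {
    scores <- vapply(lambda_grid, gcv_score, numeric(1))
    lambda <- lambda_grid[which.min(scores)]
  }
  stopifnot(is.numeric(lambda), lambda > 0)
  fit <- solve_for(lambda)
  yhat <- drop(B %*% fit$beta)
  edf <- sum(diag(backsolve(fit$R, forwardsolve(t(fit$R), BtWB))))
  rss <- sum(w * (y - yhat)^2)
  noise_variance <- if (n - edf > 1e-8) rss / (n - edf) else 0
  structure(
    list(
      spec = sp,
      lambda = lambda,
      coefficients = fit$beta,
      posterior_cov_factor = fit$R,
      noise_variance = noise_variance,
      edf = edf,
      n_clusters = n
    ),
    class = "pdi_surface"
  )
}

#' Predict the surface on a pixel grid
#'
#' The grid follows the raster convention of [generate_density_raster()]:
#' `origin` is the upper-left corner, row 1 is northernmost, and values are
#' evaluated at cell centres. All cell centres must lie inside the spline
#' domain (the bounding box of the training clusters).
#'
#' @param surface a `pdi_surface`.
#' @param origin_lon,origin_lat upper-left corner of the grid (degrees).
#' @param cell_size cell size in degrees.
#' @param n_rows,n_cols grid dimensions.
#' @return list with matrices `mean` and `sd` plus the grid header fields.
#' @export
predict_grid <- function(surface, origin_lon, origin_lat, cell_size,
                         n_rows, n_cols) {
  stopifnot(inherits(surface, "pdi_surface"))
  cx <- origin_lon + (seq_len(n_cols) - 0.5) * cell_size
  cy <- origin_lat - (seq_len(n_rows) - 0.5) * cell_size
  sp <- surface$spec
  if (min(cx) < sp$lon_lo || max(cx) > sp$lon_hi ||
      min(cy) < sp$lat_lo || max(cy) > sp$lat_hi) {
    stop("grid cell centres fall outside the spline domain (",
         sprintf("lon [%g, %g], lat [%g, %g])", sp$lon_lo, sp$lon_hi,
                 sp$lat_lo, sp$lat_hi))
  }
  pts <- expand.grid(lat = cy, lon = cx, KEEP.OUT.ATTRS = FALSE)
  Bg <- tensor_design(pts$lon, pts$lat, sp)
  mu <- drop(Bg %*% surface$coefficients)
  # sd_i = sigma * || R^-T b_i ||  with A = R'R the penalized normal matrix
  M <- forwardsolve(t(surface$posterior_cov_factor), t(Bg))
  sdv <- sqrt(pmax(surface$noise_variance, 0) * colSums(M^2))
  list(
    mean = matrix(mu, n_rows, n_cols),
    sd = matrix(sdv, n_rows, n_cols),
    origin_lon = origin_lon, origin_lat = origin_lat,
    cell_size = cell_size, n_rows = n_rows, n_cols = n_cols
  )
}

#' Pointwise surface prediction
#'
#' @param surface a `pdi_surface`.
#' @param lon,lat coordinates inside the spline domain.
#' @return data frame with `mean` and `sd`.
#' @export
predict_surface <- function(surface, lon, lat) {
  stopifnot(inherits(surface, "pdi_surface"))
  sp <- surface$spec
  if (any(lon < sp$lon_lo | lon > sp$lon_hi | lat < sp$lat_lo | lat > sp$lat_hi)) {
    stop("prediction points fall outside the spline domain")
  }
  Bg <- tensor_design(lon, lat, sp)
  M <- forwardsolve(t(surface$posterior_cov_factor), t(Bg))
  data.frame(
    mean = drop(Bg %*% surface$coefficients),
    sd = sqrt(pmax(surface$noise_variance, 0) * colSums(M^2))
  )
}

#' Min-max normalize a predicted grid
#'
#' Applies [normalize_minmax()] to the mean grid; a constant grid is a
#' degenerate range and raises an error.
#'
#' @param grid output of [predict_grid()].
#' @param domain optional explicit `c(min, max)`.
#' @return the grid with `mean` replaced by its normalized values.
#' @export
normalize_surface <- function(grid, domain = NULL) {
  stopifnot(is.list(grid), is.matrix(grid$mean))
  grid$mean <- matrix(normalize_minmax(as.vector(grid$mean), domain = domain),
                      nrow(grid$mean), ncol(grid$mean))
  grid
}
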