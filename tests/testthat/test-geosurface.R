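random_clusters <- function(n = 50, seed = 11, noise = NULL) {
  set.seed(seed)
  df <- data.frame(lon = runif(n, 0, 10), lat = runif(n, 0, 10),
                   mean_score = rnorm(n),
                   n_households = sample(5:30, n, replace = TRUE))
  df
}

test_that("coefficients equal the dense penalized-normal-equation solve", {
  for (case in list(list(n = 50, lam = 3.7), list(n = 200, lam = 0.05))) {
    pts <- random_clusters(case$n, seed = case$n)
    s <- fit_surface(pts, lambda = case$lam)
    sp <- s$spec
    B <- pdindex:::tensor_design(pts$lon, pts$lat, sp)
    k1 <- sp$n_knots + 1 + sp$degree
    P <- pdindex:::penalty_matrix(k1, k1, sp$penalty_order)
    beta <- solve(crossprod(B * pts$n_households, B) + case$lam * P,
                  crossprod(B, pts$n_households * pts$mean_score))
    expect_equal(s$coefficients, drop(beta), tolerance = 1e-6)
  }
})

test_that("constant scores give a constant surface for any lambda", {
  pts <- random_clusters(40, seed = 3)
  pts$mean_score <- 0.7
  for (lam in c(1e-3, 1, 1e4)) {
    s <- fit_surface(pts, lambda = lam)
    g <- predict_grid(s, s$spec$lon_lo, s$spec$lat_hi,
                      (s$spec$lon_hi - s$spec$lon_lo) / 10, 9, 9)
    expect_lt(max(abs(g$mean - 0.7)), 1e-6)
  }
})

test_that("lambda -> infinity shrinks to the weighted bilinear (penalty null space) fit", {
  pts <- random_clusters(60, seed = 4)
  s <- fit_surface(pts, lambda = 1e8)
  X <- cbind(1, pts$lon, pts$lat, pts$lon * pts$lat)
  wls <- lm.wfit(X, pts$mean_score, pts$n_households)
  pred <- predict_surface(s, pts$lon, pts$lat)$mean
  expect_equal(pred, drop(X %*% wls$coefficients), tolerance = 1e-3)
  # planar data: the limit is the plane itself
  pts$mean_score <- 1 + 0.2 * pts$lon - 0.1 * pts$lat
  s2 <- fit_surface(pts, lambda = 1e8)
  expect_equal(predict_surface(s2, pts$lon, pts$lat)$mean, pts$mean_score,
               tolerance = 1e-4)
})

test_that("noiseless smooth data is interpolated and recovered on a grid", {
  f <- function(x, y) 0.3 + 0.05 * x + 0.08 * y + 0.01 * x * y
  set.seed(2)
  pts <- data.frame(lon = runif(120, 0, 10), lat = runif(120, 0, 10),
                    n_households = 10)
  pts$mean_score <- f(pts$lon, pts$lat)
  s <- fit_surface(pts, lambda = 1e-6)
  expect_equal(predict_surface(s, pts$lon, pts$lat)$mean, pts$mean_score,
               tolerance = 1e-3)
  g <- predict_grid(s, 0.5, 9.5, 0.5, 17, 17)
  cx <- 0.5 + (1:17 - 0.5) * 0.5
  cy <- 9.5 - (1:17 - 0.5) * 0.5
  truth <- outer(cy, cx, function(y, x) f(x, y))
  expect_lt(sqrt(mean((g$mean - truth)^2)), 0.01)
})

test_that("grid prediction is pointwise evaluation on the raster convention", {
  pts <- random_clusters(50, seed = 5)
  s <- fit_surface(pts, lambda = 1)
  g <- predict_grid(s, 1, 9, 0.5, 6, 7)
  cx <- 1 + (1:7 - 0.5) * 0.5
  cy <- 9 - (1:6 - 0.5) * 0.5
  for (i in c(1, 4)) {
    for (j in c(2, 7)) {
      p <- predict_surface(s, cx[j], cy[i])
      expect_equal(g$mean[i, j], p$mean, tolerance = 1e-12)
      expect_equal(g$sd[i, j], p$sd, tolerance = 1e-12)
    }
  }
  expect_error(predict_grid(s, -50, 9, 1, 5, 5), "outside the spline domain")
})

test_that("prediction sd is non-negative and shrinks with more households at a cluster", {
  pts <- random_clusters(50, seed = 6)
  pts$n_households[1] <- 5
  sA <- fit_surface(pts, lambda = 10)
  pts$n_households[1] <- 500
  sB <- fit_surface(pts, lambda = 10)
  gA <- predict_grid(sA, sA$spec$lon_lo, sA$spec$lat_hi, 0.5, 10, 10)
  expect_true(all(gA$sd >= 0))
  # compare on the covariance-factor scale to isolate the weight effect
  atA <- predict_surface(sA, pts$lon[1], pts$lat[1])$sd / sqrt(sA$noise_variance)
  atB <- predict_surface(sB, pts$lon[1], pts$lat[1])$sd / sqrt(sB$noise_variance)
  expect_lte(atB, atA)
})

test_that("degenerate inputs raise instructive errors", {
  pts <- random_clusters(8, seed = 7)
  expect_error(fit_surface(pts), "at least 10")
  pts <- random_clusters(20, seed = 8)
  pts$lat <- 5
  expect_error(fit_surface(pts), "collinear")
})

test_that("normalize_surface maps the mean grid to [0, 1] preserving order", {
  pts <- random_clusters(40, seed = 9)
  s <- fit_surface(pts, lambda = 1)
  g <- predict_grid(s, s$spec$lon_lo, s$spec$lat_hi, 0.9, 10, 10)
  ng <- normalize_surface(g)
  expect_equal(min(ng$mean), 0)
  expect_equal(max(ng$mean), 1)
  expect_identical(order(as.vector(ng$mean)), order(as.vector(g$mean)))
  g$mean[] <- 0.5
  expect_error(normalize_surface(g), "degenerate")
})
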