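# steepest-slope tracing, elliptic Fourier smoothing, upright rotation

hstack_circles <- function(radii, levels, n = 120L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  structure(
    list(contours = lapply(radii, function(r) cbind(r * cos(th),
                                                    r * sin(th))),
         levels = levels, bottleneck_index = 1L, section_sizes = n, n = n),
    class = "HomologizedStack")
}

test_that("steepness is constant on a constant-slope wall", {
  # cone: radius decreases linearly with depth
  k <- 10
  z <- seq(-0.05, -0.005, length.out = k)
  r <- 0.1 * (1 + z / 0.055)
  h <- hstack_circles(r, z)
  col <- steepnessColumn(h, 7L, window = 5L)
  s <- col$steepness
  expect_lt(diff(range(s)) / mean(s), 0.02)
  expect_equal(sum(col$weights), 1, tolerance = 1e-9)
  # equal steepness implies (nearly) equal weights
  expect_lt(diff(range(col$weights)) / mean(col$weights), 0.05)
  # window = 0 reduces to within-column distances
  col0 <- steepnessColumn(h, 7L, window = 0L)
  dz <- mean(abs(diff(z)))
  expect_equal(col0$steepness[2], dz / abs(r[1] - r[2]), tolerance = 1e-9)
})

test_that("steepness peaks at the logistic wall's inflexion level", {
  depth <- 0.03; w <- 0.004; R <- 0.15; k <- 25
  z <- seq(-depth * 0.97, -depth * 0.03, length.out = k)
  zt <- -z / depth
  r <- R - w * log(zt / (1 - zt))  # analytic contour radius per level
  h <- hstack_circles(r, z)
  col <- steepnessColumn(h, 3L, window = 3L)
  z_star <- -depth / 2
  expect_equal(which.max(col$steepness), which.min(abs(z - z_star)))
})

test_that("weighted wall point follows the stated weighting rules", {
  # equal steepness: plain arithmetic mean
  col <- list(steepness = c(1, 1, 1), weights = rep(1 / 3, 3),
              point = rbind(c(0, 0), c(1, 0), c(2, 3)))
  expect_equal(weightedWallPoint(col), colMeans(col$point))
  # steepness (2, 1) with exponent 1: (2 p1 + 1 p2) / 3
  s <- c(2, 1); w <- (s / max(s))^1; w <- w / sum(w)
  col2 <- list(steepness = s, weights = w,
               point = rbind(c(1, 1), c(4, -2)))
  expect_equal(weightedWallPoint(col2),
               (2 * c(1, 1) + 1 * c(4, -2)) / 3, tolerance = 1e-12)
  # exponent 8 concentrates > 99% of the weight on the steepest level
  s3 <- c(1, 0.5, 0.4)
  w8 <- (s3 / max(s3))^8; w8 <- w8 / sum(w8)
  expect_gt(w8[1], 0.99)
  # all-zero steepness: unweighted mean with a warning
  col0 <- list(steepness = c(0, 0), weights = c(0.5, 0.5),
               point = rbind(c(0, 0), c(2, 2)))
  expect_warning(p <- weightedWallPoint(col0), "zero")
  expect_equal(p, c(1, 1))
})

test_that("raw outline of identical concentric copies is their radial mean", {
  h <- hstack_circles(c(0.5, 0.5, 0.5), c(-3, -2, -1))
  raw <- traceRawOutline(h)
  expect_equal(nrow(raw), h$n + 1L)  # closed
  expect_equal(raw[1, ], raw[nrow(raw), ])
  rr <- sqrt(rowSums(raw^2))
  expect_equal(rr, rep(0.5, h$n + 1L), tolerance = 1e-9)
})

test_that("raw outline lands on the steepest-slope circle of a logistic pit", {
  fp <- generateFootprint(footprintSpec(kind = "hemisphere",
                                        target_faces = 20000))
  st <- trimStackByArea(selectPrimaryStack(
    extractLevelContours(orientMesh(fp$mesh), 30L)), 1.5, 1.3)
  raw <- traceRawOutline(homologizeStack(st, 500L))
  rr <- sqrt(rowSums(raw^2))
  expect_lt(max(abs(rr - 0.15)) / 0.3, 0.02)
})

test_that("elliptic Fourier fit is exact on an ellipse and monotone in harmonics", {
  th <- seq(0, 2 * pi, length.out = 4001)[-4001]
  ell <- cbind(2 * cos(th), sin(th))
  out <- ellipticFourierSmooth(ell, harmonics = 1L,
                               smoothing_iterations = 0L)
  expect_lt(max(sqrt(rowSums((out$points[-4001, ] - ell)^2))) / 2, 1e-6)

  pb <- blob_polygon(400)
  res <- vapply(1:15, function(h) {
    o <- ellipticFourierSmooth(pb, harmonics = h, smoothing_iterations = 0L)
    sqrt(mean(rowSums((o$points[-401, ] - pb)^2)))
  }, 0)
  expect_true(all(diff(res) <= 1e-12))

  # defaults are recorded on the outline
  o <- ellipticFourierSmooth(blob_polygon(300))
  expect_identical(o$harmonics, 25L)
  expect_identical(o$smoothing_iterations, 10L)
  expect_error(ellipticFourierSmooth(blob_polygon(30), harmonics = 25L),
               "contract error")
})

test_that("smoothing barely moves the centroid", {
  pb <- blob_polygon(300, 4)
  o <- ellipticFourierSmooth(pb, 25L, 10L)
  diag_len <- sqrt(sum(apply(pb, 2, function(v) diff(range(v)))^2))
  expect_lt(sqrt(sum((o$centroid - colMeans(pb))^2)), 0.01 * diag_len)
})

test_that("upright rotation maximizes outline length above the centroid", {
  # circle: full rotational symmetry, any angle is optimal; the result
  # must be deterministic and leave the shape unchanged
  th <- seq(0, 2 * pi, length.out = 361)[-361]
  circ <- ellipticFourierSmooth(cbind(cos(th), sin(th)), 1L, 0L)
  up <- rotateUpright(circ)
  expect_true(up$upright_angle %in% 1:360)
  expect_identical(up$upright_angle, rotateUpright(circ)$upright_angle)
  rr <- sqrt(rowSums(sweep(up$points, 2, up$centroid)^2))
  expect_equal(rr, rep(1, length(rr)), tolerance = 1e-4)

  # rotating the input by whole degrees leaves the upright result the same
  pb <- blob_polygon(360, 2)
  u1 <- rotateUpright(ellipticFourierSmooth(pb, 15L, 0L))
  pb2 <- pb %*% t(trackline:::.rot2(37))
  u2 <- rotateUpright(ellipticFourierSmooth(pb2, 15L, 0L))
  expect_lt(outline_mean_dist(u1$points[-361, ], u2$points[-361, ]), 1e-6)
})
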