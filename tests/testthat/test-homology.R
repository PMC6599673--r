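# equidistant resampling, direction unification, bottleneck homology

test_that("equidistant resampling spaces points uniformly and keeps perimeter", {
  th <- seq(0, 2 * pi, length.out = 1001)[-1001]
  circ <- cbind(cos(th), sin(th))
  rs <- resampleEquidistant(circ, 500L)
  gaps <- sqrt(rowSums(diff(rbind(rs, rs[1, ]))^2))
  expect_lt(diff(range(gaps)) / mean(gaps), 1e-6)
  per <- sum(gaps)
  expect_equal(per, 2 * pi, tolerance = 0.005 * 2 * pi)
  expect_equal(rs[1, ], circ[1, ], tolerance = 1e-12)

  # unit square at n = 8: corners and edge midpoints (arc-length oracle)
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  rs8 <- resampleEquidistant(sq, 8L)
  expect_equal(rs8,
               rbind(c(0, 0), c(0.5, 0), c(1, 0), c(1, 0.5), c(1, 1),
                     c(0.5, 1), c(0, 1), c(0, 0.5)),
               tolerance = 1e-12)

  expect_error(resampleEquidistant(rbind(c(0, 0), c(0, 0), c(0, 0)), 10L),
               "geometry error")
})

test_that("direction unification makes all contours counter-clockwise", {
  cw <- blob_polygon(80)[80:1, ]
  ccw <- blob_polygon(90, 2)
  out <- unifyDirection(list(cw, ccw))
  sa <- vapply(out, trackline:::.polygon_area_signed, 0)
  expect_true(all(sa > 0))
  # reversal preserves the point set and the start point
  expect_equal(out[[1]][1, ], cw[1, ])
  expect_equal(out[[1]][order(out[[1]][, 1], out[[1]][, 2]), ],
               cw[order(cw[, 1], cw[, 2]), ])
  # idempotence
  expect_identical(unifyDirection(out), out)
})

exhaustive_bottleneck <- function(inner, outer, excluded = integer()) {
  best <- c(Inf, NA, NA)
  for (jo in seq_len(nrow(outer))) {
    if (jo %in% excluded) next
    for (ji in seq_len(nrow(inner))) {
      d <- sqrt(sum((inner[ji, ] - outer[jo, ])^2))
      if (d < best[1] - 1e-15) best <- c(d, ji, jo)
    }
  }
  best
}

test_that("bottleneck search equals the exhaustive n^2 scan", {
  # concentric circles: gap equals the radius difference
  th <- seq(0, 2 * pi, length.out = 121)[-121]
  inner <- cbind(cos(th), sin(th))
  outer <- 1.25 * inner
  b <- findBottleneck(inner, outer)
  expect_equal(b$gap, 0.25, tolerance = 1e-9)

  # concentric ellipses: minimal pair on the minor axis
  ei <- cbind(2 * cos(th), sin(th))
  eo <- cbind(2.4 * cos(th), 1.1 * sin(th))
  b2 <- findBottleneck(ei, eo)
  oracle <- exhaustive_bottleneck(ei, eo)
  expect_equal(b2$gap, oracle[1], tolerance = 1e-12)
  expect_lt(abs(abs(ei[b2$inner_index, 2]) - 1), 0.01)  # near minor axis

  # masking the minor-axis arcs forces the major-axis pair
  minor_arcs <- which(abs(eo[, 2]) > 0.5 * 1.1)
  b3 <- findBottleneck(ei, eo, excluded_outer = minor_arcs)
  oracle3 <- exhaustive_bottleneck(ei, eo, excluded = minor_arcs)
  expect_equal(b3$gap, oracle3[1], tolerance = 1e-12)
  expect_false(b3$outer_index %in% minor_arcs)

  # random blobs, n <= 200: exact agreement including the index pair
  for (k in 1:4) {
    a <- blob_polygon(150, k)
    bpoly <- 1.3 * blob_polygon(180, k + 0.5)
    got <- findBottleneck(a, bpoly)
    want <- exhaustive_bottleneck(a, bpoly)
    expect_equal(got$gap, want[1], tolerance = 1e-12)
  }

  expect_error(findBottleneck(inner, outer,
                              excluded_outer = seq_len(nrow(outer))),
               "contract error")
})

circle_stack <- function(radii, n = 160L) {
  cts <- lapply(seq_along(radii), function(i) {
    th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
    trackline:::.make_contour(i, list(x = radii[i] * cos(th),
                                      y = radii[i] * sin(th)), TRUE)
  })
  structure(list(contours = cts, levels = seq_along(radii),
                 level_index = seq_along(radii), impression_index = 0L),
            class = "ContourStack")
}

test_that("homologization aligns concentric circles along radial rays", {
  st <- circle_stack(c(0.5, 0.65, 0.8, 1))
  h <- homologizeStack(st, n = 200L)
  expect_true(all(vapply(h$contours, nrow, 1L) == 200L))
  expect_gte(length(h$bottleneck_index), 6L)
  # homologous points share polar angle within 1 degree
  ang <- vapply(h$contours, function(p) atan2(p[, 2], p[, 1]),
                numeric(200L))
  spread <- apply(ang, 1, function(a) {
    a <- a - a[1]
    max(abs(atan2(sin(a), cos(a))))
  })
  expect_lt(max(spread) * 180 / pi, 1)
})

blob_stack <- function(scales, n = 120L) {
  # equal-chord base polygon (fixed point of the resampler, reached by
  # iteration): whole-point start rotations then reproduce the same
  # resampled geometry exactly
  base <- blob_polygon(4 * n, 3)
  for (it in 1:20) base <- resample_ring(base, n)
  cts <- lapply(seq_along(scales), function(i)
    trackline:::.make_contour(i, list(x = scales[i] * base[, 1],
                                      y = scales[i] * base[, 2]), TRUE))
  structure(list(contours = cts, levels = seq_along(scales),
                 level_index = seq_along(scales), impression_index = 0L),
            class = "ContourStack")
}

test_that("homologization is invariant to each contour's start index", {
  # generic (non-symmetric) contours: on perfect circles every pair ties
  st <- blob_stack(c(0.6, 0.8, 1), n = 120L)
  h1 <- homologizeStack(st, n = 120L)
  st2 <- st
  for (i in seq_along(st2$contours)) {
    p <- st2$contours[[i]]$points
    k <- 13 * i
    st2$contours[[i]]$points <- p[c(k:nrow(p), seq_len(k - 1L)), ]
  }
  h2 <- homologizeStack(st2, n = 120L)
  for (i in seq_along(h1$contours))
    expect_equal(h1$contours[[i]], h2$contours[[i]], tolerance = 1e-6)
})

test_that("homologous indices never cross between bottlenecks", {
  fp <- generateFootprint(footprintSpec(kind = "tridactyl",
                                        target_faces = 20000))
  st <- trimStackByArea(selectPrimaryStack(
    extractLevelContours(orientMesh(fp$mesh), 30L)), 1.5, 1.3)
  h <- homologizeStack(st, n = 300L)
  expect_true(all(vapply(h$contours, nrow, 1L) == 300L))
  expect_true(all(diff(h$bottleneck_index) > 0))
  # single-contour stack passes through with a warning
  st1 <- st; st1$contours <- st1$contours[1]
  expect_warning(h1 <- homologizeStack(st1, n = 100L), "trivial homology")
  expect_equal(nrow(h1$contours[[1]]), 100L)
})
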