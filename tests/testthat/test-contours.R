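# contour extraction, stack selection, area trimming

circle_contour <- function(level, perimeter, center = c(0, 0), n = 100L) {
  r <- perimeter / (2 * pi)
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  pts <- cbind(center[1] + r * cos(th), center[2] + r * sin(th))
  trackline:::.make_contour(level, list(x = pts[, 1], y = pts[, 2]), TRUE)
}

open_contour <- function(level) {
  pts <- cbind(seq(0, 1, length.out = 10), 0)
  trackline:::.make_contour(level, list(x = pts[, 1], y = pts[, 2]), FALSE)
}

fake_candidates <- function(per_level) {
  list(levels = seq_along(per_level), candidates = per_level, pitch = 0.01)
}

test_that("conical pit contours match the analytic cone sections", {
  fp <- generateFootprint(footprintSpec(kind = "cone", target_faces = 40000))
  cl <- orientMesh(fp$mesh)
  cands <- extractLevelContours(cl, n_levels = 30L)
  expect_length(cands$levels, 30L)
  expect_equal(length(unique(cands$levels)), 30L)
  stack <- selectPrimaryStack(cands)
  R <- 0.15; d <- 0.03
  for (ct in stack$contours) {
    r_exp <- R * (1 - abs(ct$level) / d)
    r_obs <- sqrt(rowSums(sweep(ct$points, 2, colMeans(ct$points))^2))
    expect_lt(max(abs(r_obs - r_exp)), cands$pitch)
    # centroid on the pit axis within grid resolution
    expect_lt(sqrt(sum(colMeans(ct$points)^2)), cands$pitch)
  }
})

test_that("contours crossing the model margin come back open", {
  # craft a grid whose pit runs off the covered region
  xs <- seq(0, 1, length.out = 50)
  z <- matrix(NA_real_, 50, 50)
  for (i in 1:50) for (j in 1:50) {
    r <- sqrt((xs[i] - 0.1)^2 + (xs[j] - 0.5)^2)
    if (xs[i] > 0.05) z[i, j] <- min(r, 0.6)
  }
  cands <- extractLevelContours(list(x = xs, y = xs, z = z, pitch = xs[2]),
                                n_levels = 10L)
  flags <- unlist(lapply(cands$candidates, function(cs)
    vapply(cs, `[[`, TRUE, "is_closed")))
  expect_true(any(!flags))
})

test_that("length and area agree with brute-force perimeter/shoelace oracles", {
  fp <- generateFootprint(footprintSpec(kind = "tridactyl",
                                        target_faces = 20000))
  st <- selectPrimaryStack(extractLevelContours(orientMesh(fp$mesh), 30L))
  for (ct in st$contours[c(1, length(st$contours) %/% 2,
                           length(st$contours))]) {
    p <- ct$points
    n <- nrow(p)
    per <- 0; area2 <- 0
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      per <- per + sqrt(sum((p[j, ] - p[i, ])^2))
      area2 <- area2 + p[i, 1] * p[j, 2] - p[j, 1] * p[i, 2]
    }
    expect_equal(ct$length, per, tolerance = 1e-9)
    expect_equal(ct$area, abs(area2) / 2, tolerance = 1e-9)
  }
})

test_that("stack selection applies the open/longest/50% rules without gaps", {
  # interior short contour survives because removing it would leave a gap
  cands <- fake_candidates(list(
    list(circle_contour(1, 10)), list(circle_contour(2, 9)),
    list(circle_contour(3, 8)), list(circle_contour(4, 4)),
    list(circle_contour(5, 9))))
  st <- selectPrimaryStack(cands)
  expect_equal(vapply(st$contours, `[[`, 0, "length"), c(10, 9, 8, 4, 9),
               tolerance = 1e-3)  # polygonal perimeter < 2*pi*r

  # short end contours are removed
  cands2 <- fake_candidates(list(
    list(circle_contour(1, 3)), list(circle_contour(2, 9)),
    list(circle_contour(3, 10)), list(circle_contour(4, 9)),
    list(circle_contour(5, 4))))
  st2 <- selectPrimaryStack(cands2)
  expect_equal(vapply(st2$contours, `[[`, 0, "length"), c(9, 10, 9),
               tolerance = 1e-3)
  expect_equal(st2$level_index, 2:4)

  # longest-per-level rule; open contours never enter
  cands3 <- fake_candidates(list(
    list(circle_contour(1, 7), circle_contour(1, 5), open_contour(1)),
    list(circle_contour(2, 6))))
  st3 <- selectPrimaryStack(cands3)
  expect_equal(st3$contours[[1]]$length, 7, tolerance = 1e-3)

  expect_error(selectPrimaryStack(fake_candidates(list(
    list(open_contour(1)), list()))), "no footprint found")
})

test_that("area trimming truncates at the first jump, separately per half", {
  mk <- function(areas) {
    cts <- lapply(seq_along(areas), function(i)
      circle_contour(i, 2 * pi * sqrt(areas[i] / pi)))
    structure(list(contours = cts, levels = seq_along(areas),
                   level_index = seq_along(areas), impression_index = 0L),
              class = "ContourStack")
  }
  st <- trimStackByArea(mk(c(1.0, 1.1, 1.2, 1.3, 5.0)),
                        lower_ratio = 1.5, upper_ratio = 1.3)
  expect_length(st$contours, 4L)
  expect_equal(st$level_index, 1:4)

  # uniform areas: unchanged for any positive threshold
  st2 <- trimStackByArea(mk(rep(2, 7)), 1.01, 1.01)
  expect_length(st2$contours, 7L)

  # a huge roundish bottom contour is cut by the lower threshold
  st3 <- trimStackByArea(mk(c(9.0, 1.0, 1.05, 1.1, 1.15)), 1.5, 1.3)
  expect_equal(st3$level_index, 2:5)
})

test_that("additional impressions are recovered from disjoint pits", {
  fp <- generateFootprint(footprintSpec(kind = "multi",
                                        target_faces = 30000))
  b <- traceOutline(fp$mesh, pipelineConfig(impressions = 3L))
  expect_length(b$extra, 2L)
  ctrs <- rbind(colMeans(b$outline$points[-nrow(b$outline$points), ]),
                t(vapply(b$extra, function(e)
                  colMeans(e$outline$points[-nrow(e$outline$points), ]),
                  numeric(2))))
  # centroid separations match the generator's pit layout (frame-free)
  expect_equal(sort(as.vector(dist(ctrs))),
               sort(as.vector(dist(fp$truth$impression_centers))),
               tolerance = 0.03)
  # stacks are pairwise disjoint in contour membership
  keys <- lapply(c(list(b$stack), lapply(b$extra, `[[`, "stack")),
                 function(s) vapply(s$contours, trackline:::.contour_key, ""))
  expect_equal(anyDuplicated(unlist(keys)), 0L)
  # requesting more impressions than exist warns
  cands <- extractLevelContours(orientMesh(fp$mesh), 30L)
  st <- selectPrimaryStack(cands)
  expect_warning(selectAdditionalStacks(cands, k = 5L, primary = st),
                 "additional impression")
})
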