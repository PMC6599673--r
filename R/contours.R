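# Contour extraction from the oriented cloud and reduction to a clean
# stack representing the footprint wall.

#' Rasterize an oriented cloud onto a regular grid
#'
#' The fitted vertex cloud is interpolated onto a regular x/y grid by
#' barycentric interpolation over the mesh's own triangles (the mesh
#' connectivity is the triangulation of the points, so no re-triangulation
#' is needed). Grid pitch defaults to the median vertex nearest-neighbor
#' spacing, clamped so the grid never exceeds 2000 cells along the
#' bounding-box diagonal. Nodes not covered by any triangle are `NA`.
#'
#' @param cloud an `OrientedCloud` (with faces).
#' @param pitch optional grid pitch in model units; default as above.
#' @return List with `x`, `y` (node coordinates) and `z` (matrix,
#'   `length(x)` by `length(y)`).
#' @export
rasterizeCloud <- function(cloud, pitch = NULL) {
  p <- cloud$points
  if (is.null(pitch)) {
    med <- median_nn_spacing_cpp(p[, 1:2, drop = FALSE])
    diag_len <- sqrt(sum((apply(p[, 1:2], 2, function(v) diff(range(v))))^2))
    pitch <- max(med, diag_len / 2000, .Machine$double.eps)
  }
  # anchor the grid on the cloud centroid so that mirrored or 180-degree
  # rotated clouds are sampled at mirrored node positions
  cx <- mean(range(p[, 1])); cy <- mean(range(p[, 2]))
  x0 <- cx - pitch * floor((cx - min(p[, 1])) / pitch)
  y0 <- cy - pitch * floor((cy - min(p[, 2])) / pitch)
  nx <- floor((max(p[, 1]) - x0) / pitch) + 1L
  ny <- floor((max(p[, 2]) - y0) / pitch) + 1L
  z <- rasterize_mesh_cpp(p, cloud$faces, x0, y0, pitch, nx, ny)
  list(x = x0 + (seq_len(nx) - 1L) * pitch,
       y = y0 + (seq_len(ny) - 1L) * pitch,
       z = z, pitch = pitch)
}

.polygon_area_signed <- function(pts) {
  x <- pts[, 1]; y <- pts[, 2]
  n <- nrow(pts)
  j <- c(n, seq_len(n - 1L))
  sum(x[j] * y - x * y[j]) / 2
}

.polyline_length <- function(pts, closed = TRUE) {
  d <- sqrt(rowSums(diff(pts)^2))
  len <- sum(d)
  if (closed) len <- len + sqrt(sum((pts[1, ] - pts[nrow(pts), ])^2))
  len
}

# A Contour stores its points in "open representation": the closing vertex
# is not duplicated. length and area include the closing segment.
.make_contour <- function(level, xy, is_closed) {
  pts <- cbind(xy$x, xy$y)
  if (is_closed && nrow(pts) > 1L &&
      isTRUE(all.equal(pts[1, ], pts[nrow(pts), ], tolerance = 0,
                       check.attributes = FALSE)))
    pts <- pts[-nrow(pts), , drop = FALSE]
  list(level = level, points = pts, is_closed = is_closed,
       length = .polyline_length(pts, closed = is_closed),
       area = if (is_closed) abs(.polygon_area_signed(pts)) else 0)
}

contourCentroid <- function(contour) colMeans(contour$points)

#' Extract candidate contours at equally spaced height levels
#'
#' Levels are placed strictly inside the z-range of the rasterized cloud:
#' `z_min + i * (z_max - z_min) / (n + 1)` for `i = 1..n`, avoiding empty
#' extreme levels. Each level carries zero or more polylines flagged
#' open/closed (open polylines arise where a contour runs off the model
#' margin).
#'
#' @param cloud an `OrientedCloud`, or a grid from [rasterizeCloud()].
#' @param n_levels number of height levels (default 30).
#' @param pitch optional grid pitch forwarded to [rasterizeCloud()].
#' @return List with `levels` (numeric ladder) and `candidates` (one list
#'   of contours per level).
#' @export
extractLevelContours <- function(cloud, n_levels = 30L, pitch = NULL) {
  grid <- if (inherits(cloud, "OrientedCloud")) {
    rasterizeCloud(cloud, pitch = pitch)
  } else cloud
  zr <- range(grid$z, na.rm = TRUE)
  if (!is.finite(diff(zr)) || diff(zr) <= 0)
    stop("geometry error: cloud has zero z-range, no contours possible")
  levels <- zr[1] + seq_len(n_levels) * diff(zr) / (n_levels + 1)
  raw <- grDevices::contourLines(grid$x, grid$y, grid$z, levels = levels)
  candidates <- vector("list", n_levels)
  for (cl in raw) {
    i <- which.min(abs(levels - cl$level))
    n <- length(cl$x)
    closed <- n > 3L && cl$x[1] == cl$x[n] && cl$y[1] == cl$y[n]
    candidates[[i]] <- c(candidates[[i]],
                         list(.make_contour(levels[i], cl, closed)))
  }
  list(levels = levels, candidates = candidates, pitch = grid$pitch)
}

# longest closed contour of a level; ties broken by larger area, then by
# smaller centroid distance to `center`
.pick_longest <- function(contours, center) {
  if (length(contours) == 0L) return(NULL)
  lens <- vapply(contours, `[[`, 0, "length")
  best <- which(lens == max(lens))
  if (length(best) > 1L) {
    areas <- vapply(contours[best], `[[`, 0, "area")
    best <- best[areas == max(areas)]
    if (length(best) > 1L) {
      d <- vapply(contours[best], function(ct)
        sum((contourCentroid(ct) - center)^2), 0)
      best <- best[which.min(d)]
    }
  }
  contours[[best[1]]]
}

#' Select the primary contour stack
#'
#' Applies the three selection rules: open contours are discarded; only the
#' longest closed contour of each level is kept; contours shorter than
#' `min_length_frac` of the longest retained contour are removed, but only
#' from the ends of the level ladder so that no internal gaps arise.
#'
#' @param candidates output of [extractLevelContours()].
#' @param min_length_frac length threshold as a fraction of the longest
#'   contour (default 0.5).
#' @param exclude list of contours already used by other stacks (matched by
#'   level and identical point coordinates).
#' @param impression_index recorded on the stack (0 = primary).
#' @return A `ContourStack`: list with `contours` (ascending level),
#'   `levels` (the full ladder), `level_index` (which ladder rungs are
#'   retained), `impression_index`.
#' @export
selectPrimaryStack <- function(candidates, min_length_frac = 0.5,
                               exclude = list(), impression_index = 0L) {
  ladder <- candidates$levels
  sets <- candidates$candidates
  if (length(exclude)) {
    used_keys <- vapply(exclude, .contour_key, "")
    sets <- lapply(sets, function(cs)
      Filter(function(ct) !(.contour_key(ct) %in% used_keys), cs))
  }
  center <- {
    allpts <- do.call(rbind, lapply(unlist(sets, recursive = FALSE),
                                    `[[`, "points"))
    if (is.null(allpts)) c(0, 0) else colMeans(allpts)
  }
  per_level <- lapply(sets, function(cs)
    .pick_longest(Filter(function(ct) isTRUE(ct$is_closed), cs), center))
  have <- !vapply(per_level, is.null, TRUE)
  if (!any(have))
    stop("no footprint found: no closed contour on any height level")
  # contiguous runs of levels that carry a closed contour; keep the run
  # containing the globally longest contour
  runs <- rle(have)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  lens_all <- ifelse(have, vapply(per_level, function(ct)
    if (is.null(ct)) 0 else ct$length, 0), 0)
  runs_idx <- which(runs$values)
  best_run <- runs_idx[which.max(vapply(runs_idx, function(r)
    max(lens_all[starts[r]:ends[r]]), 0))]
  lo <- starts[best_run]; hi <- ends[best_run]
  lens <- lens_all[lo:hi]
  lmax <- max(lens)
  keep_lo <- 1L; keep_hi <- length(lens)
  while (keep_lo < keep_hi && lens[keep_lo] < min_length_frac * lmax)
    keep_lo <- keep_lo + 1L
  while (keep_hi > keep_lo && lens[keep_hi] < min_length_frac * lmax)
    keep_hi <- keep_hi - 1L
  idx <- (lo:hi)[keep_lo:keep_hi]
  structure(
    list(contours = per_level[idx], levels = ladder, level_index = idx,
         impression_index = impression_index),
    class = "ContourStack")
}

.contour_key <- function(ct) {
  ctr <- colMeans(ct$points)
  paste(format(ct$level, digits = 15), nrow(ct$points),
        format(ct$length, digits = 15), format(ct$area, digits = 15),
        format(ctr[1], digits = 15), format(ctr[2], digits = 15),
        sep = "|")
}

#' @export
print.ContourStack <- function(x, ...) {
  cat("ContourStack:", length(x$contours), "contours on levels",
      sprintf("[%g, %g]", x$levels[x$level_index[1]],
              x$levels[x$level_index[length(x$level_index)]]),
      "(impression", paste0(x$impression_index, ")"), "\n")
  invisible(x)
}

#' Trim a contour stack by area jumps
#'
#' Starting from the middle contour, neighbor pairs are scanned outward
#' toward the bottom and (separately) toward the top; the first pair whose
#' enclosed areas differ by more than the applicable ratio truncates the
#' stack there. The ratio rule (larger area / smaller area) makes the
#' thresholds scale-free; the lower and upper halves use their own
#' thresholds. This removes roundish overall-depression contours far larger
#' than the wall contours and limits the height range under consideration.
#'
#' @param stack a `ContourStack`.
#' @param lower_ratio area-jump threshold toward the bottom (default 1.5).
#' @param upper_ratio area-jump threshold toward the top (default 1.3).
#' @return The trimmed `ContourStack`.
#' @export
trimStackByArea <- function(stack, lower_ratio = 1.5, upper_ratio = 1.3) {
  k <- length(stack$contours)
  if (k <= 1L) return(stack)
  areas <- vapply(stack$contours, `[[`, 0, "area")
  mid <- ceiling(k / 2)
  jump <- function(a, b, thr) {
    lo <- min(a, b); hi <- max(a, b)
    if (lo <= 0) hi > 0 else hi / lo > thr
  }
  lo_keep <- 1L
  if (mid >= 2L) {
    for (i in seq(mid, 2L)) {
      if (jump(areas[i], areas[i - 1L], lower_ratio)) { lo_keep <- i; break }
    }
  }
  hi_keep <- k
  if (mid < k) {
    for (i in seq(mid, k - 1L)) {
      if (jump(areas[i], areas[i + 1L], upper_ratio)) { hi_keep <- i; break }
    }
  }
  stack$contours <- stack$contours[lo_keep:hi_keep]
  stack$level_index <- stack$level_index[lo_keep:hi_keep]
  stack
}

#' Select stacks for additional impressions
#'
#' Re-runs the stack selection with the contours of all previously selected
#' stacks excluded, once per requested additional impression. Useful for
#' shallow footprints composed of several separate impressions (e.g., three
#' separate digit pads).
#'
#' @param candidates output of [extractLevelContours()].
#' @param k number of additional impressions requested.
#' @param primary the already selected primary `ContourStack` (and any other
#'   stacks to exclude), a single stack or a list of stacks.
#' @param min_length_frac,lower_ratio,upper_ratio as for the primary stack.
#' @return List of up to `k` further `ContourStack`s; a warning is issued
#'   if fewer impressions exist.
#' @export
selectAdditionalStacks <- function(candidates, k, primary,
                                   min_length_frac = 0.5,
                                   lower_ratio = 1.5, upper_ratio = 1.3) {
  if (k < 1L) return(list())
  stacks <- if (inherits(primary, "ContourStack")) list(primary) else primary
  used <- unlist(lapply(stacks, `[[`, "contours"), recursive = FALSE)
  out <- list()
  for (i in seq_len(k)) {
    st <- tryCatch(
      selectPrimaryStack(candidates, min_length_frac = min_length_frac,
                         exclude = used, impression_index = length(out) + 1L),
      error = function(e) NULL)
    if (is.null(st)) break
    used <- c(used, st$contours)  # exclude pre-trim membership
    st <- trimStackByArea(st, lower_ratio, upper_ratio)
    out <- c(out, list(st))
  }
  if (length(out) < k)
    warning("only ", length(out), " additional impression(s) found of ",
            k, " requested")
  out
}
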