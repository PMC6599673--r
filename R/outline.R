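# Tracing of the outline along the steepest slope of the track wall, and
# its smoothing by elliptic Fourier approximation.

#' Steepness profile of one homologous column
#'
#' For the homologous point at column `j` of each level, steepness is the
#' level spacing divided by the minimal planar distance from that point to
#' any point on the adjacent level(s) within `window` columns on either
#' side (homologous point sets are not always perpendicular to the wall, so
#' nearby points outside the set are considered too). Top and bottom levels
#' use their single neighbor. Weights are `(s_i / s_max)^exponent`,
#' normalized to sum 1, so equal steepness yields equal weight.
#'
#' @param hstack a `HomologizedStack` with at least 2 contours.
#' @param j column index (1..n).
#' @param window neighbor half-width in columns (default 5; 0 restricts to
#'   within-column distances).
#' @param exponent weighting exponent (default 2).
#' @return List with `level`, `point` (per-level x/y), `steepness`,
#'   `weights`.
#' @export
steepnessColumn <- function(hstack, j, window = 5L, exponent = 2) {
  k <- length(hstack$contours)
  stopifnot(k >= 2L, j >= 1L, j <= hstack$n)
  n <- hstack$n
  lv <- hstack$levels
  dz <- if (k > 1) mean(abs(diff(lv))) else 1
  cols <- ((j - 1L + seq(-window, window)) %% n) + 1L
  dmin_to <- function(p, ci) {
    q <- hstack$contours[[ci]][cols, , drop = FALSE]
    sqrt(min((q[, 1] - p[1])^2 + (q[, 2] - p[2])^2))
  }
  s <- numeric(k)
  for (i in seq_len(k)) {
    p <- hstack$contours[[i]][j, ]
    d <- Inf
    if (i > 1L) d <- min(d, dmin_to(p, i - 1L))
    if (i < k) d <- min(d, dmin_to(p, i + 1L))
    s[i] <- if (d > 0) dz / d else Inf
  }
  if (any(!is.finite(s))) s <- ifelse(is.finite(s), 0, 1)
  smax <- max(s)
  w <- if (smax > 0) (s / smax)^exponent else rep(1, k)
  w <- w / sum(w)
  pts <- t(vapply(seq_len(k), function(i) hstack$contours[[i]][j, ],
                  numeric(2)))
  list(level = lv, point = pts, steepness = s, weights = w, column_index = j)
}

#' Weighted wall point of a steepness column
#'
#' @param col output of [steepnessColumn()].
#' @return The weighted arithmetic mean (x, y) of the per-level points. If
#'   all steepness values are zero, the unweighted mean is returned with a
#'   warning.
#' @export
weightedWallPoint <- function(col) {
  if (all(col$steepness == 0)) {
    warning("all steepness values zero; returning unweighted mean")
    return(colMeans(col$point))
  }
  c(sum(col$weights * col$point[, 1]), sum(col$weights * col$point[, 2]))
}

#' Trace the raw steepest-slope outline
#'
#' One weighted wall point per homologous column, in column order; the
#' sequence is closed by repeating the first point.
#'
#' @param hstack a `HomologizedStack`.
#' @param window,exponent see [steepnessColumn()].
#' @return A closed `(n + 1) x 2` matrix of outline points.
#' @export
traceRawOutline <- function(hstack, window = 5L, exponent = 2) {
  k <- length(hstack$contours)
  n <- hstack$n
  lv <- hstack$levels
  dz <- if (k > 1) mean(abs(diff(lv))) else 1
  # vectorized over columns: distance from level i to level i2 within the
  # column window
  P <- lapply(hstack$contours, identity)
  mind <- function(i, i2) {
    a <- P[[i]]; b <- P[[i2]]
    d2 <- matrix(Inf, n, 1)
    for (off in -window:window) {
      idx <- ((seq_len(n) - 1L + off) %% n) + 1L
      d2 <- pmin(d2, (a[, 1] - b[idx, 1])^2 + (a[, 2] - b[idx, 2])^2)
    }
    sqrt(d2)
  }
  S <- matrix(0, k, n)
  for (i in seq_len(k)) {
    d <- rep(Inf, n)
    if (i > 1L) d <- pmin(d, mind(i, i - 1L))
    if (i < k) d <- pmin(d, mind(i, i + 1L))
    S[i, ] <- ifelse(d > 0, dz / d, Inf)
  }
  S[!is.finite(S)] <- 0
  smax <- apply(S, 2, max)
  W <- sweep(S, 2, ifelse(smax > 0, smax, 1), "/")^2
  if (!identical(exponent, 2)) {
    W <- sweep(S, 2, ifelse(smax > 0, smax, 1), "/")^exponent
  }
  W[, smax == 0] <- 1
  W <- sweep(W, 2, colSums(W), "/")
  X <- vapply(P, function(p) p[, 1], numeric(n))  # n x k
  Y <- vapply(P, function(p) p[, 2], numeric(n))
  out <- cbind(rowSums(t(W) * X), rowSums(t(W) * Y))
  rbind(out, out[1, ])
}

# --- elliptic Fourier machinery (Kuhl-Giardina formulation) -------------

# Coefficients for a closed polygon given in open representation. The
# curve is parameterized uniformly per vertex (dt = 1): input points come
# one per homologous column at near-equal spacing, and under the uniform
# parameterization the fit reproduces an ellipse sampled at uniform
# parameter exactly, a convenient correctness oracle.
.efa_coef <- function(pts, harmonics) {
  d <- diff(rbind(pts, pts[1, , drop = FALSE]))
  dt <- rep(1, nrow(d))
  t <- c(0, cumsum(dt))
  T <- t[length(t)]
  t1 <- t[-length(t)]; t2 <- t[-1]
  an <- bn <- cn <- dn <- numeric(harmonics)
  for (h in seq_len(harmonics)) {
    w <- 2 * pi * h / T
    cosd <- cos(w * t2) - cos(w * t1)
    sind <- sin(w * t2) - sin(w * t1)
    an[h] <- sum(d[, 1] / dt * cosd) / (w^2 * T / 2)
    bn[h] <- sum(d[, 1] / dt * sind) / (w^2 * T / 2)
    cn[h] <- sum(d[, 2] / dt * cosd) / (w^2 * T / 2)
    dn[h] <- sum(d[, 2] / dt * sind) / (w^2 * T / 2)
  }
  # DC terms (mean of the piecewise-linear curve over one period)
  delta <- function(dcol) {
    cs <- c(0, cumsum(dcol)[-length(dcol)])
    cs - dcol / dt * t1
  }
  a0 <- sum(d[, 1] / (2 * dt) * (t2^2 - t1^2) + delta(d[, 1]) * dt) / T
  c0 <- sum(d[, 2] / (2 * dt) * (t2^2 - t1^2) + delta(d[, 2]) * dt) / T
  list(an = an, bn = bn, cn = cn, dn = dn,
       a0 = pts[1, 1] + a0, c0 = pts[1, 2] + c0, T = T)
}

.efa_eval <- function(coef, n_out) {
  t <- seq(0, coef$T, length.out = n_out + 1L)[-(n_out + 1L)]
  x <- rep(coef$a0, n_out); y <- rep(coef$c0, n_out)
  for (h in seq_along(coef$an)) {
    w <- 2 * pi * h / coef$T
    x <- x + coef$an[h] * cos(w * t) + coef$bn[h] * sin(w * t)
    y <- y + coef$cn[h] * cos(w * t) + coef$dn[h] * sin(w * t)
  }
  cbind(x, y)
}

# cyclic (1,2,1)/4 neighbor averaging, the conventional pre-smoothing in
# elliptic Fourier outline practice
.smooth_closed <- function(pts, iterations) {
  n <- nrow(pts)
  if (iterations < 1L || n < 3L) return(pts)
  for (it in seq_len(iterations)) {
    prev <- pts[c(n, seq_len(n - 1L)), , drop = FALSE]
    nxt <- pts[c(seq(2L, n), 1L), , drop = FALSE]
    pts <- (prev + 2 * pts + nxt) / 4
  }
  pts
}

#' Smooth a closed outline by elliptic Fourier approximation
#'
#' Applies `smoothing_iterations` passes of cyclic (1,2,1)/4 neighbor
#' averaging, fits an elliptic Fourier series with the requested number of
#' harmonics, and evaluates it at the input point count. Scale is
#' preserved: coefficients are never normalized.
#'
#' @param points closed point sequence (first = last) or open
#'   representation; a two-column matrix.
#' @param harmonics number of harmonics (default 25).
#' @param smoothing_iterations neighbor-averaging passes (default 10).
#' @return An `Outline`: list with closed `points`, `harmonics`,
#'   `smoothing_iterations`, `upright_angle` (NA until rotated),
#'   `centroid`.
#' @export
ellipticFourierSmooth <- function(points, harmonics = 25L,
                                  smoothing_iterations = 10L) {
  pts <- as.matrix(points)
  n <- nrow(pts)
  if (n > 1L && isTRUE(all.equal(pts[1, ], pts[n, ], tolerance = 0,
                                 check.attributes = FALSE)))
    pts <- pts[-n, , drop = FALSE]
  if (nrow(pts) < 2L * harmonics + 1L)
    stop("contract error: need at least 2*harmonics + 1 points")
  pts <- .smooth_closed(pts, smoothing_iterations)
  coef <- .efa_coef(pts, harmonics)
  rec <- .efa_eval(coef, nrow(pts))
  structure(
    list(points = rbind(rec, rec[1, ]), harmonics = as.integer(harmonics),
         smoothing_iterations = as.integer(smoothing_iterations),
         upright_angle = NA_real_, centroid = colMeans(rec),
         efa = coef),
    class = "Outline")
}

#' @export
print.Outline <- function(x, ...) {
  cat("Outline:", nrow(x$points) - 1L, "points;",
      x$harmonics, "harmonics,", x$smoothing_iterations,
      "smoothing iterations")
  if (!is.na(x$upright_angle))
    cat("; upright rotation", x$upright_angle, "deg")
  cat("\n")
  invisible(x)
}

.outline_pts_open <- function(outline) {
  p <- outline$points
  n <- nrow(p)
  if (isTRUE(all.equal(p[1, ], p[n, ], tolerance = 0,
                       check.attributes = FALSE)))
    p[-n, , drop = FALSE] else p
}

.rot2 <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
}

#' Rotate an outline upright
#'
#' Digit impressions need more outline length to describe than the heel, so
#' the upright orientation is the integer-degree rotation (1-360) about the
#' centroid that maximizes the arc length of the outline above the
#' centroid. The length above the centroid is measured on a 720-point
#' equidistant resampling as the summed length of segments whose midpoints
#' lie above centroid level; ties pick the smallest angle.
#'
#' @param outline an `Outline` (or closed point matrix).
#' @return The rotated `Outline` with `upright_angle` recorded in degrees.
#' @export
rotateUpright <- function(outline) {
  is_obj <- inherits(outline, "Outline")
  pts <- if (is_obj) .outline_pts_open(outline) else {
    p <- as.matrix(outline)
    if (isTRUE(all.equal(p[1, ], p[nrow(p), ], check.attributes = FALSE)))
      p[-nrow(p), , drop = FALSE] else p
  }
  ctr <- colMeans(pts)
  rs <- .resample_closed(pts, 720L)
  cen <- sweep(rs, 2, ctr)
  ring <- rbind(cen, cen[1, ])
  seg_len <- sqrt(rowSums(diff(ring)^2))
  mid <- (ring[-721, , drop = FALSE] + ring[-1, , drop = FALSE]) / 2
  # midpoint above centroid after rotation by a degrees: rotated y =
  # x*sin(a) + y*cos(a) > 0
  ang <- (1:360) * pi / 180
  above <- outer(mid[, 1], sin(ang)) + outer(mid[, 2], cos(ang)) > 0
  len_above <- colSums(seg_len * above)
  best <- which.max(len_above)  # ties: smallest angle
  R <- .rot2(best)
  rot <- sweep(pts, 2, ctr) %*% t(R)
  rot <- sweep(rot, 2, -ctr)
  if (is_obj) {
    outline$points <- rbind(rot, rot[1, ])
    outline$upright_angle <- as.numeric(best)
    outline$centroid <- colMeans(rot)
    outline
  } else {
    structure(list(points = rbind(rot, rot[1, ]), harmonics = NA_integer_,
                   smoothing_iterations = NA_integer_,
                   upright_angle = as.numeric(best), centroid = colMeans(rot)),
              class = "Outline")
  }
}
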