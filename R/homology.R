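# Point-to-point correspondence across the contour stack: equidistant
# resampling, uniform traversal direction, bottleneck detection between the
# innermost and outermost contour, and section-wise resampling.

# Resample a closed polyline (open representation, no duplicated closing
# vertex) to n points at equal arc-length spacing, starting at point 1.
.resample_closed <- function(pts, n) {
  m <- nrow(pts)
  if (m < 3L) stop("geometry error: contour has fewer than 3 points")
  ring <- rbind(pts, pts[1, , drop = FALSE])
  seg <- sqrt(rowSums(diff(ring)^2))
  total <- sum(seg)
  if (total <= 0) stop("geometry error: zero-length contour")
  s <- c(0, cumsum(seg))
  t <- (seq_len(n) - 1L) * total / n
  cbind(stats::approx(s, ring[, 1], xout = t, ties = "ordered")$y,
        stats::approx(s, ring[, 2], xout = t, ties = "ordered")$y)
}

# Resample an open polyline to m points including both endpoints.
.resample_open <- function(pts, m) {
  seg <- sqrt(rowSums(diff(pts)^2))
  total <- sum(seg)
  if (total <= 0) return(matrix(rep(pts[1, ], m), ncol = 2, byrow = TRUE))
  s <- c(0, cumsum(seg))
  t <- seq(0, total, length.out = m)
  cbind(stats::approx(s, pts[, 1], xout = t, ties = "ordered")$y,
        stats::approx(s, pts[, 2], xout = t, ties = "ordered")$y)
}

#' Resample a contour to equidistant points
#'
#' @param contour a `Contour` (as stored in a `ContourStack`) or a plain
#'   two-column matrix interpreted as a closed polyline.
#' @param n number of points (default 500).
#' @return Same type as the input, with `n` points at equal arc-length
#'   spacing starting at the original start point.
#' @export
resampleEquidistant <- function(contour, n = 500L) {
  if (is.matrix(contour)) return(.resample_closed(contour, n))
  pts <- .resample_closed(contour$points, n)
  contour$points <- pts
  contour$length <- .polyline_length(pts, closed = TRUE)
  contour$area <- abs(.polygon_area_signed(pts))
  contour
}

#' Unify traversal direction across a stack
#'
#' All contours are made counter-clockwise (positive signed area); reversal
#' preserves the start point and the point set.
#'
#' @param contours list of two-column point matrices.
#' @return The list with uniform orientation.
#' @export
unifyDirection <- function(contours) {
  lapply(contours, function(p) {
    if (.polygon_area_signed(p) < 0) {
      n <- nrow(p)
      p[c(1L, n:2L), , drop = FALSE]
    } else p
  })
}

.circ_dist <- function(i, j, n) {
  d <- abs(i - j) %% n
  pmin(d, n - d)
}

#' Find a bottleneck between the innermost and outermost contour
#'
#' Euclidean distances between all inner/outer point pairs form an
#' `n_in x n_out` matrix; the minimal pair (outer index outside
#' `excluded_outer`) is the bottleneck. Ties are broken toward the smallest
#' outer index, then the smallest inner index.
#'
#' @param inner,outer two-column point matrices.
#' @param excluded_outer integer vector of outer indices that may not carry
#'   the bottleneck.
#' @return List with `inner_index`, `outer_index`, `gap`.
#' @export
findBottleneck <- function(inner, outer, excluded_outer = integer()) {
  n_in <- nrow(inner); n_out <- nrow(outer)
  allowed <- setdiff(seq_len(n_out), excluded_outer)
  if (length(allowed) == 0L)
    stop("contract error: all outer indices excluded from bottleneck search")
  d2 <- matrix(rowSums(inner^2), n_in, length(allowed)) +
    matrix(rowSums(outer[allowed, , drop = FALSE]^2), n_in, length(allowed),
           byrow = TRUE) -
    2 * inner %*% t(outer[allowed, , drop = FALSE])
  m <- min(d2)
  hits <- which(d2 == m, arr.ind = TRUE)
  hits <- hits[order(allowed[hits[, 2]], hits[, 1]), , drop = FALSE]
  list(inner_index = unname(hits[1, 1]),
       outer_index = allowed[hits[1, 2]],
       gap = sqrt(max(0, m)))
}

# index on `pts` of the point closest to the segment a--b (the bottleneck
# chord); the segment, not the infinite line, avoids picking up antipodal
# points on elongate contours
.closest_to_segment <- function(pts, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 == 0) {
    return(which.min((pts[, 1] - a[1])^2 + (pts[, 2] - a[2])^2))
  }
  t <- ((pts[, 1] - a[1]) * ab[1] + (pts[, 2] - a[2]) * ab[2]) / len2
  t <- pmin(1, pmax(0, t))
  qx <- a[1] + t * ab[1]; qy <- a[2] + t * ab[2]
  which.min((pts[, 1] - qx)^2 + (pts[, 2] - qy)^2)
}

# rotate the point order of a closed contour so index `k` becomes index 1
.rotate_start <- function(pts, k) {
  n <- nrow(pts)
  if (k == 1L) return(pts)
  pts[c(k:n, 1L:(k - 1L)), , drop = FALSE]
}

#' Homologize a contour stack
#'
#' Establishes point homology across the stack. All contours are resampled
#' to `n` equidistant points and oriented uniformly. The first bottleneck
#' (global minimum-distance pair between the innermost and outermost
#' contour) defines the common start point; a second bottleneck is sought
#' on the opposite side (outer index within n/8 of half a turn away), then
#' two more on each side between them; further bottlenecks are inserted
#' while any inter-bottleneck section is longer than twice the mean section
#' arc (up to 3 refinement rounds). Bottlenecks closer than n/16 to an
#' accepted one are prevented. Finally the sections between consecutive
#' bottlenecks are resampled to matched equidistant point counts on every
#' contour, restoring `n` points in total.
#'
#' @param stack a `ContourStack` (at least 2 contours for a meaningful
#'   homology; with fewer, the single contour is passed through with a
#'   trivial identity homology and a warning).
#' @param n points per contour (default 500).
#' @return A `HomologizedStack`: list with `contours` (list of `n x 2`
#'   matrices, innermost first), `levels`, `bottleneck_index` (shared
#'   point indices of the bottlenecks), `section_sizes`, `n`.
#' @export
homologizeStack <- function(stack, n = 500L) {
  levels <- vapply(stack$contours, `[[`, 0, "level")
  pts <- lapply(stack$contours, function(ct) .resample_closed(ct$points, n))
  pts <- unifyDirection(pts)
  k <- length(pts)
  if (k < 2L) {
    warning("stack has fewer than 2 contours; trivial homology")
    return(structure(list(contours = pts, levels = levels,
                          bottleneck_index = 1L, section_sizes = n, n = n),
                     class = "HomologizedStack"))
  }
  inner <- pts[[1L]]; outer <- pts[[k]]

  homolog_row <- function(b) {
    # per-contour homologous indices for a bottleneck
    a <- inner[b$inner_index, ]; bb <- outer[b$outer_index, ]
    vapply(seq_len(k), function(ci) {
      if (ci == 1L) b$inner_index
      else if (ci == k) b$outer_index
      else .closest_to_segment(pts[[ci]], a, bb)
    }, 1L)
  }

  b1 <- findBottleneck(inner, outer)
  row1 <- homolog_row(b1)
  pts <- Map(.rotate_start, pts, as.list(row1))
  inner <- pts[[1L]]; outer <- pts[[k]]

  prox <- max(1L, floor(n / 16))
  excl_near <- function(centers) {
    idx <- unlist(lapply(centers, function(cc)
      which(.circ_dist(seq_len(n), cc, n) <= prox)))
    unique(idx)
  }

  accepted <- 1L  # outer indices of accepted bottlenecks (b1 now at 1)
  rows <- list(rep(1L, k))

  # opposite side: outer index within +/- n/8 of half a turn from b1
  opp_center <- 1L + round(n / 2)
  win <- max(1L, floor(n / 8))
  opp_window <- which(.circ_dist(seq_len(n), opp_center, n) <= win)
  allowed2 <- setdiff(opp_window, excl_near(accepted))
  b2 <- findBottleneck(inner, outer,
                       excluded_outer = setdiff(seq_len(n), allowed2))
  accepted <- c(accepted, b2$outer_index)
  rows <- c(rows, list(homolog_row(b2)))

  # two more bottlenecks on each side between b1 and b2
  side1 <- if (b2$outer_index >= 3L) seq(2L, b2$outer_index - 1L) else integer()
  side2 <- setdiff(seq_len(n), c(seq_len(b2$outer_index), 1L))
  for (side in list(side1, side2)) {
    for (rep_i in 1:2) {
      allowed <- setdiff(side, excl_near(accepted))
      if (length(allowed) == 0L) break
      b <- findBottleneck(inner, outer,
                          excluded_outer = setdiff(seq_len(n), allowed))
      accepted <- c(accepted, b$outer_index)
      rows <- c(rows, list(homolog_row(b)))
    }
  }

  # refine: subdivide sections longer than twice the mean section arc
  for (depth in 1:3) {
    ord <- order(accepted)
    acc <- accepted[ord]
    gaps <- diff(c(acc, acc[1] + n))  # outer contour is equidistant
    long <- which(gaps > 2 * mean(gaps))
    added <- FALSE
    for (s in long) {
      span <- seq(acc[s] + 1L, acc[s] + gaps[s] - 1L)
      span <- ((span - 1L) %% n) + 1L
      allowed <- setdiff(span, excl_near(accepted))
      if (length(allowed) == 0L) next
      b <- findBottleneck(inner, outer,
                          excluded_outer = setdiff(seq_len(n), allowed))
      accepted <- c(accepted, b$outer_index)
      rows <- c(rows, list(homolog_row(b)))
      added <- TRUE
    }
    if (!added) break
  }

  ord <- order(accepted)
  acc <- accepted[ord]
  rows <- rows[ord]
  nb <- length(acc)
  idx_mat <- do.call(rbind, rows)  # nb x k homologous indices

  # enforce cyclically increasing per-contour bottleneck indices
  for (ci in seq_len(k)) {
    v <- idx_mat[, ci]
    v[1] <- 1L
    for (j in 2:nb) {
      lo <- v[j - 1L] + 1L
      hi <- n - (nb - j)  # leave room for the remaining bottlenecks
      v[j] <- min(max(v[j], lo), hi)
    }
    idx_mat[, ci] <- v
  }

  # allocate section point counts proportionally to the outer arc
  gaps <- diff(c(acc, acc[1] + n))
  m_s <- pmax(1L, round(n * gaps / sum(gaps)))
  while (sum(m_s) != n) {
    if (sum(m_s) > n) {
      j <- which.max(m_s); m_s[j] <- m_s[j] - 1L
    } else {
      j <- which.max(gaps / m_s); m_s[j] <- m_s[j] + 1L
    }
  }

  out <- vector("list", k)
  for (ci in seq_len(k)) {
    p <- pts[[ci]]
    secs <- vector("list", nb)
    for (s in seq_len(nb)) {
      i0 <- idx_mat[s, ci]
      i1 <- if (s < nb) idx_mat[s + 1L, ci] else idx_mat[1L, ci] + n
      span <- ((seq(i0, i1) - 1L) %% n) + 1L
      rs <- .resample_open(p[span, , drop = FALSE], m_s[s] + 1L)
      secs[[s]] <- rs[seq_len(m_s[s]), , drop = FALSE]
    }
    out[[ci]] <- do.call(rbind, secs)
  }
  structure(
    list(contours = out, levels = levels,
         bottleneck_index = cumsum(c(1L, m_s[-nb])),
         section_sizes = m_s, n = n),
    class = "HomologizedStack")
}

#' @export
print.HomologizedStack <- function(x, ...) {
  cat("HomologizedStack:", length(x$contours), "contours x", x$n, "points;",
      length(x$bottleneck_index), "bottlenecks\n")
  invisible(x)
}
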