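# shared fixtures and alignment helpers

# closed-curve resampling shortcut (open representation in, open out)
resample_ring <- function(pts, n) trackline:::.resample_closed(pts, n)

# mean point distance between two closed outlines after removing
# translation, rotation (no scale), traversal direction and start index
outline_mean_dist <- function(a, b, n = 360L) {
  a <- resample_ring(a, n); b <- resample_ring(b, n)
  a <- sweep(a, 2, colMeans(a)); b <- sweep(b, 2, colMeans(b))
  kabsch <- function(p, q) {
    s <- svd(crossprod(p, q))
    R <- s$u %*% t(s$v)
    if (det(R) < 0) {
      u <- s$u; u[, 2] <- -u[, 2]; R <- u %*% t(s$v)
    }
    R
  }
  best <- Inf
  for (dir in 1:2) {
    bb <- if (dir == 1) b else b[c(1L, n:2L), , drop = FALSE]
    for (sh in seq(0L, n - 1L, by = 4L)) {
      idx <- ((seq_len(n) + sh - 1L) %% n) + 1L
      bs <- bb[idx, , drop = FALSE]
      d <- mean(sqrt(rowSums((a %*% kabsch(a, bs) - bs)^2)))
      best <- min(best, d)
    }
  }
  best
}

# mean distance from each point of P to the polygon `poly` (dense curve)
mean_dist_to_curve <- function(P, poly) {
  mean(vapply(seq_len(nrow(P)), function(i)
    min(sqrt((poly[, 1] - P[i, 1])^2 + (poly[, 2] - P[i, 2])^2)), 0))
}

max_dist_to_curve <- function(P, poly) {
  max(vapply(seq_len(nrow(P)), function(i)
    min(sqrt((poly[, 1] - P[i, 1])^2 + (poly[, 2] - P[i, 2])^2)), 0))
}

# an Outline object built directly from the generator's analytic truth
# curve (bypasses meshing/contouring; used to unit-test the landmark rules)
truth_outline <- function(fp, n = 1000L) {
  poly <- resample_ring(fp$truth$outline, n)
  structure(
    list(points = rbind(poly, poly[1, ]), harmonics = NA_integer_,
         smoothing_iterations = NA_integer_, upright_angle = NA_real_,
         centroid = colMeans(poly)),
    class = "Outline")
}

# translation aligning the pipeline outline frame to the truth frame via
# dense centroids (valid when both are upright)
truth_shift <- function(outline_pts, truth_poly) {
  colMeans(resample_ring(outline_pts, 2000L)) -
    colMeans(resample_ring(truth_poly, 2000L))
}

# blobby closed test polygon with fixed wiggles
blob_polygon <- function(n = 200L, seed_phase = 1) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  r <- 1 + 0.25 * cos(3 * th + seed_phase) + 0.1 * sin(5 * th + 2 * seed_phase)
  cbind(r * cos(th), r * sin(th))
}

default_length <- 0.3
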