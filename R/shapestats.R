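# Generalized Procrustes Analysis of outlines or landmark sets, mean
# shape, and per-landmark variability along the mid-axis.

# optimal proper rotation of a (centered) onto b (centered)
.opa_rotation <- function(a, b) {
  s <- svd(crossprod(a, b))
  R <- s$u %*% t(s$v)
  if (det(R) < 0) {
    u <- s$u
    u[, ncol(u)] <- -u[, ncol(u)]
    R <- u %*% t(s$v)
  }
  R
}

#' Generalized Procrustes alignment
#'
#' Iterative superposition of point configurations: each shape is
#' translated to the origin, scaled to unit centroid size, and rotated
#' (proper rotations only) to the running consensus until the consensus
#' changes by less than `tol` (root-mean-square). Points must be
#' homologous across shapes and counts equal.
#'
#' @param shapes list of at least two `k x 2` matrices.
#' @param tol convergence tolerance on the consensus (default 1e-10).
#' @return An `AlignedSample`: list with `shapes` (input), `aligned`
#'   (post-GPA coordinates), `mean_shape` (consensus, the coordinate-wise
#'   average of the aligned shapes), `centroid_sizes`.
#' @export
gpaAlign <- function(shapes, tol = 1e-10) {
  if (!is.list(shapes) || length(shapes) < 2L)
    stop("contract error: GPA needs at least 2 shapes")
  shapes <- lapply(shapes, function(s) {
    m <- as.matrix(unclass(s))[, 1:2, drop = FALSE]
    storage.mode(m) <- "double"
    m
  })
  ks <- vapply(shapes, nrow, 1L)
  if (length(unique(ks)) != 1L)
    stop("contract error: shapes must share one point count")
  cs <- vapply(shapes, function(s) {
    cen <- sweep(s, 2, colMeans(s))
    sqrt(sum(cen^2))
  }, 0)
  aligned <- lapply(shapes, function(s) {
    cen <- sweep(s, 2, colMeans(s))
    cen / sqrt(sum(cen^2))
  })
  consensus <- aligned[[1]]
  for (it in 1:200) {
    aligned <- lapply(aligned, function(s) s %*% .opa_rotation(s, consensus))
    new_cons <- Reduce(`+`, aligned) / length(aligned)
    # keep the consensus at unit centroid size for a stable fixed point
    new_cons <- new_cons / sqrt(sum(sweep(new_cons, 2,
                                          colMeans(new_cons))^2))
    delta <- sqrt(mean((new_cons - consensus)^2))
    consensus <- new_cons
    if (delta < tol) break
  }
  mean_shape <- Reduce(`+`, aligned) / length(aligned)
  # canonical orientation so results do not depend on input order: the
  # consensus' principal (long) axis — the footprint mid-axis — along y,
  # sign fixed by coordinate skewness
  ev <- eigen(stats::cov(mean_shape), symmetric = TRUE)$vectors
  R <- ev[, c(2, 1)]
  if (det(R) < 0) R[, 1] <- -R[, 1]
  rot_all <- function(R) {
    mean_shape <<- mean_shape %*% R
    aligned <<- lapply(aligned, function(s) s %*% R)
  }
  rot_all(R)
  sk <- colSums(mean_shape^3)
  flip_axis <- if (abs(sk[2]) >= abs(sk[1])) 2L else 1L
  if (sk[flip_axis] < 0) rot_all(-diag(2))  # proper 180-degree rotation
  structure(
    list(shapes = shapes, aligned = aligned, mean_shape = mean_shape,
         centroid_sizes = cs),
    class = "AlignedSample")
}

#' @export
print.AlignedSample <- function(x, ...) {
  cat("AlignedSample:", length(x$aligned), "shapes x",
      nrow(x$mean_shape), "points (GPA-aligned)\n")
  invisible(x)
}

#' Per-landmark variability along the mid-axis
#'
#' For each landmark, the dispersion of the aligned y-coordinates (parallel
#' to the footprint mid-axis) across the sample.
#'
#' @param aligned an `AlignedSample` from [gpaAlign()], or a list of
#'   aligned `k x 2` matrices.
#' @param stat `"sd"` (default) or `"var"`.
#' @return Named numeric vector of dispersions, one per landmark row.
#' @export
landmarkVariabilityY <- function(aligned, stat = c("sd", "var")) {
  stat <- match.arg(stat)
  sets <- if (inherits(aligned, "AlignedSample")) aligned$aligned else aligned
  if (length(sets) < 2L)
    stop("contract error: need at least 2 landmark sets")
  Y <- vapply(sets, function(s) s[, 2], numeric(nrow(sets[[1]])))
  v <- apply(Y, 1, stats::sd)
  if (stat == "var") v <- v^2
  nm <- rownames(sets[[1]])
  names(v) <- if (!is.null(nm)) nm else paste0("L", seq_along(v))
  v
}
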