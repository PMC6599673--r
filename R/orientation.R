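# Orientation of the vertex cloud: PCA fit to the tracking plane, undoing
# of accidental mirror inversion, and cast-to-mold conversion.

#' Fit the vertex cloud to the horizontal plane
#'
#' Principal component analysis of the vertex coordinates rotates the cloud
#' so that PC1/PC2 span the tracking plane (x, y) and PC3 captures the
#' relief (z). The cloud is mean-centered; units are preserved.
#'
#' @param mesh a `SurfaceMesh`.
#' @return An `OrientedCloud`: list with `points` (n x 3), `faces` (carried
#'   over for later contouring and export), `rotation` (3 x 3, columns =
#'   PC1..PC3 so `points = centered %*% rotation`), `centroid`,
#'   `mirrored_back`, `converted_cast`.
#' @export
fitHorizontalPlane <- function(mesh) {
  stopifnot(is_surface_mesh(mesh))
  v <- mesh$vertices
  ctr <- colMeans(v)
  cen <- sweep(v, 2, ctr)
  cv <- crossprod(cen) / (nrow(cen) - 1)
  e <- eigen(cv, symmetric = TRUE)
  if (e$values[2] <= e$values[1] * 1e-12)
    stop("geometry error: vertex cloud is (near-)collinear, no plane fit")
  rot <- e$vectors  # columns ordered by decreasing variance
  structure(
    list(points = cen %*% rot, faces = mesh$faces, rotation = rot,
         centroid = ctr, mirrored_back = FALSE, converted_cast = FALSE,
         source_path = mesh$source_path),
    class = "OrientedCloud")
}

#' @export
print.OrientedCloud <- function(x, ...) {
  cat("OrientedCloud:", nrow(x$points), "points;",
      "mirrored_back =", x$mirrored_back,
      "| converted_cast =", x$converted_cast, "\n")
  invisible(x)
}

# Deterministic subsample of about n_target row indices.
.subsample_idx <- function(n, n_target = 100L) {
  k <- max(1L, n %/% n_target)
  seq(1L, n, by = k)
}

# Ordinary Procrustes distance between two configurations, minimising over
# translation, scale and *proper* rotations only (reflections are exactly
# what the test must detect).
.opa_distance <- function(a, b) {
  a <- sweep(a, 2, colMeans(a)); b <- sweep(b, 2, colMeans(b))
  sa <- sqrt(sum(a^2)); sb <- sqrt(sum(b^2))
  if (sa == 0 || sb == 0) return(0)
  a <- a / sa; b <- b / sb
  s <- svd(crossprod(b, a))
  d <- sign(det(s$u %*% t(s$v)))
  dd <- c(rep(1, ncol(a) - 1), d)
  tr <- sum(s$d * dd)
  sqrt(max(0, 2 - 2 * tr))
}

#' Undo accidental mirror inversion from the PCA fit
#'
#' The signs of PCA eigenvectors are arbitrary, so the fitted cloud can be a
#' mirror image of the input. A deterministic subset of vertices (about 100,
#' every k-th vertex) is compared, via ordinary Procrustes superposition
#' over proper rotations, against the fitted subset and against its
#' z-reflection; the orientation with the smaller Procrustes distance is
#' kept. This is threshold-free and equivalent to requiring the determinant
#' of the applied basis to be +1.
#'
#' @param cloud an `OrientedCloud` from [fitHorizontalPlane()].
#' @param reference optional matrix of the same vertex subset in original
#'   coordinates; defaults to the subset taken from the cloud's provenance.
#' @return The cloud, possibly with the z-axis negated and `mirrored_back`
#'   set.
#' @export
correctMirroring <- function(cloud, reference = NULL) {
  stopifnot(inherits(cloud, "OrientedCloud"))
  idx <- .subsample_idx(nrow(cloud$points))
  fitted_sub <- cloud$points[idx, , drop = FALSE]
  if (is.null(reference)) {
    # reconstruct the original-coordinate subset from the fit itself
    reference <- sweep(fitted_sub %*% t(cloud$rotation), 2, -cloud$centroid)
  }
  refl <- fitted_sub
  refl[, 3] <- -refl[, 3]
  d_keep <- .opa_distance(reference, fitted_sub)
  d_flip <- .opa_distance(reference, refl)
  if (d_flip < d_keep) {
    cloud$points[, 3] <- -cloud$points[, 3]
    cloud$rotation[, 3] <- -cloud$rotation[, 3]
    cloud$mirrored_back <- TRUE
  }
  cloud
}

# median z of points inside the central 25% of the x/y bounding box and of
# points in the outer 10% rim; used to decide depression orientation.
.relief_medians <- function(p) {
  rx <- range(p[, 1]); ry <- range(p[, 2])
  cx <- mean(rx); cy <- mean(ry)
  wx <- diff(rx); wy <- diff(ry)
  central <- abs(p[, 1] - cx) <= 0.125 * wx & abs(p[, 2] - cy) <= 0.125 * wy
  fx <- pmin(p[, 1] - rx[1], rx[2] - p[, 1]) / wx
  fy <- pmin(p[, 2] - ry[1], ry[2] - p[, 2]) / wy
  rim <- pmin(fx, fy) <= 0.05
  c(center = stats::median(p[central, 3]), rim = stats::median(p[rim, 3]))
}

#' Ensure the footprint is a mold (central depression)
#'
#' Casts (convex hyporelief) are mirrored into molds. A footprint model is
#' a central depression by the input contract, so the relief sign is read
#' from the median z of the central 25% of the x/y bounding box versus the
#' median z of the outer 10% rim. Whether an apparent bump is a genuine
#' cast or merely a mold whose PCA z-axis came out pointing into the ground
#' cannot be told from the fitted cloud alone; it is resolved from the
#' original coordinates, assuming the model was digitized viewing the
#' surface from above (+z roughly outward, the universal convention of
#' photogrammetric track models): the object is cast-like iff its central
#' relief rises along the original +z direction. Molds are then put
#' depression-down by proper rotations only (outline chirality preserved);
#' casts receive a single reflection, which maps them onto the mold they
#' formed from, so a z-negated mold reproduces the mold's outline exactly.
#' Ties (|center - rim| < 1e-9 of the bounding-box diagonal) are treated as
#' molds and left untouched. Finally z is translated so the rim median sits
#' at 0, giving contour levels a stable physical meaning.
#'
#' @param cloud a fitted, mirror-corrected `OrientedCloud`.
#' @return The cloud with `converted_cast` set iff a reflection was applied,
#'   and z re-referenced to the rim.
#' @export
ensureMold <- function(cloud) {
  stopifnot(inherits(cloud, "OrientedCloud"))
  med <- .relief_medians(cloud$points)
  diag_len <- sqrt(sum((apply(cloud$points, 2, function(v) diff(range(v))))^2))
  tie <- !is.finite(med["center"]) || !is.finite(med["rim"]) ||
    abs(med["center"] - med["rim"]) < 1e-9 * diag_len
  if (!tie) {
    bump_up <- (med["center"] - med["rim"]) > 0  # relief rises toward center
    wz <- cloud$rotation[3, 3]  # original-z component of the fitted z-axis
    cast_like <- if (bump_up) wz > 0 else wz < 0
    if (cast_like) {
      # one reflection maps the cast onto the mold it formed from
      if (bump_up) {
        cloud$points[, 3] <- -cloud$points[, 3]
        cloud$rotation[, 3] <- -cloud$rotation[, 3]
      } else {
        cloud$points[, 1] <- -cloud$points[, 1]
        cloud$rotation[, 1] <- -cloud$rotation[, 1]
      }
      cloud$converted_cast <- TRUE
    } else if (bump_up) {
      # mold fitted upside down: proper 180-degree rotation about y
      cloud$points[, c(1, 3)] <- -cloud$points[, c(1, 3)]
      cloud$rotation[, c(1, 3)] <- -cloud$rotation[, c(1, 3)]
    }
  }
  med <- .relief_medians(cloud$points)
  if (is.finite(med["rim"]))
    cloud$points[, 3] <- cloud$points[, 3] - med["rim"]
  cloud
}

#' Orient a surface mesh for contouring
#'
#' Convenience wrapper chaining [fitHorizontalPlane()], [correctMirroring()]
#' and [ensureMold()].
#'
#' @param mesh a `SurfaceMesh`.
#' @param cast_detect logical; set `FALSE` to skip cast detection and force
#'   the mold interpretation.
#' @return An `OrientedCloud`.
#' @export
orientMesh <- function(mesh, cast_detect = TRUE) {
  cloud <- correctMirroring(fitHorizontalPlane(mesh),
                            reference = mesh$vertices[
                              .subsample_idx(nrow(mesh$vertices)), ,
                              drop = FALSE])
  if (cast_detect) {
    cloud <- ensureMold(cloud)
  } else {
    med <- .relief_medians(cloud$points)
    if (is.finite(med["rim"]))
      cloud$points[, 3] <- cloud$points[, 3] - med["rim"]
  }
  cloud
}
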