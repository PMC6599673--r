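#' Construct a surface mesh
#'
#' A `SurfaceMesh` is a triangulated surface: an `n x 3` matrix of vertex
#' coordinates in model units (typically meters for photogrammetric track
#' models) and an `m x 3` integer matrix of 1-based vertex indices. Units
#' are preserved verbatim throughout the pipeline; nothing rescales them.
#'
#' @param vertices numeric matrix, `n x 3` (x, y, z), `n >= 4`.
#' @param faces integer matrix, `m x 3`, `m >= 1`; every index must address
#'   an existing vertex.
#' @param source_path provenance string (file of origin, or a synthetic tag).
#' @return An object of class `SurfaceMesh`.
#' @export
surfaceMesh <- function(vertices, faces, source_path = "") {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L)
    stop("vertices must have three columns (x, y, z)")
  if (nrow(vertices) < 4L)
    stop("format error: mesh has fewer than 4 vertices")
  if (ncol(faces) != 3L || nrow(faces) < 1L)
    stop("format error: mesh has no triangular faces")
  if (anyNA(vertices)) stop("vertices contain missing values")
  if (min(faces) < 1L || max(faces) > nrow(vertices))
    stop("format error: face indices address nonexistent vertices")
  structure(
    list(vertices = vertices, faces = faces,
         source_path = as.character(source_path)),
    class = "SurfaceMesh")
}

#' @export
print.SurfaceMesh <- function(x, ...) {
  rng <- apply(x$vertices, 2, range)
  cat("SurfaceMesh:", nrow(x$vertices), "vertices,", nrow(x$faces), "faces\n")
  cat(sprintf("  extent x [%g, %g]  y [%g, %g]  z [%g, %g]\n",
              rng[1, 1], rng[2, 1], rng[1, 2], rng[2, 2], rng[1, 3], rng[2, 3]))
  if (nzchar(x$source_path)) cat("  source:", x$source_path, "\n")
  invisible(x)
}

is_surface_mesh <- function(x) inherits(x, "SurfaceMesh")
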