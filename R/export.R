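# Result export: SVG plots, CSV coordinates, fitted PLY.

.fmt_num <- function(x) sprintf("%.9g", x)

# outline/contours to SVG path data; y is negated so anatomical "up"
# plots upward (SVG y grows downward); 1 model unit = 1000 user units
.svg_path <- function(pts, close = TRUE) {
  s <- paste0(ifelse(seq_len(nrow(pts)) == 1L, "M", "L"),
              .fmt_num(pts[, 1] * 1000), ",", .fmt_num(-pts[, 2] * 1000),
              collapse = " ")
  if (close) s <- paste(s, "Z")
  s
}

.write_svg <- function(path, outline, stack, landmarks = NULL) {
  pts <- .outline_pts_open(outline)
  allp <- rbind(pts, do.call(rbind, lapply(stack$contours, `[[`, "points")))
  xr <- range(allp[, 1]) * 1000
  yr <- range(-allp[, 2]) * 1000
  pad <- 0.05 * max(diff(xr), diff(yr))
  lines <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    sprintf(paste0("<svg xmlns=\"http://www.w3.org/2000/svg\" ",
                   "viewBox=\"%s %s %s %s\">"),
            .fmt_num(xr[1] - pad), .fmt_num(yr[1] - pad),
            .fmt_num(diff(xr) + 2 * pad), .fmt_num(diff(yr) + 2 * pad)),
    vapply(stack$contours, function(ct)
      sprintf(paste0("<path d=\"%s\" fill=\"none\" stroke=\"#cccccc\" ",
                     "stroke-width=\"%s\"/>"),
              .svg_path(ct$points), .fmt_num(pad / 30)),
      character(1)),
    sprintf(paste0("<path d=\"%s\" fill=\"none\" stroke=\"#000000\" ",
                   "stroke-width=\"%s\"/>"),
            .svg_path(pts), .fmt_num(pad / 10)))
  if (!is.null(landmarks)) {
    r <- .fmt_num(pad / 5)
    lines <- c(lines, vapply(seq_len(nrow(landmarks)), function(i)
      sprintf(paste0("<circle cx=\"%s\" cy=\"%s\" r=\"%s\" ",
                     "fill=\"#1f6fd0\"/>"),
              .fmt_num(landmarks[i, 1] * 1000),
              .fmt_num(-landmarks[i, 2] * 1000), r),
      character(1)))
  }
  writeLines(c(lines, "</svg>"), path)
  path
}

.write_xy_csv <- function(path, pts, close = TRUE) {
  if (close && !all(pts[1, ] == pts[nrow(pts), ]))
    pts <- rbind(pts, pts[1, ])
  con <- file(path, "wb")  # binary mode: identical bytes on every platform
  on.exit(close(con))
  writeLines(c("x,y", paste(.fmt_num(pts[, 1]), .fmt_num(pts[, 2]),
                            sep = ",")), con, sep = "\n")
  path
}

#' Export pipeline results
#'
#' Writes, for a bundle without landmarks: (a) an SVG plot of the outline
#' over its contour stack, (b) a CSV of the outline x/y coordinates in
#' model units (header `x,y`, first point repeated as last row), (c) a
#' binary little-endian PLY of the fitted cloud. With landmarks, three
#' further files: (d) a landmark CSV (`label,x,y`), (e) a resampled outline
#' CSV with homologous points, (f) an SVG including the landmarks.
#'
#' @param bundle a `ResultBundle` from [traceOutline()].
#' @param directory output directory (created if missing).
#' @param basename file name stem (default `"outline"`).
#' @return Character vector (manifest) of the written file paths.
#' @export
exportResults <- function(bundle, directory, basename = "outline") {
  stopifnot(inherits(bundle, "ResultBundle"))
  if (is.null(bundle$outline) || nrow(bundle$outline$points) < 4L)
    stop("contract error: bundle has an empty outline")
  if (!dir.exists(directory) &&
      !dir.create(directory, recursive = TRUE, showWarnings = FALSE))
    stop("I/O error: cannot create directory ", directory)
  probe <- file.path(directory, ".trackline-write-test")
  ok <- tryCatch({ file.create(probe, showWarnings = FALSE) },
                 warning = function(w) FALSE)
  if (!isTRUE(ok)) stop("I/O error: directory not writable: ", directory)
  unlink(probe)

  fp <- function(ext) file.path(directory, paste0(basename, ext))
  manifest <- character()

  .write_svg(fp(".svg"), bundle$outline, bundle$stack)
  manifest <- c(manifest, fp(".svg"))

  .write_xy_csv(fp(".csv"), .outline_pts_open(bundle$outline))
  manifest <- c(manifest, fp(".csv"))

  fitted <- surfaceMesh(bundle$fitted_cloud$points, bundle$fitted_cloud$faces,
                        source_path = bundle$fitted_cloud$source_path)
  writeSurfaceModel(fitted, fp("_fitted.ply"))
  manifest <- c(manifest, fp("_fitted.ply"))

  if (!is.null(bundle$landmarks)) {
    lm <- bundle$landmarks
    con <- file(fp("_landmarks.csv"), "wb")
    writeLines(c("label,x,y",
                 paste(rownames(lm), .fmt_num(lm[, 1]), .fmt_num(lm[, 2]),
                       sep = ",")), con, sep = "\n")
    close(con)
    manifest <- c(manifest, fp("_landmarks.csv"))
    # homologous resampling of the final outline: equidistant points with
    # the point count used for the contours
    hp <- .resample_closed(.outline_pts_open(bundle$outline),
                           bundle$config_used$points)
    .write_xy_csv(fp("_homologous.csv"), hp)
    manifest <- c(manifest, fp("_homologous.csv"))
    .write_svg(fp("_landmarks.svg"), bundle$outline, bundle$stack, lm)
    manifest <- c(manifest, fp("_landmarks.svg"))
  }
  manifest
}
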