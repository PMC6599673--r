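# Synthetic footprint meshes with analytically known steepest-slope
# outlines and landmark ground truth.
#
# Every kind is built from a closed-form signed planar distance field d(x,y)
# to the footprint region boundary (negative inside). The surface is
#   z(x, y) = -depth * plogis(-d / wall_width),
# a logistic ramp whose inflexion (steepest slope) lies exactly on the zero
# level set of d — so the curve the pipeline is supposed to trace is known
# by construction. A conical kind with a linear wall is provided as well,
# because its level contours are exact circles (an analytic oracle for the
# contour extractor).

# --- signed distance primitives ----------------------------------------

.sdf_circle <- function(p, ctr, r)
  sqrt((p[, 1] - ctr[1])^2 + (p[, 2] - ctr[2])^2) - r

.sdf_capsule <- function(p, a, b, r) {
  ab <- b - a
  len2 <- sum(ab^2)
  t <- ((p[, 1] - a[1]) * ab[1] + (p[, 2] - a[2]) * ab[2]) / len2
  t <- pmin(1, pmax(0, t))
  qx <- a[1] + t * ab[1]; qy <- a[2] + t * ab[2]
  sqrt((p[, 1] - qx)^2 + (p[, 2] - qy)^2) - r
}

# run expr with a temporary RNG state seeded from `seed`
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.rot2_apply <- function(pts, deg) {
  if (deg == 0) return(pts)
  pts %*% t(.rot2(deg))
}

#' Specify a synthetic footprint
#'
#' Defaults describe a medium-sized tridactyl (theropod-like) footprint:
#' 0.3 m long, 0.03 m deep (10% of length), interdigital angles of 30
#' degrees, a central digit reaching farther than the side digits, and a
#' wall whose logistic half-width is 1.3% of footprint length.
#'
#' @param kind `"tridactyl"`, `"oval"` (stadium-shaped pit),
#'   `"hemisphere"` (circular pit, logistic wall), `"cone"` (linear wall),
#'   or `"multi"` (three disjoint oval pits).
#' @param length footprint length in model units (default 0.3).
#' @param depth maximal depth (default 0.1 * length).
#' @param wall_width logistic half-width of the wall (default
#'   0.013 * length).
#' @param web length scale of the soft union (hypex/junction fillet
#'   radius scale; default 3.5 * wall_width). The retained contour stack
#'   spans in-plane offsets of roughly +/- 3.5 wall widths around the
#'   inflexion locus, so a fillet radius beyond that band keeps the
#'   interdigital notches present on every contour — the regime in which
#'   the steepest-slope locus is well defined.
#' @param width overall width for oval kind (default 0.55 * length).
#' @param interdigital_angles angles (degrees) between the central digit
#'   axis and the left/right digit axes (default `c(30, 30)`).
#' @param digit_lengths axial lengths of the left/central/right digit
#'   capsules as fractions of `length` (default `c(0.46, 0.64, 0.46)`).
#' @param digit_widths capsule radii as fractions of `length`
#'   (default `c(0.065, 0.07, 0.065)`).
#' @param axis_angle direction the central digit points, in degrees CCW
#'   from +x (default 90 = up).
#' @param noise_sd Gaussian vertex noise (z) in model units (default 0).
#' @param target_faces approximate face count of the mesh (default 30000).
#' @param seed integer; fully determines the noise (default 1).
#' @return A `FootprintSpec` list.
#' @export
footprintSpec <- function(kind = c("tridactyl", "oval", "hemisphere",
                                   "cone", "multi"),
                          length = 0.3, depth = 0.1 * length,
                          wall_width = 0.013 * length,
                          web = 3.5 * wall_width,
                          width = 0.55 * length,
                          interdigital_angles = c(30, 30),
                          digit_lengths = c(0.46, 0.64, 0.46),
                          digit_widths = c(0.065, 0.07, 0.065),
                          axis_angle = 90, noise_sd = 0,
                          target_faces = 30000L, seed = 1L) {
  kind <- match.arg(kind)
  if (depth <= 0) stop("spec error: depth must be positive")
  if (kind == "tridactyl") {
    if (length(digit_lengths) != 3L || length(digit_widths) != 3L)
      stop("spec error: tridactyl kind needs 3 digit lengths and widths")
    if (any(interdigital_angles <= 0 | interdigital_angles >= 90))
      stop("spec error: interdigital angles must be in (0, 90) degrees")
  }
  structure(list(kind = kind, length = length, depth = depth,
                 wall_width = wall_width, web = web, width = width,
                 interdigital_angles = interdigital_angles,
                 digit_lengths = digit_lengths, digit_widths = digit_widths,
                 axis_angle = axis_angle, noise_sd = noise_sd,
                 target_faces = as.integer(target_faces),
                 seed = as.integer(seed)),
            class = "FootprintSpec")
}

# shape list (circles/capsules) of the footprint region in upright pose
.footprint_shapes <- function(spec) {
  L <- spec$length
  switch(spec$kind,
    hemisphere = list(list(type = "circle", ctr = c(0, 0), r = L / 2)),
    cone = list(list(type = "circle", ctr = c(0, 0), r = L / 2)),
    oval = {
      half <- L / 2 - spec$width / 2
      list(list(type = "capsule", a = c(0, -half), b = c(0, half),
                r = spec$width / 2))
    },
    multi = {
      # three disjoint pits of distinct size (digit pads differ), each
      # separated by several wall widths of flat surface so that every
      # impression closes its own contours
      rr <- c(0.15, 0.12, 0.10) * L
      ctrs <- list(c(-0.32 * L, 0), c(0, 0.34 * L), c(0.32 * L, 0))
      Map(function(cc, r) list(type = "circle", ctr = cc, r = r), ctrs,
          as.list(rr))
    },
    tridactyl = {
      p0 <- c(0, -0.10 * L)
      dirs <- list(
        c(-sinpi(spec$interdigital_angles[1] / 180),
          cospi(spec$interdigital_angles[1] / 180)),
        c(0, 1),
        c(sinpi(spec$interdigital_angles[2] / 180),
          cospi(spec$interdigital_angles[2] / 180)))
      t0 <- c(0.04, 0, 0.04) * L
      shapes <- lapply(1:3, function(i) {
        list(type = "capsule",
             a = p0 + t0[i] * dirs[[i]],
             b = p0 + (t0[i] + spec$digit_lengths[i] * L) * dirs[[i]],
             r = spec$digit_widths[i] * L,
             dir = dirs[[i]])
      })
      heel <- list(type = "circle", ctr = c(0, -0.26 * L), r = 0.16 * L)
      c(shapes, list(heel))
    })
}

.shapes_rotate <- function(shapes, deg) {
  lapply(shapes, function(s) {
    if (s$type == "circle") {
      s$ctr <- as.numeric(.rot2_apply(rbind(s$ctr), deg))
    } else {
      s$a <- as.numeric(.rot2_apply(rbind(s$a), deg))
      s$b <- as.numeric(.rot2_apply(rbind(s$b), deg))
      if (!is.null(s$dir)) s$dir <- as.numeric(.rot2_apply(rbind(s$dir), deg))
    }
    s
  })
}

# Union of the shape distance fields. A soft minimum (log-sum-exp with
# length scale `web`) is used instead of a hard minimum: it fillets the
# re-entrant corners where shapes meet, emulating the sediment webbing
# that rounds the hypex regions of real tracks. A hard union would leave
# zero-width interdigital slots whose bottom has no traceable
# steepest-slope locus at any resolution. With a single shape, or far from
# the junctions, the soft and hard minima coincide to machine precision.
.shapes_sdf <- function(shapes, p, web = 0) {
  D <- vapply(shapes, function(s) {
    if (s$type == "circle") .sdf_circle(p, s$ctr, s$r)
    else .sdf_capsule(p, s$a, s$b, s$r)
  }, numeric(nrow(p)))
  if (length(shapes) == 1L) return(D[, 1])
  if (web <= 0) return(do.call(pmin, as.data.frame(D)))
  m <- do.call(pmin, as.data.frame(D))
  m - web * log(rowSums(exp(-(D - m) / web)))
}

.shapes_bbox <- function(shapes, pad) {
  xs <- ys <- numeric()
  for (s in shapes) {
    if (s$type == "circle") {
      xs <- c(xs, s$ctr[1] - s$r, s$ctr[1] + s$r)
      ys <- c(ys, s$ctr[2] - s$r, s$ctr[2] + s$r)
    } else {
      xs <- c(xs, s$a[1] - s$r, s$a[1] + s$r, s$b[1] - s$r, s$b[1] + s$r)
      ys <- c(ys, s$a[2] - s$r, s$a[2] + s$r, s$b[2] - s$r, s$b[2] + s$r)
    }
  }
  c(xmin = min(xs) - pad, xmax = max(xs) + pad,
    ymin = min(ys) - pad, ymax = max(ys) + pad)
}

# zero level set of the union SDF as closed polygon(s), on a fine grid
.truth_polygons <- function(shapes, bbox, web = 0, n_fine = 800L) {
  xs <- seq(bbox["xmin"], bbox["xmax"], length.out = n_fine)
  ys <- seq(bbox["ymin"], bbox["ymax"], length.out = n_fine)
  g <- as.matrix(expand.grid(x = xs, y = ys))
  d <- matrix(.shapes_sdf(shapes, g, web = web), n_fine, n_fine)
  cls <- grDevices::contourLines(xs, ys, d, levels = 0)
  polys <- lapply(cls, function(cl) {
    m <- cbind(cl$x, cl$y)
    if (nrow(m) > 3L && all(m[1, ] == m[nrow(m), ])) m[-nrow(m), ] else m
  })
  areas <- vapply(polys, function(p) abs(.polygon_area_signed(p)), 0)
  polys[order(areas, decreasing = TRUE)]
}

# hypex ground truth: most proximal point of the truth polygon between two
# digit tips, relative to the tip-connecting chord
.truth_hypex <- function(poly, tip_a, tip_b, ctr) {
  ia <- which.min((poly[, 1] - tip_a[1])^2 + (poly[, 2] - tip_a[2])^2)
  ib <- which.min((poly[, 1] - tip_b[1])^2 + (poly[, 2] - tip_b[2])^2)
  n <- nrow(poly)
  fwd <- if (ia <= ib) seq(ia, ib) else c(seq(ia, n), seq_len(ib))
  bwd <- if (ib <= ia) seq(ib, ia) else c(seq(ib, n), seq_len(ia))
  # the inter-digit arc is the shorter one
  span <- if (length(fwd) <= length(bwd)) fwd else bwd
  seg <- poly[span, , drop = FALSE]
  v <- tip_b - tip_a
  nrm <- c(-v[2], v[1]) / sqrt(sum(v^2))
  if (sum((colMeans(rbind(tip_a, tip_b)) - ctr) * nrm) < 0) nrm <- -nrm
  sd <- (seg[, 1] - tip_a[1]) * nrm[1] + (seg[, 2] - tip_a[2]) * nrm[2]
  seg[which.min(sd), ]
}

#' Generate a synthetic footprint mesh with ground truth
#'
#' @param spec a [footprintSpec()].
#' @return List with `mesh` (a `SurfaceMesh`: flat rim plane at z = 0 with
#'   the footprint depression) and `truth` (a `GroundTruth`: `outline` —
#'   the analytic steepest-slope curve; `landmarks` — 6 x 2 matrix L1..L6
#'   for tridactyl; `axis_angle`; `impression_centers`).
#' @export
generateFootprint <- function(spec) {
  stopifnot(inherits(spec, "FootprintSpec"))
  rot <- spec$axis_angle - 90
  shapes <- .shapes_rotate(.footprint_shapes(spec), rot)
  pad <- 6 * spec$wall_width + 0.2 * spec$length
  bbox <- .shapes_bbox(shapes, pad)
  w <- bbox["xmax"] - bbox["xmin"]; h <- bbox["ymax"] - bbox["ymin"]
  # 2 * (nx - 1) * (ny - 1) faces, cells roughly square
  ncell <- spec$target_faces / 2
  nx <- max(4L, round(sqrt(ncell * w / h)) + 1L)
  ny <- max(4L, round(ncell / (nx - 1L)) + 1L)
  xs <- seq(bbox["xmin"], bbox["xmax"], length.out = nx)
  ys <- seq(bbox["ymin"], bbox["ymax"], length.out = ny)
  g <- as.matrix(expand.grid(x = xs, y = ys))
  if (spec$kind == "cone") {
    r <- sqrt(g[, 1]^2 + g[, 2]^2)
    R <- spec$length / 2
    z <- ifelse(r < R, -spec$depth * (1 - r / R), 0)
  } else {
    web_eff <- if (spec$kind == "multi") 0 else spec$web
    d <- .shapes_sdf(shapes, g, web = web_eff)
    z <- -spec$depth * stats::plogis(-d / spec$wall_width)
  }
  if (spec$noise_sd > 0)
    z <- z + .with_seed(spec$seed, stats::rnorm(length(z), 0, spec$noise_sd))
  verts <- cbind(g, z)
  # grid triangulation: vertices in column-major order of expand.grid
  # (x fastest); cell (i, j) has corners i + (j-1)*nx etc.
  i <- rep(seq_len(nx - 1L), ny - 1L)
  j <- rep(seq_len(ny - 1L), each = nx - 1L)
  v00 <- i + (j - 1L) * nx
  v10 <- v00 + 1L
  v01 <- v00 + nx
  v11 <- v01 + 1L
  faces <- rbind(cbind(v00, v10, v11), cbind(v00, v11, v01))
  dimnames(faces) <- NULL
  mesh <- surfaceMesh(verts, faces,
                      source_path = sprintf("synthetic:%s", spec$kind))

  truth_polys <- if (spec$kind == "cone") {
    th <- seq(0, 2 * pi, length.out = 1441L)[-1441L]
    list(cbind(cos(th), sin(th)) * spec$length / 2)
  } else {
    .truth_polygons(shapes, bbox,
                    web = if (spec$kind == "multi") 0 else spec$web)
  }
  landmarks <- NULL
  if (spec$kind == "tridactyl") {
    # Ground-truth landmarks are the landmark definitions evaluated on the
    # analytic truth curve (in mesh coordinates). An outline-based scheme
    # can only see the visible lobes — interdigital webbing shifts the
    # apparent digital axes away from the buried capsule axes — so the
    # meaningful reference for pipeline validation is the rule applied to
    # the exact curve, independent of meshing, contouring, homology and
    # tracing.
    poly_rs <- .resample_closed(truth_polys[[1]], 1000L)
    tro <- structure(
      list(points = rbind(poly_rs, poly_rs[1, ]),
           harmonics = NA_integer_, smoothing_iterations = NA_integer_,
           upright_angle = NA_real_, centroid = colMeans(poly_rs)),
      class = "Outline")
    lm_up <- placeLandmarks(rotateUpright(tro))
    refined <- .outline_pts_open(attr(lm_up, "outline"))
    # exact rigid map from the refined upright frame back to mesh frame
    ca <- colMeans(refined); cb <- colMeans(poly_rs)
    sv <- svd(crossprod(sweep(refined, 2, ca), sweep(poly_rs, 2, cb)))
    Rm <- sv$u %*% t(sv$v)
    landmarks <- sweep(sweep(unclass(lm_up), 2, ca) %*% Rm, 2, -cb)
    rownames(landmarks) <- rownames(unclass(lm_up))
    colnames(landmarks) <- c("x", "y")
  }
  centers <- if (spec$kind == "multi") {
    do.call(rbind, lapply(shapes, `[[`, "ctr"))
  } else NULL
  truth <- structure(
    list(outline = truth_polys[[1]], all_outlines = truth_polys,
         landmarks = landmarks, axis_angle = spec$axis_angle,
         impression_centers = centers),
    class = "GroundTruth")
  list(mesh = mesh, truth = truth, spec = spec)
}

# --- perturbation operators --------------------------------------------

.rot3 <- function(ax, ay, az) {
  cx <- cospi(ax / 180); sx <- sinpi(ax / 180)
  cy <- cospi(ay / 180); sy <- sinpi(ay / 180)
  cz <- cospi(az / 180); sz <- sinpi(az / 180)
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

# vertex-clustering pass used to bring large meshes near the decimation
# target before exact edge collapse
.decimate_cluster <- function(mesh, h) {
  v <- mesh$vertices
  cx <- floor((v[, 1] - min(v[, 1])) / h)
  cy <- floor((v[, 2] - min(v[, 2])) / h)
  key <- cx * (max(cy) + 1) + cy
  uk <- sort(unique(key))
  id <- match(key, uk)
  nv <- rowsum(v, id) / as.vector(table(id))
  f <- matrix(id[mesh$faces], ncol = 3)
  keep <- f[, 1] != f[, 2] & f[, 2] != f[, 3] & f[, 1] != f[, 3]
  f <- f[keep, , drop = FALSE]
  # drop duplicate faces irrespective of vertex order
  skey <- apply(f, 1, function(r) paste(sort(r), collapse = "_"))
  f <- f[!duplicated(skey), , drop = FALSE]
  surfaceMesh(nv, f, source_path = mesh$source_path)
}

# collapse shortest edges until exactly `target` faces remain (or parity
# leaves target - 1)
.decimate_collapse <- function(mesh, target) {
  v <- mesh$vertices
  f <- mesh$faces
  while (nrow(f) > target) {
    e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
    e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    e <- unique(e)
    len2 <- rowSums((v[e[, 1], , drop = FALSE] - v[e[, 2], , drop = FALSE])^2)
    k <- which.min(len2)
    a <- e[k, 1]; b <- e[k, 2]
    v[a, ] <- (v[a, ] + v[b, ]) / 2
    f[f == b] <- a
    keep <- f[, 1] != f[, 2] & f[, 2] != f[, 3] & f[, 1] != f[, 3]
    f <- f[keep, , drop = FALSE]
  }
  used <- sort(unique(as.vector(f)))
  map <- integer(nrow(v)); map[used] <- seq_along(used)
  surfaceMesh(v[used, , drop = FALSE], matrix(map[f], ncol = 3),
              source_path = mesh$source_path)
}

#' Perturb a synthetic mesh
#'
#' Deterministic perturbation operators for invariance and robustness
#' testing.
#'
#' @param mesh a `SurfaceMesh`.
#' @param op one of `"rotate"` (params: `angles = c(ax, ay, az)` degrees),
#'   `"translate"` (`offset`, length 3), `"mirror"` (`axis = "x"|"y"|"z"`),
#'   `"negate_z"`, `"decimate"` (`target_faces`), `"add_crack"`
#'   (`from`, `to` — 2D endpoints, `width`, `depth`), `"fill_digit_tip"`
#'   (`center` — 2D, `radius`, `level` — z the infilled area is raised to).
#' @param params list of operator parameters.
#' @param seed integer for operators with a random component (none of the
#'   current ones; accepted for interface stability).
#' @return The perturbed `SurfaceMesh`.
#' @export
perturbMesh <- function(mesh, op, params = list(), seed = 1L) {
  stopifnot(is_surface_mesh(mesh))
  v <- mesh$vertices
  switch(op,
    rotate = {
      R <- if (!is.null(params$matrix)) params$matrix
           else do.call(.rot3, as.list(params$angles))
      surfaceMesh(v %*% t(R), mesh$faces, mesh$source_path)
    },
    translate = {
      surfaceMesh(sweep(v, 2, -params$offset), mesh$faces, mesh$source_path)
    },
    mirror = {
      ax <- match(params$axis %||% "x", c("x", "y", "z"))
      v[, ax] <- -v[, ax]
      surfaceMesh(v, mesh$faces, mesh$source_path)
    },
    negate_z = {
      v[, 3] <- -v[, 3]
      surfaceMesh(v, mesh$faces, mesh$source_path)
    },
    decimate = {
      target <- as.integer(params$target_faces)
      if (is.na(target) || target < 100L)
        stop("parameter error: decimation target below 100 faces")
      if (nrow(mesh$faces) <= target) return(mesh)
      # bisect the clustering pitch to land just above the target, then
      # collapse the remaining shortest edges for an exact count
      area <- diff(range(v[, 1])) * diff(range(v[, 2]))
      h_lo <- sqrt(2 * area / nrow(mesh$faces))  # fine: many faces
      h_hi <- sqrt(2 * area / target) * 3        # coarse: few faces
      best <- NULL
      for (it in 1:14) {
        h <- sqrt(h_lo * h_hi)
        mc <- .decimate_cluster(mesh, h)
        nf <- nrow(mc$faces)
        if (nf >= target) {
          if (is.null(best) || nf < nrow(best$faces)) best <- mc
          if (nf <= target * 1.15) break
          h_lo <- h
        } else {
          h_hi <- h
        }
      }
      if (is.null(best)) best <- mesh
      .decimate_collapse(best, target)
    },
    add_crack = {
      p <- v[, 1:2, drop = FALSE]
      d <- .sdf_capsule(p, params$from, params$to, 0)
      hit <- d < params$width / 2
      v[hit, 3] <- v[hit, 3] - params$depth
      surfaceMesh(v, mesh$faces, mesh$source_path)
    },
    fill_digit_tip = {
      d <- sqrt((v[, 1] - params$center[1])^2 + (v[, 2] - params$center[2])^2)
      hit <- d < params$radius
      v[hit, 3] <- pmax(v[hit, 3], params$level)
      surfaceMesh(v, mesh$faces, mesh$source_path)
    },
    stop("unknown perturbation op: ", op))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a synthetic trackway landmark sample
#'
#' Emulates the landmark sets obtained from the consecutive footprints of
#' one trackway: the ground-truth landmark configuration of a tridactyl
#' footprint, with independent Gaussian jitter along the mid-axis
#' (y-direction) injected per track — hypexes are given their own (by
#' default larger) jitter, reflecting the common observation that hypex
#' positions vary more along a trackway than digit tips — plus a random
#' rigid motion and mild scale variation per track, which the Procrustes
#' alignment must remove.
#'
#' @param n_tracks number of footprints (default 13, a typical trackway
#'   sample).
#' @param tip_sd y-jitter of the three digit tips and the heel, model
#'   units (default 0.004, about 1.3% of the default footprint length).
#' @param hypex_sd y-jitter of the two hypexes (default `2 * tip_sd`).
#' @param seed integer seed; fully determines the sample.
#' @param spec the footprint whose truth landmarks anchor the sample.
#' @return List of `n_tracks` landmark matrices (6 x 2, rows L1..L6).
#' @export
generateTrackwayLandmarks <- function(n_tracks = 13L, tip_sd = 0.004,
                                      hypex_sd = 2 * tip_sd, seed = 1L,
                                      spec = footprintSpec("tridactyl")) {
  base <- generateFootprint(spec)$truth$landmarks
  .with_seed(seed, {
    lapply(seq_len(n_tracks), function(i) {
      lm <- base
      lm[c(1, 3, 5, 6), 2] <- lm[c(1, 3, 5, 6), 2] + stats::rnorm(4, 0, tip_sd)
      lm[c(2, 4), 2] <- lm[c(2, 4), 2] + stats::rnorm(2, 0, hypex_sd)
      ang <- stats::runif(1, -5, 5)
      sc <- exp(stats::rnorm(1, 0, 0.02))
      off <- stats::rnorm(2, 0, 0.05)
      sweep(sc * lm %*% t(.rot2(ang)), 2, -off)
    })
  })
}
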