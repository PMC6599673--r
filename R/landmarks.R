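# Tridactyl landmark placement: digit detection on the upright outline,
# mid-axis refinement from the central digit, six landmarks.

# circular local maxima of v with prominence; returns indices sorted by
# outline position
.circular_peaks <- function(v, min_prom) {
  n <- length(v)
  nxt <- c(2:n, 1L); prv <- c(n, 1:(n - 1L))
  is_max <- v > v[prv] & v >= v[nxt]
  idx <- which(is_max)
  prom <- vapply(idx, function(i) {
    # walk both ways until a higher value; prominence over the higher of
    # the two intervening minima
    lo_l <- v[i]; j <- i
    for (step in seq_len(n - 1L)) {
      j <- if (j == 1L) n else j - 1L
      if (v[j] > v[i]) break
      lo_l <- min(lo_l, v[j])
    }
    lo_r <- v[i]; j <- i
    for (step in seq_len(n - 1L)) {
      j <- if (j == n) 1L else j + 1L
      if (v[j] > v[i]) break
      lo_r <- min(lo_r, v[j])
    }
    v[i] - max(lo_l, lo_r)
  }, 0)
  idx[prom >= min_prom]
}

# index (circular) of the minimum of v along the arc from i to j (exclusive)
.arc_argmin <- function(v, i, j) {
  n <- length(v)
  span <- if (i < j) seq(i + 1L, j - 1L) else
    if (i == j) integer() else c(seq(i + 1L, n), seq_len(max(0L, j - 1L)))
  if (length(span) == 0L) return(i)
  span[which.min(v[span])]
}

# intersections of the line through p0 with direction u (unit) with the
# closed polyline pts (open representation); returns data frame with the
# intersection coordinates and their projection t onto u
.line_outline_intersections <- function(pts, p0, u) {
  n <- nrow(pts)
  ring <- rbind(pts, pts[1, , drop = FALSE])
  # signed perpendicular distance of vertices to the line
  s <- (ring[, 1] - p0[1]) * u[2] - (ring[, 2] - p0[2]) * u[1]
  hits <- which(s[-(n + 1L)] * s[-1L] <= 0 & (s[-(n + 1L)] != s[-1L]))
  if (length(hits) == 0L) return(NULL)
  out <- lapply(hits, function(i) {
    w <- s[i] / (s[i] - s[i + 1L])
    q <- ring[i, ] + w * (ring[i + 1L, ] - ring[i, ])
    c(q, sum((q - p0) * u))
  })
  m <- do.call(rbind, out)
  colnames(m) <- c("x", "y", "t")
  m
}

# digital axis of a digit segment: rotate the segment so the digit points
# upright, take the mean of the rotated x-coordinates. The digit direction
# runs from the tip to the midpoint of the two flank points at equal
# Euclidean distance from the tip: a digit impression is locally an
# elongate lobe with near-parallel flanks, for which that midpoint lies on
# the lobe axis exactly, regardless of how far either flank extends before
# its bounding re-entrant.
.digit_axis <- function(seg_pts, ctr, tip_pt, tip_pos = NULL) {
  n_seg <- nrow(seg_pts)
  if (is.null(tip_pos))
    tip_pos <- which.min((seg_pts[, 1] - tip_pt[1])^2 +
                           (seg_pts[, 2] - tip_pt[2])^2)
  dist_tip <- sqrt((seg_pts[, 1] - tip_pt[1])^2 +
                     (seg_pts[, 2] - tip_pt[2])^2)
  u <- NULL
  if (tip_pos > 2L && tip_pos < n_seg - 1L) {
    rho <- 0.9 * min(dist_tip[1], dist_tip[n_seg])
    ia <- which.min(abs(dist_tip[seq_len(tip_pos - 1L)] - rho))
    ib <- tip_pos + which.min(abs(dist_tip[(tip_pos + 1L):n_seg] - rho))
    base <- (seg_pts[ia, ] + seg_pts[ib, ]) / 2
    u <- tip_pt - base
  }
  if (is.null(u) || sum(u^2) < .Machine$double.eps) u <- tip_pt - ctr
  u <- u / sqrt(sum(u^2))
  R <- rbind(c(u[2], -u[1]), c(u[1], u[2]))  # maps u -> (0, 1)
  rot <- sweep(seg_pts, 2, ctr) %*% t(R)
  mx <- mean(rot[, 1])
  p0 <- ctr + mx * c(u[2], -u[1])  # axis offset along the rotated x-axis
  list(point = p0, direction = u)
}

#' Detect the three digit impressions of a tridactyl outline
#'
#' Operates on the upright outline. Prominent circular maxima of the radial
#' distance from the centroid are the candidate lobes; the three lobes
#' whose tips lie above the centroid are the digit impressions, separated
#' at the deepest radial re-entrants between adjacent lobes. Left, central
#' and right are assigned by tip x-order.
#'
#' @param outline an `Outline` in upright orientation.
#' @param prominence minimal peak prominence as a fraction of the radial
#'   range (default 0.1).
#' @return List of three `DigitSegment`s (`which`, `indices`, `axis`,
#'   `tip`), ordered left, central, right.
#' @export
detectDigits <- function(outline, prominence = 0.1) {
  pts <- .outline_pts_open(outline)
  ctr <- colMeans(pts)
  r <- sqrt((pts[, 1] - ctr[1])^2 + (pts[, 2] - ctr[2])^2)
  peaks <- .circular_peaks(r, min_prom = prominence * diff(range(r)))
  upper <- peaks[pts[peaks, 2] > ctr[2]]
  if (length(upper) != 3L)
    stop("not tridactyl: found ", length(upper),
         " distal lobe(s) above the centroid instead of 3 ",
         "(radial prominence threshold ", prominence, ")")
  # boundaries between consecutive prominent lobes (all peaks, so the heel
  # lobe, when present, bounds the side digits too)
  allp <- sort(peaks)
  bnd <- vapply(seq_along(allp), function(k) {
    i <- allp[k]; j <- allp[if (k == length(allp)) 1L else k + 1L]
    .arc_argmin(r, i, j)
  }, 1L)
  n <- nrow(pts)
  segs <- lapply(sort(upper), function(i) {
    k <- match(i, allp)
    b_prev <- bnd[if (k == 1L) length(allp) else k - 1L]
    b_next <- bnd[k]
    span <- if (b_prev <= b_next) seq(b_prev, b_next) else
      c(seq(b_prev, n), seq_len(b_next))
    # clip symmetrically about the tip: the two bounding re-entrants can
    # sit at very different arc distances (e.g. hypex vs heel waist), which
    # would tilt the midline of the lobe
    p <- match(i, span)
    k <- min(p - 1L, length(span) - p)
    span <- span[(p - k):(p + k)]
    tip_pt <- pts[i, ]
    list(indices = span, tip = tip_pt,
         axis = .digit_axis(pts[span, , drop = FALSE], ctr, tip_pt,
                            tip_pos = k + 1L))
  })
  ord <- order(vapply(segs, function(s) s$tip[1], 0))
  segs <- segs[ord]
  for (i in 1:3) segs[[i]]$which <- c("left", "central", "right")[i]
  segs
}

#' Refine outline rotation by the central digital axis
#'
#' The central digit impression approximates the footprint mid-axis; the
#' outline is re-rotated about its centroid so that the central digital
#' axis is vertical, and digits are re-detected.
#'
#' @param outline an upright `Outline`.
#' @param central optional central `DigitSegment` (detected if missing).
#' @param prominence forwarded to [detectDigits()].
#' @param max_iter re-detection/re-rotation passes (the axis estimate
#'   improves as the outline straightens; iteration stops once a pass
#'   rotates by less than 0.2 degrees).
#' @return List with the rotated `outline`, the re-detected `digits`, and
#'   the total applied `angle` in degrees (counter-clockwise).
#' @export
refineAxisRotation <- function(outline, central = NULL, prominence = 0.1,
                               max_iter = 5L) {
  digits <- if (is.null(central)) detectDigits(outline, prominence)
            else NULL
  total <- 0
  for (it in seq_len(max_iter)) {
    cen <- if (!is.null(central)) central else digits[[2]]
    u <- cen$axis$direction
    phi <- atan2(u[1], u[2]) * 180 / pi  # CCW rotation mapping u upright
    pts <- .outline_pts_open(outline)
    ctr <- colMeans(pts)
    rot <- sweep(sweep(pts, 2, ctr) %*% t(.rot2(phi)), 2, -ctr)
    outline$points <- rbind(rot, rot[1, ])
    outline$centroid <- colMeans(rot)
    total <- total + phi
    central <- NULL
    digits <- detectDigits(outline, prominence)
    if (abs(phi) < 0.2) break
  }
  list(outline = outline, digits = digits, angle = total)
}

.axis_tip <- function(pts, axis, most_distal = TRUE) {
  hits <- .line_outline_intersections(pts, axis$point, axis$direction)
  if (is.null(hits))
    stop("landmark error: digital axis does not intersect the outline")
  i <- if (most_distal) which.max(hits[, "t"]) else which.min(hits[, "t"])
  hits[i, c("x", "y")]
}

# most proximal outline point of the arc between two tips, relative to the
# chord connecting the tips ("lowest point relative to a line")
.hypex_between <- function(pts, i_from, i_to, tip_a, tip_b, ctr) {
  n <- nrow(pts)
  span <- if (i_from <= i_to) seq(i_from, i_to) else
    c(seq(i_from, n), seq_len(i_to))
  seg <- pts[span, , drop = FALSE]
  v <- tip_b - tip_a
  nrm <- c(-v[2], v[1]) / sqrt(sum(v^2))
  if (sum((colMeans(rbind(tip_a, tip_b)) - ctr) * nrm) < 0) nrm <- -nrm
  # nrm points distally; minimize the signed distance (most proximal)
  sd <- (seg[, 1] - tip_a[1]) * nrm[1] + (seg[, 2] - tip_a[2]) * nrm[2]
  seg[which.min(sd), ]
}

#' Place the six tridactyl landmarks
#'
#' Detects the digits, refines the rotation by the central digital axis,
#' and places: L1/L3/L5 on the digit tips (distal intersection of each
#' digital axis with the outline, reducing the influence of claw marks),
#' L2/L4 on the hypexes (most proximal outline point between the enclosing
#' digit tips relative to the tip-connecting chord), and L6 on the heel
#' (intersection of the central digital axis with the proximal margin).
#' Landmarks are reported in geometric order: L1 left tip, L2 left hypex,
#' L3 central tip, L4 right hypex, L5 right tip, L6 heel (in upright view);
#' anatomical medial/lateral labels require knowing the foot side, which
#' cannot be inferred from geometry.
#'
#' @param outline an upright `Outline` of a tridactyl track.
#' @param prominence forwarded to [detectDigits()].
#' @return A `LandmarkSet`: 6 x 2 matrix with rows L1..L6, attributes
#'   `refined_angle` (degrees) and `outline` (the refined outline).
#' @export
placeLandmarks <- function(outline, prominence = 0.1) {
  ref <- refineAxisRotation(outline, prominence = prominence)
  outline <- ref$outline
  digits <- ref$digits
  pts <- .outline_pts_open(outline)
  ctr <- colMeans(pts)
  tips <- lapply(digits, function(d) .axis_tip(pts, d$axis, TRUE))
  # nearest outline indices of the tips, to delimit the hypex arcs
  tip_idx <- vapply(tips, function(tp)
    which.min((pts[, 1] - tp[1])^2 + (pts[, 2] - tp[2])^2), 1L)
  # the arc from left tip to central tip not containing the right tip
  arc_between <- function(ia, ib, avoid) {
    n <- nrow(pts)
    fwd <- if (ia <= ib) seq(ia, ib) else c(seq(ia, n), seq_len(ib))
    if (avoid %in% fwd) list(from = ib, to = ia) else list(from = ia, to = ib)
  }
  a12 <- arc_between(tip_idx[1], tip_idx[2], tip_idx[3])
  a23 <- arc_between(tip_idx[2], tip_idx[3], tip_idx[1])
  L2 <- .hypex_between(pts, a12$from, a12$to, tips[[1]], tips[[2]], ctr)
  L4 <- .hypex_between(pts, a23$from, a23$to, tips[[2]], tips[[3]], ctr)
  L6 <- .axis_tip(pts, digits[[2]]$axis, most_distal = FALSE)
  lm <- rbind(L1 = tips[[1]], L2 = L2, L3 = tips[[2]], L4 = L4,
              L5 = tips[[3]], L6 = L6)
  colnames(lm) <- c("x", "y")
  structure(lm, class = c("LandmarkSet", class(lm)),
            refined_angle = ref$angle, outline = outline)
}

#' @export
print.LandmarkSet <- function(x, ...) {
  cat("LandmarkSet: 6 tridactyl landmarks (refined rotation ",
      format(attr(x, "refined_angle"), digits = 3), " deg)\n", sep = "")
  print(unclass(x)[, , drop = FALSE])
  invisible(x)
}
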