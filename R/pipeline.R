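# End-to-end pipeline: oriented cloud -> contour stack -> homology ->
# steepest-slope outline -> elliptic Fourier smoothing -> upright rotation
# -> optional tridactyl landmarks.

#' Pipeline configuration
#'
#' Collects every parameter that influences a run; the configuration used
#' is recorded on the result for reproducibility.
#'
#' @param levels number of contour height levels (default 30).
#' @param points points per contour for homologization (default 500).
#' @param harmonics elliptic Fourier harmonics (default 25).
#' @param smooth_iters outline smoothing iterations (default 10).
#' @param min_length_frac contour length threshold (default 0.5).
#' @param lower_area_ratio,upper_area_ratio area-jump thresholds for the
#'   lower/upper half of the stack (defaults 1.5 and 1.3).
#' @param weight_exponent steepness weighting exponent (default 2).
#' @param window steepness neighbor half-width in columns (default 5).
#' @param impressions number of impressions to extract (default 1).
#' @param tridactyl place the six tridactyl landmarks (default FALSE).
#' @param digit_prominence radial prominence threshold for digit detection
#'   (default 0.1).
#' @param cast_detect detect and convert casts (default TRUE).
#' @param pitch optional grid pitch override (model units).
#' @return A `PipelineConfig` list.
#' @export
pipelineConfig <- function(levels = 30L, points = 500L, harmonics = 25L,
                           smooth_iters = 10L, min_length_frac = 0.5,
                           lower_area_ratio = 1.5, upper_area_ratio = 1.3,
                           weight_exponent = 2, window = 5L,
                           impressions = 1L, tridactyl = FALSE,
                           digit_prominence = 0.1, cast_detect = TRUE,
                           pitch = NULL) {
  structure(list(levels = as.integer(levels), points = as.integer(points),
                 harmonics = as.integer(harmonics),
                 smooth_iters = as.integer(smooth_iters),
                 min_length_frac = min_length_frac,
                 lower_area_ratio = lower_area_ratio,
                 upper_area_ratio = upper_area_ratio,
                 weight_exponent = weight_exponent,
                 window = as.integer(window),
                 impressions = as.integer(impressions),
                 tridactyl = isTRUE(tridactyl),
                 digit_prominence = digit_prominence,
                 cast_detect = isTRUE(cast_detect),
                 pitch = pitch),
            class = "PipelineConfig")
}

.stack_to_outline <- function(stack, config) {
  hstack <- homologizeStack(stack, n = config$points)
  raw <- traceRawOutline(hstack, window = config$window,
                         exponent = config$weight_exponent)
  # equal arc-length spacing before smoothing, so the Fourier fit's
  # uniform parameterization corresponds to arc length; homologous-column
  # spacing varies between bottleneck sections
  raw <- .resample_closed(raw[-nrow(raw), , drop = FALSE], config$points)
  outline <- ellipticFourierSmooth(raw, harmonics = config$harmonics,
                                   smoothing_iterations = config$smooth_iters)
  outline <- rotateUpright(outline)
  list(outline = outline, hstack = hstack)
}

#' Run the full outline pipeline
#'
#' @param mesh a `SurfaceMesh` or a path to a PLY file.
#' @param config a [pipelineConfig()].
#' @return A `ResultBundle`: list with `outline`, `stack`, `hstack`,
#'   `landmarks` (or NULL), `fitted_cloud`, `extra` (additional-impression
#'   results), `config_used`.
#' @export
traceOutline <- function(mesh, config = pipelineConfig()) {
  if (is.character(mesh)) mesh <- readSurfaceModel(mesh)
  stopifnot(is_surface_mesh(mesh), inherits(config, "PipelineConfig"))
  cloud <- orientMesh(mesh, cast_detect = config$cast_detect)
  cands <- extractLevelContours(cloud, n_levels = config$levels,
                                pitch = config$pitch)
  stack <- selectPrimaryStack(cands,
                              min_length_frac = config$min_length_frac)
  stack <- trimStackByArea(stack, lower_ratio = config$lower_area_ratio,
                           upper_ratio = config$upper_area_ratio)
  main <- .stack_to_outline(stack, config)
  extra <- list()
  if (config$impressions > 1L) {
    more <- selectAdditionalStacks(cands, k = config$impressions - 1L,
                                   primary = stack,
                                   min_length_frac = config$min_length_frac,
                                   lower_ratio = config$lower_area_ratio,
                                   upper_ratio = config$upper_area_ratio)
    extra <- lapply(more, function(st)
      c(list(stack = st), .stack_to_outline(st, config)))
  }
  landmarks <- NULL
  if (config$tridactyl) {
    landmarks <- placeLandmarks(main$outline,
                                prominence = config$digit_prominence)
    # landmarks live on the axis-refined outline; keep the two consistent
    main$outline <- attr(landmarks, "outline")
  }
  structure(
    list(outline = main$outline, stack = stack, hstack = main$hstack,
         landmarks = landmarks, fitted_cloud = cloud, extra = extra,
         config_used = config),
    class = "ResultBundle")
}

#' @export
print.ResultBundle <- function(x, ...) {
  cat("ResultBundle\n")
  print(x$outline)
  print(x$stack)
  if (!is.null(x$landmarks)) print(x$landmarks)
  if (length(x$extra))
    cat("  +", length(x$extra), "additional impression(s)\n")
  invisible(x)
}
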