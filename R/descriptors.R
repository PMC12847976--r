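#' Names of the 15 vessel descriptors
#' @return Character vector of descriptor column names.
#' @export
descriptor_names <- function() {
  c("explant_area", "thick_area", "thin_area", "total_area",
    "thick_density", "thin_density", "total_density",
    "n_junctions", "branching_index",
    "total_length", "avg_branch_length", "avg_width",
    "thick_total_area_ratio", "inout_total_ratio", "inout_thick_ratio")
}

#' Compute the 15 morphometric vessel descriptors for one chip
#'
#' Descriptors (pixel units unless `pixel_size` converts them):
#' \itemize{
#'   \item explant_area: area of the convex hull of all vessel pixels.
#'   \item thick/thin/total_area: per-class vessel pixel counts.
#'   \item thick/thin/total_density: class area divided by the area of the
#'     central circle of the tumor compartment.
#'   \item n_junctions: branching points of the vessel skeleton (merged
#'     junction nodes).
#'   \item branching_index: junction count divided by total vessel area.
#'   \item total_length: sum of all skeleton branch lengths.
#'   \item avg_branch_length: mean skeleton branch length.
#'   \item avg_width: total vessel area divided by total vessel length.
#'   \item thick_total_area_ratio: thick area / total area.
#'   \item inout_total_ratio, inout_thick_ratio: class area inside the
#'     central circle divided by class area outside it (within the
#'     compartment).
#' }
#' Degenerate denominators: if a class has zero area outside the circle the
#' inside/outside ratio is reported `NA` and flagged (excluded from
#' downstream standardization); if total length is 0, avg_width is 0; an
#' empty mask yields all-zero descriptors with the `empty` flag.
#'
#' @param mask A cleaned [vessel_mask()].
#' @param graph A [build_graph()] result for the same chip.
#' @param geometry A [chip_geometry()].
#' @param pixel_size Optional micrometres per pixel; when given, areas are
#'   reported in um^2 and lengths/widths in um.
#' @return One-row data frame with the 15 descriptors; attribute `flags`
#'   lists degenerate-case flags.
#' @export
compute_descriptors <- function(mask, graph, geometry, pixel_size = NULL) {
  lab <- mask$labels
  flags <- character(0)
  vessel <- lab > 0L
  d <- stats::setNames(as.list(numeric(15)), descriptor_names())
  if (!any(vessel)) {
    flags <- "empty"
    out <- as.data.frame(d)
    attr(out, "flags") <- flags
    return(out)
  }
  circ <- center_circle_mask(geometry)
  comp <- compartment_mask(geometry)
  circ_area <- sum(circ & comp)

  d$thick_area <- sum(lab == 2L)
  d$thin_area <- sum(lab == 1L)
  d$total_area <- d$thick_area + d$thin_area
  d$thick_density <- d$thick_area / circ_area
  d$thin_density <- d$thin_area / circ_area
  d$total_density <- d$total_area / circ_area

  idx <- which(vessel)
  rs <- (idx - 1L) %% nrow(lab) + 1L
  cs <- (idx - 1L) %/% nrow(lab) + 1L
  hull <- grDevices::chull(cs, rs)
  # hull of pixel centres plus the half-pixel boundary band (Pick-style
  # correction), so thin shapes are not undercounted
  hx <- cs[hull]; hy <- rs[hull]
  per <- sum(sqrt(diff(c(hx, hx[1]))^2 + diff(c(hy, hy[1]))^2))
  d$explant_area <- polygon_area(hx, hy) + per / 2 + 1

  d$n_junctions <- sum(graph$nodes$kind == "junction")
  d$total_length <- sum(graph$edges$length)
  d$branching_index <- if (d$total_area > 0) d$n_junctions / d$total_area else 0
  d$avg_branch_length <- if (nrow(graph$edges) > 0)
    d$total_length / nrow(graph$edges) else 0
  d$avg_width <- if (d$total_length > 0) d$total_area / d$total_length else 0
  if (d$total_length == 0) flags <- c(flags, "zero_length")

  d$thick_total_area_ratio <- if (d$total_area > 0)
    d$thick_area / d$total_area else 0

  inside_tot <- sum(vessel & circ)
  outside_tot <- sum(vessel & !circ & comp)
  if (outside_tot > 0) {
    d$inout_total_ratio <- inside_tot / outside_tot
  } else {
    d$inout_total_ratio <- NA_real_
    flags <- c(flags, "inout_total_degenerate")
  }
  inside_thick <- sum(lab == 2L & circ)
  outside_thick <- sum(lab == 2L & !circ & comp)
  if (outside_thick > 0) {
    d$inout_thick_ratio <- inside_thick / outside_thick
  } else {
    d$inout_thick_ratio <- NA_real_
    flags <- c(flags, "inout_thick_degenerate")
  }

  if (!is.null(pixel_size)) {
    a <- pixel_size^2
    for (nm in c("explant_area", "thick_area", "thin_area", "total_area"))
      d[[nm]] <- d[[nm]] * a
    for (nm in c("total_length", "avg_branch_length", "avg_width"))
      d[[nm]] <- d[[nm]] * pixel_size
    d$branching_index <- d$branching_index / a
  }
  out <- as.data.frame(d)
  attr(out, "flags") <- flags
  out
}

# shoelace polygon area
polygon_area <- function(x, y) {
  n <- length(x)
  if (n < 3) return(0)
  abs(sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y)) / 2
}

#' Full morphometry of one chip image
#'
#' Convenience wrapper running the image pipeline on a single chip:
#' rolling-ball background subtraction, Otsu segmentation with thickness
#' classification, compartment crop and small-object removal,
#' skeletonization, spur pruning, graph extraction and the 15 descriptors.
#'
#' @param image A [chip_image()].
#' @param rolling_ball_radius Rolling-ball radius in pixels.
#' @param thick_width_px Thick/thin width cutoff in pixels.
#' @param min_object_px Minimum connected-component size kept.
#' @param spur_prune_px Minimum terminal branch length kept.
#' @param preprocess If `FALSE`, skip background subtraction.
#' @return List with `descriptors` (one-row data frame), `mask`, `graph`.
#' @export
analyze_chip <- function(image, rolling_ball_radius = 50, thick_width_px = 4,
                         min_object_px = 50, spur_prune_px = 3,
                         preprocess = TRUE) {
  img <- if (preprocess) rolling_ball_subtract(image, rolling_ball_radius)
         else image
  mask <- segment_vessels(img, thick_width_px = thick_width_px)
  mask <- postprocess_mask(mask, image$geometry, min_object_px)
  skel <- skeletonize_mask(mask)
  skel <- prune_spurs(skel, spur_prune_px)
  graph <- build_graph(skel)
  desc <- compute_descriptors(mask, graph, image$geometry,
                              pixel_size = image$pixel_size)
  list(descriptors = desc, mask = mask, graph = graph)
}
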