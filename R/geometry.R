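#' Chip geometry
#'
#' Describes the fixed geometry of one chip: the image frame, the tumor
#' compartment (region of interest) and the central circular region -- the
#' "glass hole" at the center of the tumor compartment against which vessel
#' densities and inside/outside ratios are defined.
#'
#' @param nrow,ncol Image size in pixels.
#' @param center Numeric length-2, (row, col) of the central circle.
#'   Default: image center.
#' @param radius Radius of the central circle in pixels (> 0).
#' @param compartment Optional logical matrix (`nrow` x `ncol`) marking the
#'   tumor compartment; `NULL` means the full frame.
#' @return An object of class `chip_geometry`.
#' @export
chip_geometry <- function(nrow = 1024L, ncol = 1024L,
                          center = c(nrow / 2, ncol / 2),
                          radius = 300,
                          compartment = NULL) {
  stopifnot(nrow >= 1, ncol >= 1, length(center) == 2)
  if (!is.numeric(radius) || radius <= 0)
    stop("central circle radius must be > 0")
  if (!is.null(compartment)) {
    if (!is.logical(compartment) ||
        !all(dim(compartment) == c(nrow, ncol)))
      stop("compartment must be a logical nrow x ncol matrix")
  }
  g <- structure(list(nrow = as.integer(nrow), ncol = as.integer(ncol),
                      center = as.numeric(center), radius = as.numeric(radius),
                      compartment = compartment),
                 class = "chip_geometry")
  cm <- compartment_mask(g)
  if (!cm[round(center[1]), round(center[2])])
    stop("center circle must lie inside the compartment")
  g
}

#' @export
print.chip_geometry <- function(x, ...) {
  cat(sprintf("chip_geometry: %d x %d px, center circle (%.1f, %.1f) r=%.1f, %s compartment\n",
              x$nrow, x$ncol, x$center[1], x$center[2], x$radius,
              if (is.null(x$compartment)) "full-frame" else "masked"))
  invisible(x)
}

#' Logical mask of the central circle
#' @param geometry A [chip_geometry()].
#' @return Logical matrix, `TRUE` inside the circle.
#' @export
center_circle_mask <- function(geometry) {
  r <- matrix(seq_len(geometry$nrow), geometry$nrow, geometry$ncol)
  cc <- matrix(seq_len(geometry$ncol), geometry$nrow, geometry$ncol, byrow = TRUE)
  (r - geometry$center[1])^2 + (cc - geometry$center[2])^2 <= geometry$radius^2
}

#' Logical mask of the tumor compartment
#' @param geometry A [chip_geometry()].
#' @return Logical matrix, `TRUE` inside the compartment.
#' @export
compartment_mask <- function(geometry) {
  if (is.null(geometry$compartment))
    matrix(TRUE, geometry$nrow, geometry$ncol)
  else
    geometry$compartment
}

#' Single-channel chip image
#'
#' @param intensity Numeric matrix of non-negative intensities.
#' @param bitdepth Bit depth of the acquisition (default 16).
#' @param pixel_size Optional pixel size in micrometres per pixel.
#' @param geometry A [chip_geometry()]; defaults to a full-frame geometry
#'   matching the matrix with the default central circle.
#' @return An object of class `chip_image`.
#' @export
chip_image <- function(intensity, bitdepth = 16L, pixel_size = NULL,
                       geometry = NULL) {
  stopifnot(is.matrix(intensity), length(intensity) > 0)
  if (any(intensity < 0) || any(intensity > 2^bitdepth - 1))
    stop("intensities must lie in [0, 2^bitdepth - 1]")
  if (is.null(geometry))
    geometry <- chip_geometry(nrow(intensity), ncol(intensity),
                              radius = min(dim(intensity)) * 0.3)
  stopifnot(all(dim(intensity) == c(geometry$nrow, geometry$ncol)))
  structure(list(intensity = intensity, bitdepth = as.integer(bitdepth),
                 pixel_size = pixel_size, geometry = geometry),
            class = "chip_image")
}

#' @export
print.chip_image <- function(x, ...) {
  cat(sprintf("chip_image: %d x %d px, %d-bit, intensity range [%.0f, %.0f]\n",
              nrow(x$intensity), ncol(x$intensity), x$bitdepth,
              min(x$intensity), max(x$intensity)))
  invisible(x)
}

# Evaluate a function with a temporary RNG state seeded by `seed`,
# restoring the caller's state afterwards.  All stochastic operations in
# the package funnel through this.
with_seed <- function(seed, code) {
  if (is.null(seed)) stop("an explicit seed is required")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# 8-connected component labelling of a logical matrix (EBImage::bwlabel is
# 4-connected).  Returns an integer matrix, 0 = background.
label8 <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  idx <- which(mask)
  if (!length(idx)) return(lab)
  nr <- nrow(mask)
  lut <- integer(length(mask)); lut[idx] <- seq_along(idx)
  edges <- integer(0)
  for (off in c(1L, nr, nr - 1L, nr + 1L)) {  # S, E, NE, SE neighbours
    j <- idx + off
    ok <- j >= 1 & j <= length(mask)
    # forbid wrap across matrix rows
    ri <- (idx - 1L) %% nr + 1L
    if (off == 1L)           ok <- ok & ri < nr
    else if (off == nr - 1L) ok <- ok & ri > 1L
    else if (off == nr + 1L) ok <- ok & ri < nr
    ok[ok] <- mask[j[ok]]
    if (any(ok))
      edges <- c(edges, rbind(lut[idx[ok]], lut[j[ok]]))
  }
  g <- igraph::graph_from_edgelist(matrix(edges, ncol = 2, byrow = TRUE),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  lab[idx] <- as.integer(comp)
  lab
}
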