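#' Three-class vessel mask
#'
#' @param labels Integer matrix with values 0 (background), 1 (thin
#'   vessel), 2 (thick vessel).
#' @param provenance Named list recording the backend and parameters that
#'   produced the mask.
#' @return Object of class `vessel_mask`.
#' @export
vessel_mask <- function(labels, provenance = list()) {
  stopifnot(is.matrix(labels), all(labels %in% 0:2))
  structure(list(labels = labels, provenance = provenance),
            class = "vessel_mask")
}

#' @export
print.vessel_mask <- function(x, ...) {
  n <- table(factor(x$labels, 0:2))
  cat(sprintf("vessel_mask: %d x %d px (background %d, thin %d, thick %d)\n",
              nrow(x$labels), ncol(x$labels), n[1], n[2], n[3]))
  invisible(x)
}

#' Segment vessels into background / thin / thick classes
#'
#' The default backend thresholds the (background-subtracted) image with
#' Otsu's method computed over the compartment interior, then splits the
#' binary vessel mask into thin and thick classes by local width
#' ([classify_thickness()]).  A user-supplied pixel classifier can replace
#' the default: any function taking the `chip_image` and returning either a
#' logical vessel mask or a 0/1/2 label matrix honours the contract.
#'
#' @param image A background-subtracted [chip_image()].
#' @param backend `"otsu"` (default) or a function, see Details.
#' @param thick_width_px Width cutoff in pixels at or above which a vessel
#'   pixel is labelled thick (default 4).
#' @param threshold Optional fixed intensity threshold overriding Otsu.
#' @return A [vessel_mask()].
#' @export
segment_vessels <- function(image, backend = "otsu", thick_width_px = 4,
                            threshold = NULL) {
  img <- image$intensity
  comp <- compartment_mask(image$geometry)
  if (is.function(backend)) {
    out <- backend(image)
    lab <- if (is.logical(out)) {
      classify_thickness(out, thick_width_px)$labels
    } else {
      stopifnot(all(out %in% 0:2))
      out
    }
    return(vessel_mask(lab, list(backend = "custom",
                                 thick_width_px = thick_width_px)))
  }
  vals <- img[comp]
  if (max(vals) - min(vals) < .Machine$double.eps * 10) {
    warning("image is flat (all-zero or all-saturated); returning empty mask")
    return(vessel_mask(matrix(0L, nrow(img), ncol(img)),
                       list(backend = "otsu", threshold = NA)))
  }
  maxv <- 2^image$bitdepth - 1
  thr <- if (!is.null(threshold)) threshold else
    EBImage::otsu(EBImage::Image(img / maxv), range = c(0, 1),
                  levels = 256) * maxv
  binary <- img > thr & comp
  cls <- classify_thickness(binary, thick_width_px)
  vessel_mask(cls$labels,
              list(backend = "otsu", threshold = thr,
                   thick_width_px = thick_width_px))
}

#' Split a binary vessel mask into thin and thick classes by local width
#'
#' The local vessel width at a skeleton point is twice its Euclidean
#' distance to the background; this width is propagated from the skeleton
#' to every vessel pixel (nearest-skeleton assignment by wavefront
#' propagation).  Pixels with width at or above the cutoff are thick,
#' the rest thin; the partition conserves the binary vessel area exactly.
#'
#' @param binary Logical matrix of vessel pixels.
#' @param cutoff Width cutoff in pixels (>= 1).
#' @return List with `labels` (0/1/2 matrix) and `width` (per-pixel local
#'   width estimate, 0 on background).
#' @export
classify_thickness <- function(binary, cutoff = 4) {
  if (cutoff < 1) stop("width cutoff must be >= 1")
  stopifnot(is.logical(binary) || all(binary %in% 0:1))
  binary <- binary > 0
  lab <- matrix(0L, nrow(binary), ncol(binary))
  if (!any(binary))
    return(list(labels = lab, width = matrix(0, nrow(binary), ncol(binary))))
  skel <- skeletonize_mask(binary)
  d <- EBImage::distmap(binary)
  w <- matrix(NA_real_, nrow(binary), ncol(binary))
  w[skel] <- 2 * d[skel]
  # wavefront propagation of skeleton widths to all vessel pixels
  nr <- nrow(binary)
  todo <- binary & is.na(w)
  while (any(todo)) {
    wn <- w
    for (off in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
                     c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))) {
      sh <- shift_matrix(w, off[1], off[2])
      take <- todo & !is.na(sh) & (is.na(wn) | sh > wn)
      wn[take] <- sh[take]
    }
    if (identical(wn, w)) break  # unreachable vessel pixels (no skeleton)
    w <- wn
    todo <- binary & is.na(w)
  }
  w[is.na(w) & binary] <- 2 * d[is.na(w) & binary]
  w[!binary] <- 0
  lab[binary & w >= cutoff] <- 2L
  lab[binary & w < cutoff] <- 1L
  list(labels = lab, width = w)
}

# shift a matrix by (dr, dc), padding with NA
shift_matrix <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(NA, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

#' Clean a vessel mask: compartment crop and small-object removal
#'
#' Sets all vessel pixels outside the tumor compartment to background and
#' removes connected components (8-connectivity, thin and thick merged)
#' smaller than `min_size` pixels.  Idempotent.
#'
#' @param mask A [vessel_mask()].
#' @param geometry A [chip_geometry()] aligned to the mask.
#' @param min_size Minimum component size in pixels (default 50).
#' @return A cleaned [vessel_mask()].
#' @export
postprocess_mask <- function(mask, geometry, min_size = 50) {
  lab <- mask$labels
  lab[!compartment_mask(geometry)] <- 0L
  comp <- label8(lab > 0L)
  if (max(comp) > 0L) {
    sizes <- tabulate(comp[comp > 0L])
    drop <- which(sizes < min_size)
    if (length(drop)) lab[comp %in% drop] <- 0L
  }
  vessel_mask(lab, c(mask$provenance,
                     list(postprocessed = TRUE, min_object_px = min_size)))
}
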