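#' Read a single-channel TIFF as a chip image
#'
#' @param path TIFF file path.
#' @param bitdepth Bit depth the integer intensities are scaled to
#'   (default 16).
#' @param geometry Optional [chip_geometry()]; default derived from the
#'   image size.
#' @param pixel_size Optional micrometres per pixel.
#' @return A [chip_image()].
#' @export
read_chip_image <- function(path, bitdepth = 16L, geometry = NULL,
                            pixel_size = NULL) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  chip_image(round(m * (2^bitdepth - 1)), bitdepth = bitdepth,
             geometry = geometry, pixel_size = pixel_size)
}

#' Write a chip image as a single-channel TIFF
#'
#' @param image A [chip_image()].
#' @param path Output path.
#' @export
write_chip_image <- function(image, path) {
  maxv <- 2^image$bitdepth - 1
  bits <- if (image$bitdepth <= 8) 8L else 16L
  tiff::writeTIFF(image$intensity / maxv, path, bits.per.sample = bits)
  invisible(path)
}

#' Write a vessel mask as an 8-bit TIFF with values 0/1/2
#' @param mask A [vessel_mask()].
#' @param path Output path.
#' @export
write_vessel_mask <- function(mask, path) {
  tiff::writeTIFF(mask$labels / 255, path, bits.per.sample = 8L)
  invisible(path)
}

#' Read a vessel mask written by [write_vessel_mask()]
#' @param path TIFF path.
#' @return A [vessel_mask()].
#' @export
read_vessel_mask <- function(path) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  vessel_mask(matrix(as.integer(round(m * 255)), nrow(m), ncol(m)),
              list(backend = "file", path = path))
}

#' Write network ground truth as sidecar CSV tables
#'
#' Branch polylines go to `<stem>_branches.csv` (branch id, vertex order,
#' row, col, width, class), junctions to `<stem>_junctions.csv`.
#'
#' @param network A `network_truth`.
#' @param stem Output path stem (no extension).
#' @export
write_network_truth <- function(network, stem) {
  br <- do.call(rbind, lapply(seq_along(network$branches), function(i) {
    b <- network$branches[[i]]
    data.frame(branch = i, vertex = seq_len(nrow(b$path)),
               row = b$path[, 1], col = b$path[, 2],
               width = b$width, class = b$class)
  }))
  utils::write.csv(br, paste0(stem, "_branches.csv"), row.names = FALSE)
  jn <- as.data.frame(network$junctions)
  names(jn) <- c("row", "col")[seq_len(ncol(jn))]
  utils::write.csv(jn, paste0(stem, "_junctions.csv"), row.names = FALSE)
  invisible(stem)
}

#' Write a screen dataset as CSV tables
#'
#' Writes `layout.csv`, `viability.csv`, `analytes.csv` and
#' `descriptors.csv` into `dir`; this is also the expected format for real
#' screen data entering the statistics layer.
#'
#' @param screen A `screen_dataset`.
#' @param dir Output directory (created if needed).
#' @export
write_screen <- function(screen, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(screen$layout, file.path(dir, "layout.csv"),
                   row.names = FALSE)
  utils::write.csv(screen$viability, file.path(dir, "viability.csv"),
                   row.names = FALSE)
  utils::write.csv(screen$analytes, file.path(dir, "analytes.csv"),
                   row.names = FALSE)
  utils::write.csv(screen$descriptors, file.path(dir, "descriptors.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read a screen dataset from CSV tables written by [write_screen()]
#' @param dir Directory holding the CSV tables.
#' @return A `screen_dataset` (without generating truth).
#' @export
read_screen <- function(dir) {
  rd <- function(f) utils::read.csv(file.path(dir, f), check.names = FALSE)
  structure(list(layout = rd("layout.csv"), viability = rd("viability.csv"),
                 analytes = rd("analytes.csv"),
                 descriptors = rd("descriptors.csv"), truth = NULL),
            class = "screen_dataset")
}

#' Default pipeline configuration
#'
#' All tunable parameters of the pipeline with their defaults, as a nested
#' list; [read_config()] merges a YAML file over these and rejects unknown
#' keys.
#'
#' @return Nested named list.
#' @export
default_config <- function() {
  list(
    geometry = list(nrow = 1024L, ncol = 1024L, center = NULL, radius = 300),
    preprocess = list(rolling_ball_radius = 50),
    segmentation = list(backend = "otsu", thick_width_px = 4,
                        min_object_px = 50, spur_prune_px = 3),
    statistics = list(control_label = "DMSO", adjust = "bh",
                      design = "auto"),
    pixel_size = NULL,
    exclude_chips = character(0),
    seed = 1L
  )
}

#' Read and validate a pipeline configuration file
#'
#' @param path YAML config file; keys not in [default_config()] are an
#'   error, missing keys take defaults.
#' @return Validated nested config list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  def <- default_config()
  merged <- merge_config(def, user, prefix = "")
  validate_config(merged)
  merged
}

merge_config <- function(def, user, prefix) {
  if (is.null(user)) return(def)
  unknown <- setdiff(names(user), names(def))
  if (length(unknown))
    stop("unknown config key(s): ",
         paste0(prefix, unknown, collapse = ", "))
  for (k in names(user)) {
    if (is.list(def[[k]]) && !is.null(names(def[[k]])))
      def[[k]] <- merge_config(def[[k]], user[[k]], paste0(prefix, k, "."))
    else def[[k]] <- user[[k]]
  }
  def
}

validate_config <- function(cfg) {
  with(cfg, {
    if (geometry$radius <= 0) stop("geometry.radius must be > 0")
    if (preprocess$rolling_ball_radius < 1)
      stop("preprocess.rolling_ball_radius must be >= 1")
    if (segmentation$thick_width_px < 1)
      stop("segmentation.thick_width_px must be >= 1")
    if (segmentation$min_object_px < 0)
      stop("segmentation.min_object_px must be >= 0")
    if (!statistics$adjust %in% c("bh", "bonferroni"))
      stop("statistics.adjust must be 'bh' or 'bonferroni'")
    if (!statistics$design %in% c("auto", "parametric", "nonparametric"))
      stop("statistics.design must be auto/parametric/nonparametric")
  })
  invisible(cfg)
}
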