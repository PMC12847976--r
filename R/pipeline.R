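#' Run the full chip-screen image pipeline
#'
#' For every chip in the layout: read its TIFF, subtract background,
#' segment, clean, skeletonize and compute the 15 vessel descriptors; then
#' run the statistics layer (vehicle normalization of viability if
#' supplied, PCA embedding of descriptors, and treatment-vs-control
#' descriptor comparisons).  Chips whose image file is missing are
#' recorded as excluded and the run continues.  All deterministic stages
#' are bit-reproducible across reruns with the same inputs and config.
#'
#' @param image_dir Directory of single-channel TIFFs named `<chip>.tif`.
#' @param layout Data frame (`plate`, `chip`, `donor`, `treatment`,
#'   `replicate`) or path to a layout CSV.
#' @param config Nested config list ([default_config()]) or YAML path.
#' @param viability Optional data frame (`chip`, `viability`) or CSV path.
#' @param out_dir Optional output directory; when given, descriptor,
#'   results and embedding CSVs, the per-chip log and the resolved config
#'   are written there.
#' @return List: `descriptors` (chip x 15 + metadata), `results`
#'   (descriptor comparisons), `embedding`, `normalized_viability`, `log`
#'   (per-chip status data frame), `config`.
#' @export
run_pipeline <- function(image_dir, layout, config = default_config(),
                         viability = NULL, out_dir = NULL) {
  if (is.character(config)) config <- read_config(config)
  validate_config(config)
  if (is.character(layout)) layout <- utils::read.csv(layout)
  if (is.character(viability)) viability <- utils::read.csv(viability)
  gcfg <- config$geometry
  seg <- config$segmentation

  chips <- layout$chip
  log <- data.frame(chip = chips, status = "ok", message = "",
                    stringsAsFactors = FALSE)
  desc_rows <- list()
  for (i in seq_along(chips)) {
    ch <- chips[i]
    if (ch %in% config$exclude_chips) {
      log$status[i] <- "excluded"; log$message[i] <- "listed in config"
      next
    }
    path <- file.path(image_dir, paste0(ch, ".tif"))
    if (!file.exists(path))
      path2 <- file.path(image_dir, paste0(ch, ".tiff"))
    else path2 <- path
    if (!file.exists(path2)) {
      log$status[i] <- "excluded"; log$message[i] <- "image file missing"
      next
    }
    img <- read_chip_image(path2, pixel_size = config$pixel_size)
    geom <- chip_geometry(
      nrow(img$intensity), ncol(img$intensity),
      center = gcfg$center %||% c(nrow(img$intensity) / 2,
                                  ncol(img$intensity) / 2),
      radius = gcfg$radius)
    img$geometry <- geom
    res <- analyze_chip(img,
                        rolling_ball_radius = config$preprocess$rolling_ball_radius,
                        thick_width_px = seg$thick_width_px,
                        min_object_px = seg$min_object_px,
                        spur_prune_px = seg$spur_prune_px)
    desc_rows[[ch]] <- cbind(chip = ch, res$descriptors)
  }
  descriptors <- if (length(desc_rows)) do.call(rbind, desc_rows) else NULL
  ctl <- config$statistics$control_label

  normalized <- NULL
  if (!is.null(viability))
    normalized <- normalize_to_vehicle(viability, layout, control = ctl)

  results <- NULL; embedding <- NULL
  if (!is.null(descriptors) && nrow(descriptors) >= 4) {
    lay <- layout[match(descriptors$chip, layout$chip), ]
    if (length(unique(lay$treatment)) >= 2) {
      results <- do.call(rbind, lapply(descriptor_names(), function(dn) {
        v <- descriptors[[dn]]
        if (anyNA(v) || stats::sd(v) == 0) return(NULL)
        grp_n <- table(lay$treatment)
        if (any(grp_n < 2)) return(NULL)
        r <- compare_groups(v, lay$treatment,
                            design = config$statistics$design,
                            adjust = if (config$statistics$adjust == "bh")
                              "bh" else "bonferroni")
        cbind(descriptor = dn, r)
      }))
    }
    if (nrow(descriptors) >= 4)
      embedding <- embed_descriptors(descriptors[, c("chip", descriptor_names())],
                                     method = "pca", seed = config$seed)
  }

  out <- list(descriptors = descriptors, results = results,
              embedding = embedding, normalized_viability = normalized,
              log = log, config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(descriptors))
      utils::write.csv(descriptors, file.path(out_dir, "descriptors.csv"),
                       row.names = FALSE)
    if (!is.null(results))
      utils::write.csv(results, file.path(out_dir, "results.csv"),
                       row.names = FALSE)
    if (!is.null(embedding))
      utils::write.csv(embedding, file.path(out_dir, "embedding.csv"),
                       row.names = FALSE)
    if (!is.null(normalized))
      utils::write.csv(normalized, file.path(out_dir, "viability_normalized.csv"),
                       row.names = FALSE)
    utils::write.csv(log, file.path(out_dir, "chip_log.csv"),
                     row.names = FALSE)
    yaml::write_yaml(config, file.path(out_dir, "config_resolved.yaml"))
  }
  out
}
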