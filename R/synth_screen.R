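#' Design of a synthetic chip screen
#'
#' Describes a screen of `donors` x `treatments` x replicate chips laid out
#' across plates, with multiplicative treatment effects on viability, the
#' 15 vessel descriptors and a cytokine/chemokine analyte panel, plus
#' lognormal donor, plate and replicate noise.  A vehicle-control
#' treatment with all multipliers equal to 1 must be present.
#'
#' @param donors Character vector of donor labels.
#' @param treatments Named list; each element a list with elements
#'   `viability` (scalar multiplier), `descriptors` (named numeric vector
#'   of per-descriptor multipliers; unnamed scalar recycles), `analytes`
#'   (same, over analytes).  Missing elements default to 1.
#' @param analytes Character vector of analyte labels.
#' @param control Label of the vehicle-control treatment (default "DMSO").
#' @param replicates Chips per treatment per plate (control may differ via
#'   `control_replicates`).
#' @param control_replicates Chips per plate for the vehicle control
#'   (default 6, as in a Graft-plate screen layout).
#' @param plates_per_donor Number of plates per donor (default 2).
#' @param donor_cv,plate_cv,replicate_cv Lognormal coefficients of
#'   variation of the donor, plate and replicate effects.
#' @param viability_base Mean raw viability fluorescence of vehicle chips.
#' @param analyte_base Named numeric vector of baseline analyte
#'   concentrations; default 13-plex panel plus IL6.
#' @param descriptor_base Named numeric vector of baseline descriptor
#'   values; defaults emulate a well-vascularized chip.
#' @param seed Integer seed.
#' @return Object of class `screen_design`.
#' @export
screen_design <- function(donors = paste0("D", 1:2),
                          treatments = list(),
                          analytes = default_analytes(),
                          control = "DMSO",
                          replicates = 2,
                          control_replicates = 6,
                          plates_per_donor = 2,
                          donor_cv = 0.15, plate_cv = 0.10,
                          replicate_cv = 0.10,
                          viability_base = 10000,
                          analyte_base = NULL,
                          descriptor_base = NULL,
                          seed = 1L) {
  if (replicates < 1 || control_replicates < 1)
    stop("replicate counts must be >= 1")
  if (!control %in% names(treatments))
    treatments[[control]] <- list()
  norm_effect <- function(tr) {
    list(viability = if (is.null(tr$viability)) 1 else tr$viability,
         descriptors = tr$descriptors %||% 1,
         analytes = tr$analytes %||% 1)
  }
  treatments <- lapply(treatments, norm_effect)
  for (tr in treatments) {
    if (tr$viability < 0 || any(tr$descriptors < 0) || any(tr$analytes < 0))
      stop("treatment multipliers must be >= 0")
  }
  ctl <- treatments[[control]]
  if (ctl$viability != 1 || any(ctl$descriptors != 1) || any(ctl$analytes != 1))
    stop("vehicle control must have all multipliers equal to 1")
  if (is.null(analyte_base))
    analyte_base <- stats::setNames(rep(100, length(analytes)), analytes)
  if (is.null(descriptor_base)) descriptor_base <- default_descriptor_base()
  structure(list(donors = donors, treatments = treatments,
                 analytes = analytes, control = control,
                 replicates = replicates,
                 control_replicates = control_replicates,
                 plates_per_donor = plates_per_donor,
                 donor_cv = donor_cv, plate_cv = plate_cv,
                 replicate_cv = replicate_cv,
                 viability_base = viability_base,
                 analyte_base = analyte_base,
                 descriptor_base = descriptor_base, seed = seed),
            class = "screen_design")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default analyte panel (13 chemokines/cytokines plus IL6)
#' @return Character vector of analyte names.
#' @export
default_analytes <- function() {
  c("AFP", "CCL2", "CCL4", "CXCL1", "CXCL10", "CXCL12", "IL21", "IL4",
    "TNFa", "IFNg", "IL10", "VEGF", "CCL5", "IL6")
}

# plausible baseline values for the 15 descriptors of a healthy network
default_descriptor_base <- function() {
  stats::setNames(
    c(600000, 12000, 8000, 20000, 0.045, 0.030, 0.075,
      60, 0.003, 4000, 65, 5, 0.6, 0.8, 0.7),
    descriptor_names())
}

#' Generate a synthetic screen dataset
#'
#' Draws per-chip raw viability, analyte concentrations and vessel
#' descriptors under the multiplicative model: plate baseline x donor
#' effect x treatment multiplier x lognormal replicate noise.  Lognormal
#' effects have mean 1 (so multipliers are recovered exactly by
#' vehicle-control normalization when noise is zero).  The generating
#' truth (all effects and multipliers) is stored alongside the tables.
#'
#' @param design A [screen_design()].
#' @return Object of class `screen_dataset`: list of data frames `layout`
#'   (plate, chip, donor, treatment, replicate), `viability` (chip,
#'   viability), `analytes` (chip x analyte, wide), `descriptors` (chip x
#'   15, wide) and `truth`.
#' @export
generate_screen <- function(design) {
  stopifnot(inherits(design, "screen_design"))
  with_seed(design$seed, {
    ln <- function(n, cv) {
      if (cv <= 0) return(rep(1, n))
      s <- sqrt(log(1 + cv^2))
      stats::rlnorm(n, meanlog = -s^2 / 2, sdlog = s)
    }
    dn <- descriptor_names()
    an <- design$analytes
    mult_vec <- function(m, names) {
      v <- stats::setNames(rep(1, length(names)), names)
      if (length(m) == 1 && is.null(names(m))) v[] <- m
      else v[names(m)] <- m
      v
    }
    donor_eff <- stats::setNames(ln(length(design$donors), design$donor_cv),
                                 design$donors)
    rows <- list(); via <- list(); ana <- list(); des <- list()
    plate_eff <- c()
    chip_i <- 0L
    for (d in design$donors) {
      for (p in seq_len(design$plates_per_donor)) {
        plate <- sprintf("%s_P%d", d, p)
        pe <- ln(1, design$plate_cv)
        plate_eff[plate] <- pe
        for (tr in names(design$treatments)) {
          eff <- design$treatments[[tr]]
          nrep <- if (tr == design$control) design$control_replicates
                  else design$replicates
          dmult <- mult_vec(eff$descriptors, dn)
          amult <- mult_vec(eff$analytes, an)
          for (r in seq_len(nrep)) {
            chip_i <- chip_i + 1L
            chip <- sprintf("chip%04d", chip_i)
            rows[[chip_i]] <- data.frame(plate = plate, chip = chip,
                                         donor = d, treatment = tr,
                                         replicate = r)
            via[[chip_i]] <- data.frame(chip = chip,
              viability = design$viability_base * pe * donor_eff[d] *
                eff$viability * ln(1, design$replicate_cv))
            a <- design$analyte_base[an] * pe * donor_eff[d] * amult *
              ln(length(an), design$replicate_cv)
            ana[[chip_i]] <- data.frame(chip = chip, t(a))
            dd <- design$descriptor_base[dn] * donor_eff[d] * dmult *
              ln(length(dn), design$replicate_cv)
            des[[chip_i]] <- data.frame(chip = chip, t(dd))
          }
        }
      }
    }
    unrowname <- function(d) { rownames(d) <- NULL; d }
    layout <- unrowname(do.call(rbind, rows))
    analytes <- unrowname(do.call(rbind, ana))
    names(analytes) <- c("chip", an)
    descriptors <- unrowname(do.call(rbind, des))
    names(descriptors) <- c("chip", dn)
    structure(list(layout = layout,
                   viability = unrowname(do.call(rbind, via)),
                   analytes = analytes,
                   descriptors = descriptors,
                   truth = list(design = design, donor_eff = donor_eff,
                                plate_eff = plate_eff)),
              class = "screen_dataset")
  })
}

#' @export
print.screen_dataset <- function(x, ...) {
  cat(sprintf("screen_dataset: %d chips, %d donors, %d treatments, %d plates\n",
              nrow(x$layout), length(unique(x$layout$donor)),
              length(unique(x$layout$treatment)),
              length(unique(x$layout$plate))))
  invisible(x)
}
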