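#' Grow a synthetic vascular network with known ground truth
#'
#' Vessels are grown as persistent random walks seeded on the compartment
#' border and directed inward.  At each step a tip advances by
#' `step_length` pixels in a direction that mixes its previous heading with
#' random turning, and with probability `branch_prob` spawns a daughter
#' branch at its current position (a ground-truth junction).  Every branch
#' carries a stroke width drawn from a thin or thick width distribution.
#' The full branch polylines, junction coordinates and total arc length are
#' returned, so downstream morphometry can be validated against exact
#' truth.
#'
#' @param n_seeds Number of starting tips placed on the compartment border.
#' @param max_steps Maximum number of growth steps per tip.
#' @param branch_prob Per-step probability that a tip spawns a daughter.
#' @param step_length Step length in pixels.
#' @param persistence Direction persistence in `[0, 1]`; 1 = straight.
#' @param p_thick Probability that a new branch is a thick vessel.
#' @param thick_width,thin_width Length-2 ranges (pixels) from which thick
#'   and thin stroke widths are drawn uniformly.
#' @param max_branches Cap on the total number of branches grown.
#' @param corridor_px Exclusion corridor half-width in pixels: a tip
#'   terminates rather than step within this distance of another branch's
#'   centerline, so rasterized strokes only meet at true branching
#'   junctions and the ground-truth junction list stays pixel-faithful.
#' @param min_branch_len Minimum established daughter-branch length in
#'   pixels: a daughter that dies shorter than this is discarded and its
#'   branching event retracted (it would leave no resolvable junction in
#'   the raster), and a tip may only branch once it has itself grown this
#'   long.  A junction is likewise retracted when its parent terminates
#'   within a few pixels of it (the raster shows a corner, not a Y).
#' @param branch_angle Length-2 range (radians) of the daughter's heading
#'   offset from the parent.
#' @param geometry A [chip_geometry()] defining the frame and compartment.
#' @param seed Integer seed; growth is deterministic given the seed.
#' @return An object of class `network_truth`: list with `branches` (each a
#'   list with `path` n x 2 matrix of (row, col), `width`, `class`),
#'   `junctions` (m x 2 matrix), `total_length`, and an `events` data frame
#'   logging every Bernoulli branching draw (the independent oracle for the
#'   junction count).
#' @export
generate_network <- function(n_seeds = 4, max_steps = 60, branch_prob = 0.05,
                             step_length = 3, persistence = 0.7,
                             p_thick = 0.3,
                             thick_width = c(4.5, 7),
                             thin_width = c(1.5, 2.5),
                             max_branches = 60,
                             corridor_px = 8, min_branch_len = 20,
                             branch_angle = c(0.7, 1.3),
                             geometry = chip_geometry(),
                             seed) {
  if (missing(seed)) stop("seed must be set explicitly")
  if (n_seeds < 1 || max_steps < 1)
    stop("empty network: need at least one seed and one step")
  stopifnot(branch_prob >= 0, branch_prob <= 1,
            persistence >= 0, persistence <= 1,
            p_thick >= 0, p_thick <= 1,
            all(thick_width > 0), all(thin_width > 0), step_length > 0)

  with_seed(seed, {
    nr <- geometry$nrow; nc <- geometry$ncol
    occ <- matrix(0L, nr, nc)  # corridor ownership by branch id
    ri <- ceiling(corridor_px)
    disc <- expand.grid(dr = -ri:ri, dc = -ri:ri)
    disc <- disc[disc$dr^2 + disc$dc^2 <= corridor_px^2, , drop = FALSE]
    stamp <- function(pos, id) {
      rr <- round(pos[1]) + disc$dr; cc <- round(pos[2]) + disc$dc
      k <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
      j <- (cc[k] - 1L) * nr + rr[k]
      occ[j][occ[j] == 0L] <<- id
      invisible(NULL)
    }
    blocked <- function(pos, allowed) {
      r0 <- round(pos[1]); c0 <- round(pos[2])
      rr <- max(1, r0 - 1):min(nr, r0 + 1)
      cc <- max(1, c0 - 1):min(nc, c0 + 1)
      v <- occ[rr, cc]
      any(v != 0L & !(v %in% allowed))
    }
    # grace long enough for a daughter at the shallowest branch angle to
    # clear the parent corridor before collisions with it count
    grace <- ceiling(corridor_px / (step_length * sin(branch_angle[1]))) + 1L
    draw_width <- function() {
      if (stats::runif(1) < p_thick)
        list(w = stats::runif(1, thick_width[1], thick_width[2]), cls = "thick")
      else
        list(w = stats::runif(1, thin_width[1], thin_width[2]), cls = "thin")
    }
    # seeds spaced around the frame border, heading inward
    side_pos <- stats::runif(n_seeds)
    side <- (seq_len(n_seeds) - 1L) %% 4L
    tips <- vector("list", n_seeds)
    for (i in seq_len(n_seeds)) {
      p <- side_pos[i]
      start <- switch(side[i] + 1L,
                      c(1, 1 + p * (nc - 1)),    # top edge
                      c(nr, 1 + p * (nc - 1)),   # bottom
                      c(1 + p * (nr - 1), 1),    # left
                      c(1 + p * (nr - 1), nc))   # right
      ctr <- geometry$center
      ang <- atan2(ctr[1] - start[1], ctr[2] - start[2]) +
        stats::runif(1, -0.3, 0.3)
      wd <- draw_width()
      tips[[i]] <- list(pos = start, ang = ang, width = wd$w, cls = wd$cls,
                        path = matrix(start, 1, 2), steps = 0L,
                        id = i, parent_id = NA_integer_)
      stamp(start, i)
    }
    branches <- list()
    junctions <- matrix(numeric(0), 0, 2)
    events <- data.frame(step = integer(0), tip = integer(0),
                         draw = numeric(0), branched = logical(0))
    junc_keep <- logical(0)
    n_branch_total <- n_seeds
    active <- tips
    min_branch_steps <- ceiling(min_branch_len / step_length)
    min_continue <- 10  # px of parent continuation needed to keep a junction
    finish <- function(tip) {
      if (!is.null(tip$last_junc)) {
        lj <- tip$last_junc
        if (sqrt(sum((tip$pos - lj$pos)^2)) < min_continue) {
          # the parent died just past its last junction: trim the stub
          # back to the junction (the raster then shows a clean corner)
          # and retract the junction from the ground truth
          tip$path <- tip$path[seq_len(lj$vertex), , drop = FALSE]
          tip$pos <- tip$path[nrow(tip$path), ]
          junc_keep[lj$junc_idx] <<- FALSE
          events$branched[lj$event_idx] <<- FALSE
        }
      }
      arclen <- if (nrow(tip$path) >= 2)
        sum(sqrt(rowSums(diff(tip$path)^2))) else 0
      if (!is.null(tip$junc_idx) && arclen < min_branch_len) {
        # daughter died before establishing itself: retract its junction
        # and mark the branching event unsuccessful, keeping the event log
        # an exact oracle for the junction count
        junc_keep[tip$junc_idx] <<- FALSE
        events$branched[tip$event_idx] <<- FALSE
      } else if (nrow(tip$path) >= 2) {
        branches[[length(branches) + 1L]] <<-
          list(path = tip$path, width = tip$width, class = tip$cls)
      }
    }
    while (length(active)) {
      nxt <- list()
      for (k in seq_along(active)) {
        tip <- active[[k]]
        if (tip$steps >= max_steps) { finish(tip); next }
        # hold a straight course while a fresh junction is nearby (both
        # daughter launch and parent continuation), so the two strokes
        # separate monotonically and cannot ladder against each other
        in_grace <- (!is.na(tip$parent_id) && tip$steps < grace) ||
          (length(tip$children) &&
             tip$steps - tip$children[[length(tip$children)]]$step < grace)
        if (!in_grace) {
          turn <- stats::rnorm(1, 0, (1 - persistence) * 0.9)
          tip$ang <- tip$ang + turn
        }
        newpos <- tip$pos + step_length * c(sin(tip$ang), cos(tip$ang))
        inside <- newpos[1] >= 1 && newpos[1] <= nr &&
          newpos[2] >= 1 && newpos[2] <= nc
        if (inside) {
          rr <- pmin(pmax(round(newpos), 1), c(nr, nc))
          inside <- compartment_mask(geometry)[rr[1], rr[2]]
        }
        if (!inside) { finish(tip); next }
        allowed <- c(tip$id,
                     if (tip$steps < grace) tip$parent_id else NULL)
        # symmetric grace toward recently spawned daughters, whose
        # corridors overlap the parent's path near the junction
        if (length(tip$children))
          for (ch in tip$children)
            if (tip$steps - ch$step < grace) allowed <- c(allowed, ch$id)
        if (blocked(newpos, allowed)) { finish(tip); next }
        stamp(newpos, tip$id)
        tip$pos <- newpos
        tip$path <- rbind(tip$path, newpos)
        tip$steps <- tip$steps + 1L
        draw <- stats::runif(1)
        # successive junctions on one parent must stay far enough apart
        # that their skeleton junction clusters cannot merge
        gap_ok <- is.null(tip$last_junc) ||
          sqrt(sum((tip$pos - tip$last_junc$pos)^2)) >= 12
        branched <- draw < branch_prob && n_branch_total < max_branches &&
          tip$steps >= min_branch_steps && tip$steps < max_steps && gap_ok
        events <- rbind(events, data.frame(step = tip$steps, tip = k,
                                           draw = draw, branched = branched))
        if (branched) {
          n_branch_total <- n_branch_total + 1L
          junctions <- rbind(junctions, newpos)
          junc_keep <- c(junc_keep, TRUE)
          wd <- draw_width()
          child_ang <- tip$ang + sample(c(-1, 1), 1) *
            stats::runif(1, branch_angle[1], branch_angle[2])
          nxt[[length(nxt) + 1L]] <-
            list(pos = newpos, ang = child_ang, width = wd$w, cls = wd$cls,
                 path = matrix(newpos, 1, 2), steps = 0L,
                 id = n_branch_total, parent_id = tip$id,
                 junc_idx = nrow(junctions), event_idx = nrow(events))
          tip$last_junc <- list(junc_idx = nrow(junctions),
                                event_idx = nrow(events), pos = newpos,
                                vertex = nrow(tip$path))
          tip$children <- c(tip$children,
                            list(list(id = n_branch_total, step = tip$steps)))
        }
        nxt[[length(nxt) + 1L]] <- tip
      }
      # tips that hit max_steps are finished at the top of the next pass
      active <- nxt
    }
    if (!length(branches)) stop("empty network: no branch survived growth")
    junctions <- junctions[junc_keep, , drop = FALSE]
    total_length <- sum(vapply(branches, function(b) {
      d <- diff(b$path); sum(sqrt(rowSums(d^2)))
    }, numeric(1)))
    structure(list(branches = branches, junctions = junctions,
                   total_length = total_length,
                   areas = c(thick = NA_real_, thin = NA_real_),
                   events = events, geometry = geometry, seed = seed),
              class = "network_truth")
  })
}

#' @export
print.network_truth <- function(x, ...) {
  cat(sprintf("network_truth: %d branches, %d junctions, total length %.1f px\n",
              length(x$branches), nrow(x$junctions), x$total_length))
  invisible(x)
}

# Pixels covered by a stroked polyline: points sampled densely along the
# path, each stamped with a disc of radius (width - 1) / 2 so that a
# width-w stroke covers ~w pixel rows.
stroke_pixels <- function(path, width, nr, nc) {
  pts <- path
  if (nrow(path) >= 2) {
    out <- vector("list", nrow(path) - 1L)
    for (i in seq_len(nrow(path) - 1L)) {
      a <- path[i, ]; b <- path[i + 1L, ]
      n <- max(2L, ceiling(sqrt(sum((b - a)^2)) / 0.4))
      tt <- seq(0, 1, length.out = n)
      out[[i]] <- cbind(a[1] + tt * (b[1] - a[1]), a[2] + tt * (b[2] - a[2]))
    }
    pts <- do.call(rbind, out)
  }
  r <- max(0, (width - 1) / 2)
  ri <- ceiling(r)
  off <- expand.grid(dr = -ri:ri, dc = -ri:ri)
  off <- off[off$dr^2 + off$dc^2 <= r^2 + 1e-9, , drop = FALSE]
  rr <- rep(round(pts[, 1]), each = nrow(off)) + off$dr
  cc <- rep(round(pts[, 2]), each = nrow(off)) + off$dc
  keep <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
  unique((cc[keep] - 1L) * nr + rr[keep])
}

#' Rasterize a network into a chip image and a pixel-exact label grid
#'
#' Each branch polyline is drawn as a stroked path of its width.  The label
#' grid records the vessel class per pixel (0 background, 1 thin, 2 thick;
#' thick wins where strokes overlap), and the per-class areas of the truth
#' object are set from this grid -- so truth areas are pixel-exact, not
#' polyline approximations.
#'
#' @param network A [generate_network()] result.
#' @param geometry A [chip_geometry()].
#' @param foreground,background Intensity levels for vessel and background
#'   pixels (within the bit depth).
#' @param bitdepth Image bit depth (default 16).
#' @return List with `image` (a [chip_image()]), `labels` (integer matrix
#'   0/1/2) and `network` (the input with per-class `areas` filled in).
#' @export
rasterize_network <- function(network, geometry = network$geometry,
                              foreground = 20000, background = 500,
                              bitdepth = 16L) {
  maxv <- 2^bitdepth - 1
  if (foreground > maxv || background > maxv || foreground < 0 || background < 0)
    stop("intensities must lie within the bit depth")
  nr <- geometry$nrow; nc <- geometry$ncol
  labels <- matrix(0L, nr, nc)
  clipped <- FALSE
  for (b in network$branches) {
    if (any(b$path[, 1] < 1 | b$path[, 1] > nr |
            b$path[, 2] < 1 | b$path[, 2] > nc)) clipped <- TRUE
    px <- stroke_pixels(b$path, b$width, nr, nc)
    val <- if (identical(b$class, "thick")) 2L else 1L
    labels[px] <- pmax(labels[px], val)  # thick (2) wins ties
  }
  if (clipped) warning("polyline extends outside image bounds; clipped")
  network$areas <- c(thick = sum(labels == 2L), thin = sum(labels == 1L))
  img <- matrix(background, nr, nc)
  img[labels > 0L] <- foreground
  list(image = chip_image(img, bitdepth = bitdepth, geometry = geometry),
       labels = labels, network = network)
}

#' Corrupt a clean chip image with background, noise and speck artifacts
#'
#' Adds a slowly varying background field (planar gradient or Gaussian
#' blobs), i.i.d. Gaussian noise, and small bright speck artifacts placed
#' away from vessels, then clips to the bit depth.  This emulates the
#' acquisition defects that rolling-ball background subtraction and
#' small-object removal are meant to undo.
#'
#' @param image A [chip_image()].
#' @param background_field `NULL`, or a list: `list(type = "plane", a=, b=,
#'   c=)` adds `a + b*(col/ncol) + c*(row/nrow)`; `list(type = "blobs",
#'   n=, amplitude=, sigma=)` adds Gaussian bumps.
#' @param noise_sigma Standard deviation of additive Gaussian noise (>= 0).
#' @param specks `NULL`, or `list(n=, size_range=c(lo, hi))`: `n` compact
#'   bright artifacts of `lo`..`hi` pixels each, placed off-vessel.
#' @param avoid Optional logical matrix of pixels (e.g. the vessel mask)
#'   that specks must not touch.
#' @param seed Integer seed.
#' @return A corrupted [chip_image()].
#' @export
corrupt_image <- function(image, background_field = NULL, noise_sigma = 0,
                          specks = NULL, avoid = NULL, seed = 1L) {
  if (noise_sigma < 0) stop("noise sigma must be >= 0")
  maxv <- 2^image$bitdepth - 1
  img <- image$intensity
  nr <- nrow(img); nc <- ncol(img)
  with_seed(seed, {
    if (!is.null(background_field)) {
      f <- background_field
      if (identical(f$type, "plane")) {
        rr <- matrix(seq_len(nr) / nr, nr, nc)
        cc <- matrix(seq_len(nc) / nc, nr, nc, byrow = TRUE)
        img <- img + f$a + f$b * cc + f$c * rr
      } else if (identical(f$type, "blobs")) {
        rr <- matrix(seq_len(nr), nr, nc)
        cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
        for (i in seq_len(f$n)) {
          c0 <- c(stats::runif(1, 1, nr), stats::runif(1, 1, nc))
          img <- img + f$amplitude *
            exp(-((rr - c0[1])^2 + (cc - c0[2])^2) / (2 * f$sigma^2))
        }
      } else stop("unknown background field type: ", f$type)
    }
    if (noise_sigma > 0)
      img <- img + matrix(stats::rnorm(nr * nc, 0, noise_sigma), nr, nc)
    if (!is.null(specks) && specks$n > 0) {
      forbidden <- if (is.null(avoid)) matrix(FALSE, nr, nc) else avoid
      # keep specks clear of vessels and each other so they stay distinct
      # connected components
      forbidden <- EBImage::dilate(forbidden,
                                   EBImage::makeBrush(15L, "disc")) > 0
      margin <- 12
      placed <- 0L
      guard <- 0L
      while (placed < specks$n && guard < 10000L) {
        guard <- guard + 1L
        r0 <- sample(seq(margin, nr - margin), 1)
        c0 <- sample(seq(margin, nc - margin), 1)
        if (forbidden[r0, c0]) next
        size <- sample(seq(specks$size_range[1], specks$size_range[2]), 1)
        px <- c(r0 + (c0 - 1L) * nr)
        cur <- c(r0, c0)
        while (length(px) < size) {
          cur <- cur + sample(c(-1L, 0L, 1L), 2, replace = TRUE)
          cur <- pmin(pmax(cur, margin), c(nr - margin, nc - margin))
          px <- union(px, cur[1] + (cur[2] - 1L) * nr)
        }
        rs <- (px - 1L) %% nr + 1L; cs <- (px - 1L) %/% nr + 1L
        if (any(forbidden[cbind(rs, cs)])) next
        img[px] <- img[px] + maxv * 0.5
        forbidden[cbind(pmax(rs - 6, 1), cs)] <- TRUE
        lo_r <- pmax(rs - 6, 1); hi_r <- pmin(rs + 6, nr)
        lo_c <- pmax(cs - 6, 1); hi_c <- pmin(cs + 6, nc)
        for (i in seq_along(px))
          forbidden[lo_r[i]:hi_r[i], lo_c[i]:hi_c[i]] <- TRUE
        placed <- placed + 1L
      }
      if (placed < specks$n)
        warning("could only place ", placed, " of ", specks$n, " specks")
    }
    img <- pmin(pmax(img, 0), maxv)
    chip_image(img, bitdepth = image$bitdepth, pixel_size = image$pixel_size,
               geometry = image$geometry)
  })
}
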