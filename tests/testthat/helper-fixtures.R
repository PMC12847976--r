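# shared fixtures, all built in code

small_geom <- function(n = 256, radius = 0.3 * n)
  chip_geometry(n, n, radius = radius)

# the standard test geometry for synthetic networks
net_geom <- function() chip_geometry(384, 384, radius = 110)

# a horizontal bar rendered as a network stroke, for analytic descriptor
# checks: nominal 100 px long, 5 px wide
bar_network <- function(geom = small_geom(200, 60),
                        from = c(100, 50), to = c(100, 150), width = 5,
                        class = "thick") {
  structure(list(
    branches = list(list(path = rbind(from, to), width = width,
                         class = class)),
    junctions = matrix(numeric(0), 0, 2),
    total_length = sqrt(sum((to - from)^2)),
    areas = c(thick = NA_real_, thin = NA_real_),
    geometry = geom), class = "network_truth")
}

# an exact filled rectangle mask (not stroked), rows x cols
rect_mask <- function(nrow = 60, ncol = 120, r = 30:34, c = 11:110) {
  m <- matrix(FALSE, nrow, ncol)
  m[r, c] <- TRUE
  m
}

# exhaustive per-pixel neighbour-count classification, the independent
# oracle for junction/endpoint detection on small shapes
brute_neighbor_counts <- function(skel) {
  nr <- nrow(skel); nc <- ncol(skel)
  out <- matrix(0L, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!skel[r, c]) next
    s <- 0L
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      r2 <- r + dr; c2 <- c + dc
      if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc && skel[r2, c2])
        s <- s + 1L
    }
    out[r, c] <- s
  }
  out
}

# brute-force grayscale erosion/dilation with a disc, the independent
# oracle for the rolling-ball background estimate
brute_opening <- function(img, radius) {
  ri <- floor(radius)
  off <- expand.grid(dr = -ri:ri, dc = -ri:ri)
  brush <- EBImage::makeBrush(2L * ri + 1L, "disc")
  off <- off[brush[cbind(off$dr + ri + 1L, off$dc + ri + 1L)] > 0, ]
  nr <- nrow(img); nc <- ncol(img)
  ero <- matrix(Inf, nr, nc)
  for (k in seq_len(nrow(off))) {
    sh <- matrix(Inf, nr, nc)
    rs <- max(1, 1 + off$dr[k]):min(nr, nr + off$dr[k])
    cs <- max(1, 1 + off$dc[k]):min(nc, nc + off$dc[k])
    sh[rs, cs] <- img[rs - off$dr[k], cs - off$dc[k]]
    ero <- pmin(ero, sh)
  }
  dil <- matrix(-Inf, nr, nc)
  for (k in seq_len(nrow(off))) {
    sh <- matrix(-Inf, nr, nc)
    rs <- max(1, 1 + off$dr[k]):min(nr, nr + off$dr[k])
    cs <- max(1, 1 + off$dc[k]):min(nc, nc + off$dc[k])
    sh[rs, cs] <- ero[rs - off$dr[k], cs - off$dc[k]]
    dil <- pmax(dil, sh)
  }
  dil
}

# a network meeting the >= 20 branch study condition: deterministically
# re-draws from derived sub-seeds until the condition holds
gen_big_network <- function(geom, seed) {
  for (k in 0:20) {
    net <- generate_network(n_seeds = 4, max_steps = 70, branch_prob = 0.07,
                            geometry = geom, seed = seed + 100000L * k)
    if (length(net$branches) >= 20) return(net)
  }
  stop("no network with >= 20 branches found")
}

# a modest synthetic screen design used across statistics tests
null_design <- function(seed, n_treat = 3, replicates = 4) {
  trts <- stats::setNames(rep(list(list()), n_treat + 1),
                          c("DMSO", paste0("T", seq_len(n_treat))))
  screen_design(donors = "D1", treatments = trts, replicates = replicates,
                control_replicates = 6, plates_per_donor = 1,
                donor_cv = 0.1, plate_cv = 0.1, replicate_cv = 0.15,
                seed = seed)
}
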