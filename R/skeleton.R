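#' Skeletonize a vessel mask
#'
#' Reduces the union of the thin and thick vessel classes to a
#' one-pixel-wide, 8-connected medial skeleton by iterative Guo-Hall
#' thinning.  The procedure preserves topology: connected components and
#' holes of the mask survive in the skeleton (a ring thins to a closed
#' cycle, a disk to a near-point).
#'
#' @param mask A [vessel_mask()] or a logical/0-1 matrix.
#' @return Logical skeleton matrix.
#' @export
skeletonize_mask <- function(mask) {
  m <- if (inherits(mask, "vessel_mask")) mask$labels > 0L else mask > 0
  if (!any(m)) return(m & FALSE)
  p <- matrix(0L, nrow(m) + 2L, ncol(m) + 2L)
  p[2:(nrow(m) + 1L), 2:(ncol(m) + 1L)] <- m * 1L
  repeat {
    changed <- FALSE
    for (iter in 0:1) {
      del <- guo_hall_marker(p, iter)
      if (any(del)) { p[del] <- 0L; changed <- TRUE }
    }
    if (!changed) break
  }
  out <- p[2:(nrow(m) + 1L), 2:(ncol(m) + 1L)] > 0L
  out
}

# One Guo-Hall subiteration: returns the deletion marker for the padded
# image.  Neighbour labels p2..p9 run clockwise from north.
guo_hall_marker <- function(p, iter) {
  nr <- nrow(p); nc <- ncol(p)
  ri <- 2:(nr - 1L); ci <- 2:(nc - 1L)
  ctr <- p[ri, ci]
  p2 <- p[ri - 1L, ci];      p3 <- p[ri - 1L, ci + 1L]
  p4 <- p[ri, ci + 1L];      p5 <- p[ri + 1L, ci + 1L]
  p6 <- p[ri + 1L, ci];      p7 <- p[ri + 1L, ci - 1L]
  p8 <- p[ri, ci - 1L];      p9 <- p[ri - 1L, ci - 1L]
  C <- ((1L - p2) * pmax(p3, p4)) + ((1L - p4) * pmax(p5, p6)) +
       ((1L - p6) * pmax(p7, p8)) + ((1L - p8) * pmax(p9, p2))
  N1 <- pmax(p9, p2) + pmax(p3, p4) + pmax(p5, p6) + pmax(p7, p8)
  N2 <- pmax(p2, p3) + pmax(p4, p5) + pmax(p6, p7) + pmax(p8, p9)
  N <- pmin(N1, N2)
  m <- if (iter == 0) pmax(pmax(p6, p7), 1L - p9) * p8
       else           pmax(pmax(p2, p3), 1L - p5) * p4
  del <- ctr == 1L & C == 1L & N >= 2L & N <= 3L & m == 0L
  full <- matrix(FALSE, nr, nc)
  full[ri, ci] <- del
  full
}

# count of 8-neighbours for each skeleton pixel
neighbor_count <- function(skel) {
  p <- matrix(0L, nrow(skel) + 2L, ncol(skel) + 2L)
  p[2:(nrow(skel) + 1L), 2:(ncol(skel) + 1L)] <- skel * 1L
  nr <- nrow(p); nc <- ncol(p)
  ri <- 2:(nr - 1L); ci <- 2:(nc - 1L)
  s <- p[ri - 1L, ci] + p[ri - 1L, ci + 1L] + p[ri, ci + 1L] +
    p[ri + 1L, ci + 1L] + p[ri + 1L, ci] + p[ri + 1L, ci - 1L] +
    p[ri, ci - 1L] + p[ri - 1L, ci - 1L]
  s * (skel * 1L)
}

#' Build the branch/junction graph of a skeleton
#'
#' Skeleton pixels with three or more 8-neighbours are junction pixels;
#' 8-adjacent junction pixels are merged into a single junction node (so an
#' X-crossing that thins to a small pixel cluster counts once).  Pixels
#' with exactly one neighbour are endpoints.  The remaining pixels form
#' branch paths; each path becomes an edge whose geometric length sums its
#' steps, 1 per axial step and sqrt(2) per diagonal step, plus the steps
#' connecting the path ends to their incident nodes.
#'
#' @param skel Logical skeleton matrix (from [skeletonize_mask()]).
#' @return Object of class `skeleton_graph`: list with `nodes` (data frame:
#'   id, kind in junction/endpoint/isolated, row, col), `edges` (data
#'   frame: node_a, node_b -- `NA` for a free end or pure cycle --, length,
#'   n_pixels) and `skeleton`.
#' @export
build_graph <- function(skel) {
  nb <- neighbor_count(skel)
  nodes <- data.frame(id = integer(0), kind = character(0),
                      row = numeric(0), col = numeric(0))
  edges <- data.frame(node_a = integer(0), node_b = integer(0),
                      length = numeric(0), n_pixels = integer(0))
  if (!any(skel))
    return(structure(list(nodes = nodes, edges = edges, skeleton = skel),
                     class = "skeleton_graph"))
  nr <- nrow(skel)
  junc_px <- skel & nb >= 3L
  junc_lab <- label8(junc_px)
  n_junc <- max(junc_lab)
  node_list <- list()
  if (n_junc > 0) {
    jidx <- which(junc_lab > 0L)
    jl <- junc_lab[jidx]
    jr <- (jidx - 1L) %% nr + 1L; jc <- (jidx - 1L) %/% nr + 1L
    node_list[[1]] <- data.frame(
      id = seq_len(n_junc), kind = "junction",
      row = as.numeric(tapply(jr, jl, mean)),
      col = as.numeric(tapply(jc, jl, mean)))
    junc_members <- split(data.frame(r = jr, c = jc), jl)
  } else junc_members <- list()
  wiso <- which(skel & nb == 0L)
  if (length(wiso))
    node_list[[length(node_list) + 1L]] <- data.frame(
      id = n_junc + seq_along(wiso), kind = "isolated",
      row = (wiso - 1L) %% nr + 1L, col = (wiso - 1L) %/% nr + 1L)
  nodes <- if (length(node_list)) do.call(rbind, node_list) else nodes

  # arcs: skeleton minus junction pixels
  arc_mask <- skel & !junc_px & nb > 0L
  arc_lab <- label8(arc_mask)
  n_arc <- max(arc_lab)
  aidx <- which(arc_lab > 0L)
  arc_members <- split(aidx, arc_lab[aidx])
  edge_list <- vector("list", n_arc)
  ep_nodes <- list()
  ep_node <- new.env()
  add_endpoint <- function(r, c) {
    key <- paste(r, c)
    if (is.null(ep_node[[key]])) {
      id <- nrow(nodes) + length(ep_nodes) + 1L
      ep_nodes[[length(ep_nodes) + 1L]] <<-
        data.frame(id = id, kind = "endpoint", row = r, col = c)
      ep_node[[key]] <- id
    }
    ep_node[[key]]
  }
  for (a in seq_len(n_arc)) {
    px <- arc_members[[a]]
    rs <- (px - 1L) %% nr + 1L; cs <- (px - 1L) %/% nr + 1L
    path <- order_arc(rs, cs)
    plen <- path_length(path)
    npx <- length(px)
    ends <- list(path[1, ], path[nrow(path), ])
    node_ids <- c(NA_integer_, NA_integer_)
    extra <- 0
    if (npx == 1L) {
      r0 <- path[1, 1]; c0 <- path[1, 2]
      rsn <- pmax(r0 - 1, 1):pmin(r0 + 1, nr)
      csn <- pmax(c0 - 1, 1):pmin(c0 + 1, ncol(skel))
      jl <- junc_lab[rsn, csn, drop = FALSE]
      jids <- unique(jl[jl > 0L])
      for (e in seq_len(min(2L, length(jids)))) {
        node_ids[e] <- jids[e]
        jm <- junc_members[[as.character(jids[e])]]
        extra <- extra + min(sqrt((jm$r - r0)^2 + (jm$c - c0)^2))
      }
      if (length(jids) == 1L)
        node_ids[2] <- add_endpoint(r0, c0)  # terminal stub
      edge_list[[a]] <- data.frame(node_a = node_ids[1], node_b = node_ids[2],
                                   length = max(extra, 1), n_pixels = 1L)
      next
    }
    # a closed cycle: path ends 8-adjacent with no free endpoint -- close
    # the loop geometrically instead of inventing endpoint nodes
    touches_junction <- any(vapply(ends, function(en) {
      rsn <- pmax(en[1] - 1, 1):pmin(en[1] + 1, nr)
      csn <- pmax(en[2] - 1, 1):pmin(en[2] + 1, ncol(skel))
      any(junc_lab[rsn, csn] > 0L)
    }, logical(1)))
    if (npx > 2L && !touches_junction &&
        max(abs(ends[[1]] - ends[[2]])) == 1L &&
        nb[ends[[1]][1], ends[[1]][2]] == 2L &&
        nb[ends[[2]][1], ends[[2]][2]] == 2L) {
      step <- if (sum(abs(ends[[1]] - ends[[2]])) == 2L) sqrt(2) else 1
      edge_list[[a]] <- data.frame(node_a = NA_integer_,
                                   node_b = NA_integer_,
                                   length = plen + step, n_pixels = npx)
      next
    }
    for (e in 1:2) {
      r0 <- ends[[e]][1]; c0 <- ends[[e]][2]
      # adjacent junction clusters
      rsn <- pmax(r0 - 1, 1):pmin(r0 + 1, nr)
      csn <- pmax(c0 - 1, 1):pmin(c0 + 1, ncol(skel))
      jl <- junc_lab[rsn, csn, drop = FALSE]
      jids <- unique(jl[jl > 0L])
      if (length(jids)) {
        jid <- jids[1]
        node_ids[e] <- jid
        # connection step to the nearest pixel of that junction cluster
        jm <- junc_members[[as.character(jid)]]
        extra <- extra + min(sqrt((jm$r - r0)^2 + (jm$c - c0)^2))
      } else {
        node_ids[e] <- add_endpoint(r0, c0)
      }
    }
    edge_list[[a]] <- data.frame(node_a = node_ids[1], node_b = node_ids[2],
                                 length = plen + extra, n_pixels = npx)
  }
  if (length(ep_nodes)) nodes <- rbind(nodes, do.call(rbind, ep_nodes))
  if (n_arc > 0) edges <- do.call(rbind, edge_list)
  # direct junction-junction adjacencies with no arc pixel between them
  if (n_junc > 1) {
    adj <- junction_adjacencies(junc_lab)
    if (nrow(adj)) {
      have <- paste(pmin(edges$node_a, edges$node_b),
                    pmax(edges$node_a, edges$node_b))
      for (i in seq_len(nrow(adj))) {
        key <- paste(min(adj[i, 1:2]), max(adj[i, 1:2]))
        if (!(key %in% have)) {
          edges <- rbind(edges, data.frame(node_a = adj[i, 1],
                                           node_b = adj[i, 2],
                                           length = adj[i, 3], n_pixels = 0L))
          have <- c(have, key)
        }
      }
    }
  }
  structure(list(nodes = nodes, edges = edges, skeleton = skel),
            class = "skeleton_graph")
}

#' @export
print.skeleton_graph <- function(x, ...) {
  cat(sprintf("skeleton_graph: %d junctions, %d endpoints, %d edges, total length %.1f px\n",
              sum(x$nodes$kind == "junction"), sum(x$nodes$kind == "endpoint"),
              nrow(x$edges), sum(x$edges$length)))
  invisible(x)
}

# order the pixels of a simple arc (each pixel has <= 2 neighbours within
# the arc) into a path; for a closed cycle an arbitrary start is used.
order_arc <- function(rs, cs) {
  n <- length(rs)
  if (n == 1L) return(cbind(rs, cs))
  key <- paste(rs, cs)
  idx <- seq_len(n)
  adj <- vector("list", n)
  lut <- new.env()
  for (i in idx) lut[[key[i]]] <- i
  for (i in idx) {
    nbr <- integer(0)
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      j <- lut[[paste(rs[i] + dr, cs[i] + dc)]]
      if (!is.null(j)) nbr <- c(nbr, j)
    }
    adj[[i]] <- nbr
  }
  deg <- lengths(adj)
  start <- if (any(deg == 1L)) which(deg == 1L)[1] else 1L
  path <- integer(n); path[1] <- start
  visited <- logical(n); visited[start] <- TRUE
  for (k in 2:n) {
    cur <- path[k - 1L]
    nxt <- adj[[cur]][!visited[adj[[cur]]]]
    if (!length(nxt)) { path <- path[1:(k - 1L)]; break }
    # prefer axial over diagonal steps to avoid corner cutting
    if (length(nxt) > 1L) {
      dd <- abs(rs[nxt] - rs[cur]) + abs(cs[nxt] - cs[cur])
      nxt <- nxt[order(dd)]
    }
    path[k] <- nxt[1]
    visited[nxt[1]] <- TRUE
  }
  cbind(rs[path], cs[path])
}

# geometric length of an ordered pixel path: 1 per axial, sqrt(2) per
# diagonal step
path_length <- function(path) {
  if (nrow(path) < 2L) return(0)
  d <- abs(diff(path))
  sum(ifelse(d[, 1] + d[, 2] == 2L, sqrt(2), 1))
}

# neighbouring junction-cluster pairs (touching clusters are distinct only
# if label8 separated them, so this finds clusters joined through
# 8-adjacency across a gap of 0 arc pixels -- rare, but keeps every
# skeleton pixel accounted for)
junction_adjacencies <- function(junc_lab) {
  nr <- nrow(junc_lab); nc <- ncol(junc_lab)
  out <- matrix(numeric(0), 0, 3)
  for (off in list(c(1, 0), c(0, 1), c(1, 1), c(1, -1))) {
    sh <- shift_matrix(junc_lab, off[1], off[2])
    both <- !is.na(sh) & junc_lab > 0L & sh > 0L & junc_lab != sh
    if (any(both)) {
      l1 <- pmin(junc_lab[both], sh[both])
      l2 <- pmax(junc_lab[both], sh[both])
      out <- rbind(out, cbind(l1, l2, sqrt(sum(off^2))))
    }
  }
  unique(out)
}

#' Prune short terminal spurs from a skeleton
#'
#' Removes edges shorter than `min_len` pixels that end at a free endpoint
#' (skeletonization artifacts at vessel boundaries), then returns the
#' cleaned skeleton.  Junction pixels are retained.
#'
#' @param skel Logical skeleton matrix.
#' @param min_len Minimum terminal branch length to keep (default 3).
#' @return Pruned logical skeleton matrix.
#' @export
prune_spurs <- function(skel, min_len = 3) {
  g <- build_graph(skel)
  if (!nrow(g$edges)) return(skel)
  ep_ids <- g$nodes$id[g$nodes$kind == "endpoint"]
  drop <- which(g$edges$length < min_len &
                  (g$edges$node_a %in% ep_ids | g$edges$node_b %in% ep_ids))
  if (!length(drop)) return(skel)
  nb <- neighbor_count(skel)
  junc_px <- skel & nb >= 3L
  arc_lab <- label8(skel & !junc_px & nb > 0L)
  # arcs were labelled in the same order edges were built
  arc_edge_rows <- which(g$edges$n_pixels > 0L)
  out <- skel
  for (d in drop) {
    k <- match(d, arc_edge_rows)
    if (!is.na(k)) out[arc_lab == k] <- FALSE
  }
  out
}
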