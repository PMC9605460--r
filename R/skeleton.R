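# Centerline extraction: thinning, spur pruning, branch/end point detection,
# and ordered segment tracing. All rasters are logical matrices indexed
# [row, col]; neighborhoods are 8-connected throughout.

# Shift a logical matrix by (dr, dc) with FALSE fill.
shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

NEIGHBOR_OFFSETS <- rbind( # clockwise scan starting north
  c(-1L, 0L), c(-1L, 1L), c(0L, 1L), c(1L, 1L),
  c(1L, 0L), c(1L, -1L), c(0L, -1L), c(-1L, -1L)
)

# Count of 8-connected foreground neighbors at every pixel.
neighbor_count <- function(m) {
  acc <- matrix(0L, nrow(m), ncol(m))
  for (i in seq_len(8)) {
    acc <- acc + shift_mat(m, NEIGHBOR_OFFSETS[i, 1], NEIGHBOR_OFFSETS[i, 2])
  }
  acc
}

#' Extract the centerline skeleton of a binary vessel mask
#'
#' Iterative topology-preserving thinning (Guo–Hall two-subiteration
#' scheme): pixels are peeled from alternating sides of the vessel until a
#' 1-pixel-wide, 8-connected medial line remains, without the 4-connected
#' staircase corners simpler schemes leave behind. Every skeleton pixel lies
#' on the input foreground.
#'
#' @param mask Logical matrix (`TRUE` = vessel), e.g. from [read_mask()] or
#'   [rasterize_curve()].
#' @return Logical matrix of the same shape: the skeleton.
#' @export
skeletonize <- function(mask) {
  if (!is.matrix(mask)) abort("mask must be a matrix")
  mask <- mask > 0
  if (!any(mask)) abort("empty mask: no foreground pixel")
  img <- mask
  repeat {
    changed <- FALSE
    for (phase in 1:2) {
      # neighbor rasters p2..p9 = N, NE, E, SE, S, SW, W, NW
      p <- lapply(seq_len(8), function(i) {
        shift_mat(img, NEIGHBOR_OFFSETS[i, 1], NEIGHBOR_OFFSETS[i, 2])
      })
      # C: number of distinct background runs around the pixel
      cc <- (!p[[1]] & (p[[2]] | p[[3]])) + (!p[[3]] & (p[[4]] | p[[5]])) +
            (!p[[5]] & (p[[6]] | p[[7]])) + (!p[[7]] & (p[[8]] | p[[1]]))
      n1 <- (p[[8]] | p[[1]]) + (p[[2]] | p[[3]]) +
            (p[[4]] | p[[5]]) + (p[[6]] | p[[7]])
      n2 <- (p[[1]] | p[[2]]) + (p[[3]] | p[[4]]) +
            (p[[5]] | p[[6]]) + (p[[7]] | p[[8]])
      nn <- pmin(n1, n2)
      m <- if (phase == 1) {
        (p[[1]] | p[[2]] | !p[[4]]) & p[[3]]
      } else {
        (p[[5]] | p[[6]] | !p[[8]]) & p[[7]]
      }
      del <- img & cc == 1 & nn >= 2 & nn <= 3 & !m
      if (any(del)) {
        img[del] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  img
}

#' Remove short spur branches from a skeleton
#'
#' A spur is an endpoint-terminated chain, shorter than `max_spur_length`
#' pixels, that terminates at a branch point — a thinning artifact, not a
#' vessel. Spurs are removed iteratively until a fixed point is reached, so
#' spurs revealed by earlier removals are pruned too. The operation is
#' idempotent and preserves the path topology between surviving branch
#' points.
#'
#' @param skel Logical skeleton matrix from [skeletonize()].
#' @param max_spur_length Maximum chain length (in pixels, branch pixel
#'   excluded) that is still considered a spur.
#' @return Pruned skeleton (logical matrix).
#' @export
prune_spurs <- function(skel, max_spur_length = 5) {
  repeat {
    nb <- neighbor_count(skel)
    ends <- which(skel & nb == 1, arr.ind = TRUE)
    # pseudo-endpoints: degree-2 pixels whose two neighbors touch each other
    # (the tip of a junction "L" triangle) behave as spur tips too
    cand2 <- which(skel & nb == 2, arr.ind = TRUE)
    if (nrow(cand2)) {
      tri <- vapply(seq_len(nrow(cand2)), function(i) {
        nbrs <- sweep(NEIGHBOR_OFFSETS, 2, cand2[i, ], `+`)
        nbrs <- nbrs[nbrs[, 1] >= 1 & nbrs[, 1] <= nrow(skel) &
                     nbrs[, 2] >= 1 & nbrs[, 2] <= ncol(skel), , drop = FALSE]
        on <- nbrs[skel[nbrs], , drop = FALSE]
        nrow(on) == 2 && max(abs(on[1, ] - on[2, ])) <= 1
      }, logical(1))
      ends <- rbind(ends, cand2[tri, , drop = FALSE])
    }
    removed_any <- FALSE
    for (e in seq_len(nrow(ends))) {
      path <- walk_chain(skel, nb, ends[e, ], max_steps = max_spur_length)
      if (path$hit_branch && nrow(path$pixels) < max_spur_length) {
        skel[path$pixels] <- FALSE
        removed_any <- TRUE
        nb <- neighbor_count(skel) # degrees change as spurs fall away
      }
    }
    if (!removed_any) break
    # re-thin: removing a spur can expose a redundant junction pixel (the
    # stub of an "L" triangle); the thinning fixed point clears it
    if (any(skel)) skel <- skeletonize(skel)
  }
  skel
}

# Walk from an endpoint along a degree-<=2 chain. Stops after `max_steps`
# collected pixels, at a branch pixel (degree >= 3), or when the chain ends.
walk_chain <- function(skel, nb, start, max_steps) {
  pixels <- matrix(integer(0), 0, 2)
  cur <- as.integer(start)
  hit_branch <- FALSE
  repeat {
    pixels <- rbind(pixels, cur)
    if (nrow(pixels) >= max_steps) break
    nxt <- NULL
    for (i in seq_len(8)) {
      cand <- cur + NEIGHBOR_OFFSETS[i, ]
      if (cand[1] < 1 || cand[1] > nrow(skel) ||
          cand[2] < 1 || cand[2] > ncol(skel)) next
      if (!skel[cand[1], cand[2]]) next
      if (any(pixels[, 1] == cand[1] & pixels[, 2] == cand[2])) next
      if (nb[cand[1], cand[2]] >= 3) {
        hit_branch <- TRUE
        nxt <- NULL
        break
      }
      nxt <- cand
      break
    }
    if (is.null(nxt)) break
    cur <- nxt
  }
  dimnames(pixels) <- NULL
  list(pixels = pixels, hit_branch = hit_branch)
}

# All pixels with >= 3 skeleton neighbors (ungrouped branch candidates).
branch_pixels <- function(skel) {
  which(skel & neighbor_count(skel) >= 3, arr.ind = TRUE)
}

# 8-connected components of a pixel set given as an n x 2 (row, col) matrix.
# Returns an integer membership vector of length n.
pixel_components <- function(px) {
  n <- nrow(px)
  if (n == 0) return(integer(0))
  key <- paste(px[, 1], px[, 2])
  idx <- stats::setNames(seq_len(n), key)
  edges <- list()
  for (i in seq_len(8)) {
    nk <- paste(px[, 1] + NEIGHBOR_OFFSETS[i, 1], px[, 2] + NEIGHBOR_OFFSETS[i, 2])
    hit <- !is.na(idx[nk])
    if (any(hit)) edges[[length(edges) + 1]] <- cbind(which(hit), idx[nk[hit]])
  }
  g <- igraph::graph_from_edgelist(
    if (length(edges)) do.call(rbind, edges) else matrix(integer(0), 0, 2),
    directed = FALSE
  )
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  igraph::components(g)$membership[seq_len(n)]
}

#' Detect branch points of a skeleton
#'
#' Pixels with three or more 8-connected skeleton neighbors mark vessel
#' crossings and bifurcations. Adjacent branch pixels (one crossing often
#' thins to a small cluster) are merged by 8-connected labeling and each
#' cluster is reported by one representative: the member pixel closest to the
#' cluster centroid.
#'
#' @param skel Logical skeleton matrix.
#' @return Tibble with columns `row`, `col`, `cluster_size`; zero rows for a
#'   branchless skeleton.
#' @export
detect_branch_points <- function(skel) {
  bp <- branch_pixels(skel)
  if (nrow(bp) == 0) {
    return(tibble(row = integer(0), col = integer(0), cluster_size = integer(0)))
  }
  memb <- pixel_components(bp)
  reps <- purrr::map(sort(unique(memb)), function(m) {
    px <- bp[memb == m, , drop = FALSE]
    rep <- cluster_representative(px)
    tibble(row = rep[1], col = rep[2], cluster_size = nrow(px))
  })
  dplyr::arrange(dplyr::bind_rows(reps), .data$row, .data$col)
}

#' Detect end points of a skeleton
#'
#' @param skel Logical skeleton matrix.
#' @return Tibble with columns `row`, `col`: pixels with exactly one
#'   8-connected skeleton neighbor.
#' @export
detect_end_points <- function(skel) {
  ep <- which(skel & neighbor_count(skel) == 1, arr.ind = TRUE)
  dplyr::arrange(tibble(row = as.integer(ep[, 1]), col = as.integer(ep[, 2])),
                 .data$row, .data$col)
}

#' Split a skeleton into ordered vessel segments
#'
#' Removes branch-point pixels from the skeleton so the vasculature falls
#' apart into simple chains, then traces each chain into an ordered point
#' list. Two kinds of fragments are discarded: junction ("L"-shaped)
#' artifacts, i.e. chains lying entirely within `junction_radius` (Chebyshev)
#' of a branch pixel, and chains with fewer than `min_segment_points` points,
#' which are too short to carry curvature information. Tracing starts at the
#' lexicographically smallest chain endpoint (closed rings: smallest pixel)
#' and advances by a clockwise neighbor scan starting north, so the point
#' order is deterministic.
#'
#' @param skel Logical skeleton matrix.
#' @param image_id Identifier copied into every row.
#' @param min_segment_points Minimum number of points for a kept segment.
#' @param junction_radius Chebyshev radius (pixels) around branch pixels used
#'   to flag junction artifacts.
#' @return Tibble with columns `image_id`, `segment_id`, `point_index`,
#'   `row`, `col`. Attribute `"accounting"` carries the exact pixel budget
#'   (skeleton = segment + branch + discarded pixels).
#' @export
extract_segments <- function(skel, image_id = "image",
                             min_segment_points = 5, junction_radius = 2) {
  empty <- tibble(image_id = character(0), segment_id = integer(0),
                  point_index = integer(0), row = integer(0), col = integer(0))
  if (!any(skel)) {
    attr(empty, "accounting") <- list(n_skeleton = 0L, n_segment = 0L,
                                      n_branch = 0L, n_discarded = 0L)
    return(empty)
  }
  bp <- branch_pixels(skel)
  rest <- skel
  if (nrow(bp) > 0) rest[bp] <- FALSE
  px <- which(rest, arr.ind = TRUE)
  acct <- list(n_skeleton = sum(skel), n_segment = 0L,
               n_branch = nrow(bp), n_discarded = 0L)
  if (nrow(px) == 0) {
    acct$n_discarded <- 0L
    attr(empty, "accounting") <- acct
    return(empty)
  }
  memb <- pixel_components(px)
  # deterministic component order: by smallest (row, col) member
  comp_ids <- sort(unique(memb))
  first_px <- t(vapply(comp_ids, function(m) {
    p <- px[memb == m, , drop = FALSE]
    p[order(p[, 1], p[, 2])[1], ]
  }, integer(2)))
  comp_ids <- comp_ids[order(first_px[, 1], first_px[, 2])]

  segments <- list()
  seg_id <- 0L
  for (m in comp_ids) {
    p <- px[memb == m, , drop = FALSE]
    if (nrow(bp) > 0 && all_near_branch(p, bp, junction_radius)) {
      acct$n_discarded <- acct$n_discarded + nrow(p)
      next
    }
    if (nrow(p) < min_segment_points) {
      acct$n_discarded <- acct$n_discarded + nrow(p)
      next
    }
    ordered <- trace_chain(p)
    seg_id <- seg_id + 1L
    segments[[seg_id]] <- tibble(
      image_id = image_id, segment_id = seg_id,
      point_index = seq_len(nrow(ordered)),
      row = as.integer(ordered[, 1]), col = as.integer(ordered[, 2])
    )
    acct$n_segment <- acct$n_segment + nrow(ordered)
  }
  out <- if (length(segments)) dplyr::bind_rows(segments) else empty
  attr(out, "accounting") <- acct
  attr(out, "branch_points") <- detect_branch_points(skel)
  out
}

# TRUE when every pixel of `p` lies within Chebyshev distance `radius` of
# some branch pixel.
all_near_branch <- function(p, bp, radius) {
  for (i in seq_len(nrow(p))) {
    d <- pmax(abs(bp[, 1] - p[i, 1]), abs(bp[, 2] - p[i, 2]))
    if (min(d) > radius) return(FALSE)
  }
  TRUE
}

# Order the pixels of a degree-<=2 chain (path or ring) into a traversal.
trace_chain <- function(p) {
  n <- nrow(p)
  if (n == 1) return(p)
  key <- paste(p[, 1], p[, 2])
  idx <- stats::setNames(seq_len(n), key)
  deg <- integer(n)
  for (i in seq_len(8)) {
    nk <- paste(p[, 1] + NEIGHBOR_OFFSETS[i, 1], p[, 2] + NEIGHBOR_OFFSETS[i, 2])
    deg <- deg + !is.na(idx[nk])
  }
  ends <- which(deg <= 1)
  start <- if (length(ends)) {
    ends[order(p[ends, 1], p[ends, 2])[1]]
  } else { # ring
    order(p[, 1], p[, 2])[1]
  }
  visited <- logical(n)
  path <- integer(n)
  cur <- start
  for (k in seq_len(n)) {
    path[k] <- cur
    visited[cur] <- TRUE
    nxt <- NA_integer_
    for (i in seq_len(8)) {
      cand <- idx[paste(p[cur, 1] + NEIGHBOR_OFFSETS[i, 1],
                        p[cur, 2] + NEIGHBOR_OFFSETS[i, 2])]
      if (!is.na(cand) && !visited[cand]) {
        nxt <- cand
        break
      }
    }
    if (is.na(nxt)) break
    cur <- nxt
  }
  p[path[path > 0], , drop = FALSE]
}
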