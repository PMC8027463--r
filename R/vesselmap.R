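# Shift a matrix by (dr, dc) with zero fill; helper for neighborhood ops.
shift_mat <- function(m, dr, dc) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0, h, w)
  rs <- max(1, 1 + dr):min(h, h + dr)
  cs <- max(1, 1 + dc):min(w, w + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# Shift with edge replication: derivatives computed from these vanish at
# the frame border instead of producing spurious ridges.
shift_mat_rep <- function(m, dr, dc) {
  h <- nrow(m); w <- ncol(m)
  ri <- pmin(pmax(seq_len(h) - dr, 1), h)
  ci <- pmin(pmax(seq_len(w) - dc, 1), w)
  m[ri, ci]
}

# Gaussian smoothing with edge-replicated padding (no circular wrap, and
# kernels larger than small frames are truncated instead of failing).
gaussian_smooth <- function(x, sigma) {
  h <- nrow(x); w <- ncol(x)
  r <- max(1L, min(ceiling(3 * sigma), h - 1L, w - 1L))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  pad <- x[c(rep(1, r), seq_len(h), rep(h, r)),
           c(rep(1, r), seq_len(w), rep(w, r))]
  sm <- EBImage::filter2(pad, outer(k, k))
  as.matrix(sm)[r + seq_len(h), r + seq_len(w)]
}

#' Multiscale vesselness filter (dark tubular structures)
#'
#' Hessian-eigenvalue ridge measure in the Frangi style, oriented for dark
#' vessels on a bright scleral background: at each scale the frame is
#' Gaussian-smoothed, the scale-normalized Hessian eigenvalues
#' \eqn{|\lambda_1| \le |\lambda_2|} computed, and pixels with
#' \eqn{\lambda_2 > 0} (dark ridge) scored by blobness
#' \eqn{\exp(-R_b^2/2\beta^2)} and structure strength
#' \eqn{1 - \exp(-S^2/2c^2)}. The response is the per-pixel maximum over
#' scales, normalized to `[0, 1]`.
#'
#' The default scales cover vessel radii from a couple of pixels to a dozen,
#' matching conjunctival vessels of roughly 5-45 um at typical slit-lamp
#' calibrations.
#'
#' @param frame Numeric intensity matrix.
#' @param scales Gaussian standard deviations in pixels (all positive).
#' @param beta Blobness sensitivity (Frangi beta), default 0.5.
#' @return Response matrix in `[0, 1]`.
#' @export
vesselness_filter <- function(frame, scales = c(1.5, 3, 6, 9, 12), beta = 0.5) {
  stopifnot(is.matrix(frame), length(scales) > 0, all(scales > 0))
  h <- nrow(frame); w <- ncol(frame)
  best <- matrix(0, h, w)
  for (s in scales) {
    sm <- gaussian_smooth(frame, s)
    # central-difference Hessian, gamma = 2 scale normalization
    dyy <- shift_mat_rep(sm, -1, 0) + shift_mat_rep(sm, 1, 0) - 2 * sm
    dxx <- shift_mat_rep(sm, 0, -1) + shift_mat_rep(sm, 0, 1) - 2 * sm
    dxy <- (shift_mat_rep(sm, -1, -1) + shift_mat_rep(sm, 1, 1) -
              shift_mat_rep(sm, -1, 1) - shift_mat_rep(sm, 1, -1)) / 4
    dyy <- dyy * s^2; dxx <- dxx * s^2; dxy <- dxy * s^2
    # the outermost ring only has one-sided differences; no usable Hessian
    ring <- function(m) {
      m[c(1, h), ] <- 0; m[, c(1, w)] <- 0; m
    }
    dyy <- ring(dyy); dxx <- ring(dxx); dxy <- ring(dxy)
    tmp <- sqrt(((dxx - dyy) / 2)^2 + dxy^2)
    mid <- (dxx + dyy) / 2
    la <- mid - tmp; lb <- mid + tmp
    swap <- abs(la) > abs(lb)
    lam1 <- ifelse(swap, lb, la)  # smaller magnitude
    lam2 <- ifelse(swap, la, lb)  # larger magnitude
    S2 <- lam1^2 + lam2^2
    cpar <- sqrt(max(S2)) / 2
    if (cpar <= 1e-10) next
    Rb2 <- ifelse(lam2 != 0, (lam1 / lam2)^2, 0)
    v <- exp(-Rb2 / (2 * beta^2)) * (1 - exp(-S2 / (2 * cpar^2)))
    v[lam2 <= 0] <- 0  # keep dark ridges only
    best <- pmax(best, v)
  }
  m <- max(best)
  if (m > 0) best <- best / m
  best
}

#' Binarize a vesselness response by hysteresis thresholding
#'
#' Pixels above `high * max(response)` seed vessels; connected regions above
#' `low * max(response)` that contain a seed survive. Components smaller
#' than `min_area` pixels are removed. A permissive low threshold keeps thin
#' vessels connected to their stronger trunks.
#'
#' When the intensity `frame` is supplied, the detection mask is refined to
#' the full-width-at-half-maximum convention: per connected component, the
#' vessel is the region (within a dilation of the detection) where the
#' darkening below the local background exceeds half the component's peak
#' darkening. The vesselness response finds vessels robustly but its
#' support tracks curvature strength, not lumen width; the half-depth
#' contour of the intensity profile is the width convention under
#' slit-lamp blur, and for a hard-edged vessel any half-depth cut recovers
#' the same support.
#'
#' @param response Vesselness response in `[0, 1]`.
#' @param low,high Threshold fractions of the response maximum.
#' @param min_area Minimum connected-component area in pixels.
#' @param frame Optional intensity frame enabling half-depth refinement.
#' @param dilate_px Dilation radius (pixels) used for background estimation.
#' @param min_depth Minimum peak darkening below the local background for a
#'   component to count as a vessel (intensity units); shallow ridges below
#'   it are background texture, not vessels. Applied only when `frame` is
#'   given.
#' @return Object of class `vessel_mask`: list with logical matrix `binary`
#'   and the input `vesselness`.
#' @export
binarize <- function(response, low = 0.05, high = 0.15, min_area = 30,
                     frame = NULL, dilate_px = 6, min_depth = 0.08) {
  stopifnot(is.matrix(response), low > 0, high >= low)
  m <- max(response)
  if (m <= 0) {
    return(structure(list(binary = matrix(FALSE, nrow(response), ncol(response)),
                          vesselness = response), class = "vessel_mask"))
  }
  lo <- response >= low * m
  hi <- response >= high * m
  lab <- EBImage::bwlabel(lo * 1)
  keep_ids <- unique(lab[hi & lab > 0])
  bin <- matrix(lab %in% keep_ids & lab > 0, nrow(response), ncol(response))
  if (min_area > 0 && any(bin)) {
    lab2 <- EBImage::bwlabel(bin * 1)
    sizes <- tabulate(lab2[lab2 > 0])
    small <- which(sizes < min_area)
    if (length(small)) bin[lab2 %in% small] <- FALSE
  }
  if (!is.null(frame) && any(bin)) {
    bin <- refine_half_depth(bin, frame, dilate_px, min_depth)
  }
  structure(list(binary = bin, vesselness = response), class = "vessel_mask")
}

# Half-depth (FWHM) refinement of a detection mask against the intensity
# frame. Each pixel is compared with the peak darkening in its own
# neighborhood (grayscale dilation), so a vessel whose darkness varies
# along its length is cut at the local half-depth per cross-section, not
# at one global threshold; a global floor keeps background speckle from
# qualifying against its own faint local peaks. Per connected component,
# so vessels of different contrast are measured independently.
refine_half_depth <- function(bin, frame, dilate_px = 6, min_depth = 0) {
  h <- nrow(bin); w <- ncol(bin)
  brush <- EBImage::makeBrush(2 * dilate_px + 1, shape = "disc")
  dil_all <- EBImage::dilate(bin * 1, brush) > 0
  outside <- !dil_all
  bg <- if (any(outside)) stats::median(frame[outside]) else max(frame)
  depth <- bg - frame
  lab <- EBImage::bwlabel(bin * 1)
  out <- matrix(FALSE, h, w)
  for (i in seq_len(max(lab))) {
    comp <- lab == i
    if (!any(comp)) next
    dmax <- max(depth[comp])
    if (dmax < min_depth) next   # too shallow to be a vessel
    if (dmax <= 0) { out <- out | comp; next }
    # neighborhood radius: generous enough that every within-vessel pixel
    # sees its cross-section's centreline peak
    r_loc <- min(25L, max(dilate_px, ceiling(2.5 * max(as.matrix(
      EBImage::distmap(comp * 1))))))
    peak_brush <- EBImage::makeBrush(2 * r_loc + 1, shape = "disc")
    local_peak <- as.matrix(EBImage::dilate(depth, peak_brush))
    half <- depth >= pmax(0.5 * local_peak, 0.25 * dmax)
    # keep the connected part of the half-depth set touching the
    # detection; a wide flat-bottomed vessel whose ridge response fires
    # only on the edges is recovered in full this way
    lab2 <- EBImage::bwlabel(half * 1)
    ids <- unique(lab2[half & comp])
    ids <- ids[ids > 0]
    ref <- if (length(ids)) matrix(lab2 %in% ids, h) else comp
    out <- out | ref
  }
  out
}

#' @export
print.vessel_mask <- function(x, ...) {
  cat(sprintf("<vessel_mask> %d x %d, %d vessel pixels (%.1f%%)\n",
              nrow(x$binary), ncol(x$binary), sum(x$binary),
              100 * mean(x$binary)))
  invisible(x)
}

#' Skeletonize a vessel mask
#'
#' Topology-preserving two-subiteration (Guo-Hall) thinning to a
#' 1-pixel-wide, 8-connected centreline, followed by removal of redundant
#' staircase pixels. Connected components of the mask map one-to-one onto
#' components of the skeleton. Guo-Hall is used rather than Zhang-Suen
#' because the latter erodes even-width diagonal runs completely.
#'
#' @param mask A `vessel_mask` or logical matrix.
#' @return Logical skeleton matrix.
#' @export
skeletonize_mask <- function(mask) {
  bin <- if (inherits(mask, "vessel_mask")) mask$binary else mask
  stopifnot(is.matrix(bin))
  img <- (bin != 0) * 1
  repeat {
    changed <- FALSE
    for (iter in 0:1) {
      # clockwise neighbours from north: P2..P9
      p2 <- shift_mat(img, 1, 0);  p3 <- shift_mat(img, 1, -1)
      p4 <- shift_mat(img, 0, -1); p5 <- shift_mat(img, -1, -1)
      p6 <- shift_mat(img, -1, 0); p7 <- shift_mat(img, -1, 1)
      p8 <- shift_mat(img, 0, 1);  p9 <- shift_mat(img, 1, 1)
      C <- ((1 - p2) * pmax(p3, p4)) + ((1 - p4) * pmax(p5, p6)) +
        ((1 - p6) * pmax(p7, p8)) + ((1 - p8) * pmax(p9, p2))
      N1 <- pmax(p9, p2) + pmax(p3, p4) + pmax(p5, p6) + pmax(p7, p8)
      N2 <- pmax(p2, p3) + pmax(p4, p5) + pmax(p6, p7) + pmax(p8, p9)
      N <- pmin(N1, N2)
      m <- if (iter == 0) pmax(p6, p7, 1 - p9) * p8 else pmax(p2, p3, 1 - p5) * p4
      cond <- img == 1 & C == 1 & N >= 2 & N <= 3 & m == 0
      if (any(cond)) {
        img[cond] <- 0
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  minimal_skeleton(img == 1)
}

# Yokoi 8-connectivity number of the neighborhood of one pixel;
# 1 means the pixel is simple (removable without changing topology).
yokoi_c8 <- function(x) {
  # x: neighbors counterclockwise from east: E, NE, N, NW, W, SW, S, SE
  xb <- 1 - x
  x9 <- c(xb, xb[1], xb[2])
  sum(vapply(c(1, 3, 5, 7), function(k) {
    x9[k] - x9[k] * x9[k + 1] * x9[k + 2]
  }, numeric(1)))
}

# Remove redundant "thick corner" pixels that thinning leaves on diagonal
# runs: a non-endpoint pixel whose neighborhood stays connected without it
# is deleted, sequentially, until the skeleton is minimally 8-connected.
minimal_skeleton <- function(skel) {
  h <- nrow(skel); w <- ncol(skel)
  off <- rbind(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1),
               c(0, -1), c(1, -1), c(1, 0), c(1, 1))
  repeat {
    changed <- FALSE
    px <- which(skel, arr.ind = TRUE)
    px <- px[order(px[, 1], px[, 2]), , drop = FALSE]
    for (i in seq_len(nrow(px))) {
      r <- px[i, 1]; c <- px[i, 2]
      if (!skel[r, c]) next
      nb <- vapply(seq_len(8), function(k) {
        rr <- r + off[k, 1]; cc <- c + off[k, 2]
        rr >= 1 && rr <= h && cc >= 1 && cc <= w && skel[rr, cc]
      }, logical(1))
      # >= 3 neighbours: removing a 2-neighbour simple pixel would erode
      # thick diagonal runs from their ends instead of just unsticking
      # staircase corners
      if (sum(nb) >= 3 && yokoi_c8(as.numeric(nb)) == 1) {
        skel[r, c] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  skel
}

skeleton_neighbor_count <- function(skel) {
  s <- skel * 1
  (shift_mat(s, 1, 0) + shift_mat(s, -1, 0) + shift_mat(s, 0, 1) +
     shift_mat(s, 0, -1) + shift_mat(s, 1, 1) + shift_mat(s, 1, -1) +
     shift_mat(s, -1, 1) + shift_mat(s, -1, -1))
}

# 8-connected labeling of a (small) pixel set given as an n x 2 matrix of
# (row, col); returns integer cluster ids in input order.
label_pixel_set <- function(px) {
  n <- nrow(px)
  if (n == 0) return(integer(0))
  key <- paste(px[, 1], px[, 2])
  lookup <- stats::setNames(seq_len(n), key)
  lab <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (lab[i] > 0) next
    cur <- cur + 1L
    queue <- i
    lab[i] <- cur
    while (length(queue)) {
      j <- queue[1]; queue <- queue[-1]
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        k <- lookup[paste(px[j, 1] + dr, px[j, 2] + dc)]
        if (!is.na(k) && lab[k] == 0) {
          lab[k] <- cur
          queue <- c(queue, k)
        }
      }
    }
  }
  lab
}

#' Detect branch and end points of a skeleton
#'
#' End points have exactly one 8-connected skeleton neighbour; branch points
#' have three or more. Adjacent branch pixels are clustered so that one
#' anatomical junction counts once.
#'
#' @param skeleton Logical skeleton matrix (from [skeletonize_mask()]).
#' @return List with tibbles `branch_points` (`row`, `col`, `cluster`) and
#'   `end_points` (`row`, `col`).
#' @export
detect_nodes <- function(skeleton) {
  stopifnot(is.matrix(skeleton))
  nb <- skeleton_neighbor_count(skeleton)
  ep <- which(skeleton & nb == 1, arr.ind = TRUE)
  bp <- which(skeleton & nb >= 3, arr.ind = TRUE)
  cl <- label_pixel_set(bp)
  list(
    branch_points = tibble::tibble(row = as.integer(bp[, 1]),
                                   col = as.integer(bp[, 2]),
                                   cluster = cl),
    end_points = tibble::tibble(row = as.integer(ep[, 1]),
                                col = as.integer(ep[, 2]))
  )
}

#' Split a skeleton into vessel segments with EDT radii
#'
#' Each node-to-node skeleton path becomes one vessel segment. Per-point
#' radii are the Euclidean distance transform of the binary mask evaluated
#' on the centreline pixels (the distance from a centreline pixel to the
#' nearest non-vessel pixel is the local radius), and the summary diameter
#' is twice the mean radius scaled to micrometres. Centreline points within
#' `branch_exclusion_px` of a branch cluster are excluded from the radii
#' average because the distance transform inflates at junctions. Segments
#' with fewer than `min_length_px` centreline pixels are discarded (the
#' count is reported), since slope estimation on the spatio-temporal image
#' needs spatial extent.
#'
#' @param skeleton Logical skeleton matrix.
#' @param nodes Output of [detect_nodes()] (recomputed when `NULL`).
#' @param mask `vessel_mask` or logical matrix used for the distance
#'   transform.
#' @param calibration A [calibration_profile()].
#' @param min_length_px Minimum number of centreline pixels to keep a
#'   segment.
#' @param branch_exclusion_px Radius (pixels) around branch clusters to
#'   exclude from the diameter average.
#' @return Tibble with one row per segment: `segment_id`, `n_points`,
#'   `diameter_um`, `length_um`, and list-columns `points` (n x 2 row/col
#'   matrices) and `radii_px`.
#' @export
split_segments <- function(skeleton, nodes = NULL, mask, calibration,
                           min_length_px = 15, branch_exclusion_px = 2) {
  stopifnot(is.matrix(skeleton), inherits(calibration, "calibration_profile"))
  bin <- if (inherits(mask, "vessel_mask")) mask$binary else mask
  if (is.null(nodes)) nodes <- detect_nodes(skeleton)
  empty <- tibble::tibble(segment_id = character(), n_points = integer(),
                          diameter_um = numeric(), length_um = numeric(),
                          points = list(), radii_px = list())
  if (!any(skeleton)) return(empty)

  h <- nrow(skeleton); w <- ncol(skeleton)
  node_mat <- matrix(FALSE, h, w)
  bp <- nodes$branch_points; ep <- nodes$end_points
  if (nrow(bp)) node_mat[cbind(bp$row, bp$col)] <- TRUE
  if (nrow(ep)) node_mat[cbind(ep$row, ep$col)] <- TRUE

  edt <- as.matrix(EBImage::distmap(bin * 1))

  visited <- matrix(FALSE, h, w)  # interior (non-node) pixels consumed
  used_pairs <- character(0)      # direct node-node adjacencies consumed
  paths <- list()

  nbrs <- function(r, c) {
    rr <- r + c(-1, -1, -1, 0, 0, 1, 1, 1)
    cc <- c + c(-1, 0, 1, -1, 1, -1, 0, 1)
    ok <- rr >= 1 & rr <= h & cc >= 1 & cc <= w
    rr <- rr[ok]; cc <- cc[ok]
    on <- skeleton[cbind(rr, cc)]
    cbind(rr[on], cc[on])
  }

  node_px <- rbind(as.matrix(bp[, c("row", "col")]),
                   as.matrix(ep[, c("row", "col")]))
  # deterministic order: row-major
  if (nrow(node_px)) node_px <- node_px[order(node_px[, 1], node_px[, 2]), , drop = FALSE]

  walk_from <- function(start, second) {
    path <- list(start, second)
    prev <- start; cur <- second
    visited[cur[1], cur[2]] <<- TRUE
    repeat {
      nb <- nbrs(cur[1], cur[2])
      keep <- !(nb[, 1] == prev[1] & nb[, 2] == prev[2])
      nb <- nb[keep, , drop = FALSE]
      if (nrow(nb) == 0) break  # dead end
      is_node <- node_mat[cbind(nb[, 1], nb[, 2])]
      if (any(is_node)) {
        nn <- nb[is_node, , drop = FALSE]
        nn <- nn[order(nn[, 1], nn[, 2]), , drop = FALSE]
        path[[length(path) + 1]] <- nn[1, ]
        break
      }
      free <- !visited[cbind(nb[, 1], nb[, 2])]
      nb <- nb[free, , drop = FALSE]
      if (nrow(nb) == 0) break
      nb <- nb[order(nb[, 1], nb[, 2]), , drop = FALSE]
      nxt <- nb[1, ]
      path[[length(path) + 1]] <- nxt
      visited[nxt[1], nxt[2]] <<- TRUE
      prev <- cur; cur <- nxt
    }
    do.call(rbind, path)
  }

  if (nrow(node_px)) {
    for (i in seq_len(nrow(node_px))) {
      p <- node_px[i, ]
      nb <- nbrs(p[1], p[2])
      if (nrow(nb) == 0) next
      nb <- nb[order(nb[, 1], nb[, 2]), , drop = FALSE]
      for (j in seq_len(nrow(nb))) {
        q <- nb[j, ]
        if (node_mat[q[1], q[2]]) {
          key <- paste(pmin(p[1] * w + p[2], q[1] * w + q[2]),
                       pmax(p[1] * w + p[2], q[1] * w + q[2]))
          same_cluster <- FALSE
          if (nrow(bp)) {
            ci <- bp$cluster[bp$row == p[1] & bp$col == p[2]]
            cj <- bp$cluster[bp$row == q[1] & bp$col == q[2]]
            same_cluster <- length(ci) > 0 && length(cj) > 0 && ci[1] == cj[1]
          }
          if (!same_cluster && !(key %in% used_pairs)) {
            used_pairs <- c(used_pairs, key)
            paths[[length(paths) + 1]] <- rbind(p, q)
          }
        } else if (!visited[q[1], q[2]]) {
          paths[[length(paths) + 1]] <- walk_from(p, q)
        }
      }
    }
  }

  # remaining unvisited non-node pixels belong to closed loops
  left <- which(skeleton & !visited & !node_mat, arr.ind = TRUE)
  while (nrow(left)) {
    left <- left[order(left[, 1], left[, 2]), , drop = FALSE]
    start <- left[1, ]
    visited[start[1], start[2]] <- TRUE
    nb <- nbrs(start[1], start[2])
    nb <- nb[!visited[cbind(nb[, 1], nb[, 2])], , drop = FALSE]
    if (nrow(nb) == 0) {
      paths[[length(paths) + 1]] <- rbind(start, start)
    } else {
      nb <- nb[order(nb[, 1], nb[, 2]), , drop = FALSE]
      paths[[length(paths) + 1]] <- walk_from(start, nb[1, ])
    }
    left <- which(skeleton & !visited & !node_mat, arr.ind = TRUE)
  }

  if (length(paths) == 0) return(empty)

  scale <- calibration$pixel_scale_um
  bp_mat <- as.matrix(bp[, c("row", "col")])
  rows <- lapply(seq_along(paths), function(i) {
    pts <- paths[[i]]
    colnames(pts) <- c("row", "col")
    rownames(pts) <- NULL
    r <- edt[cbind(pts[, 1], pts[, 2])]
    # where a vessel exits the image, the medial axis grows a tail toward
    # the border with shrinking radii; exclude points closer to the border
    # than the segment's reference radius, where clipping biases the EDT
    border_dist <- pmin(pts[, 1] - 1, h - pts[, 1], pts[, 2] - 1, w - pts[, 2])
    r_ref <- stats::quantile(r, 0.95, names = FALSE)
    include <- border_dist >= r_ref + 1
    if (!any(include)) include <- rep(TRUE, nrow(pts))
    if (nrow(bp_mat)) {
      d2min <- vapply(seq_len(nrow(pts)), function(k) {
        min((bp_mat[, 1] - pts[k, 1])^2 + (bp_mat[, 2] - pts[k, 2])^2)
      }, numeric(1))
      include <- include & d2min > branch_exclusion_px^2
      if (!any(include)) include <- rep(TRUE, nrow(pts))
    }
    steps <- sqrt(diff(pts[, 1])^2 + diff(pts[, 2])^2)
    tibble::tibble(
      segment_id = sprintf("seg_%03d", i),
      n_points = nrow(pts),
      diameter_um = 2 * mean(r[include]) * scale,
      length_um = sum(steps) * scale,
      # a segment hugging the image border is a clipping artifact whose
      # width cannot be measured
      border_artifact = stats::median(border_dist) < stats::median(r) + 1,
      points = list(pts),
      radii_px = list(r)
    )
  })
  out <- dplyr::bind_rows(rows)
  drop <- out$n_points < min_length_px | out$border_artifact
  if (any(drop)) {
    message(sum(drop),
            " segment(s) discarded (below minimum length or border artifact)")
    out <- out[!drop, , drop = FALSE]
  }
  out$border_artifact <- NULL
  out
}

#' Map vessels on a stabilized reference frame
#'
#' Convenience wrapper chaining [vesselness_filter()], [binarize()],
#' [skeletonize_mask()], [detect_nodes()] and [split_segments()].
#'
#' @inheritParams vesselness_filter
#' @inheritParams binarize
#' @inheritParams split_segments
#' @param frame Reference frame intensity matrix (the temporal mean of a
#'   stabilized stack gives the cleanest vessel silhouette).
#' @param calibration A [calibration_profile()].
#' @param refine Apply half-depth intensity refinement of the mask.
#' @return List with `segments` (tibble), `mask` (`vessel_mask`),
#'   `skeleton`, `nodes`.
#' @export
map_vessels <- function(frame, calibration, scales = c(1.5, 3, 6, 9, 12),
                        low = 0.05, high = 0.15, min_area = 30,
                        min_length_px = 15, refine = TRUE) {
  resp <- vesselness_filter(frame, scales = scales)
  mask <- binarize(resp, low = low, high = high, min_area = min_area,
                   frame = if (refine) frame else NULL)
  skel <- skeletonize_mask(mask)
  nodes <- detect_nodes(skel)
  segs <- split_segments(skel, nodes, mask, calibration,
                         min_length_px = min_length_px)
  list(segments = segs, mask = mask, skeleton = skel, nodes = nodes)
}
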