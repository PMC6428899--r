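# Ordering identified flagellar pixels into a centerline trace, including
# the refinements needed for visually-overlapping flagella: linear stitching
# of nearby segments and tangent-preserving branch resolution.

sk_neighbors <- function(sk, p) {
  H <- nrow(sk); W <- ncol(sk)
  rr <- p[1] + c(-1, -1, -1, 0, 0, 1, 1, 1)
  cc <- p[2] + c(-1, 0, 1, -1, 1, -1, 0, 1)
  ok <- rr >= 1 & rr <= H & cc >= 1 & cc <= W
  rr <- rr[ok]; cc <- cc[ok]
  on <- sk[cbind(rr, cc)]
  cbind(row = rr[on], col = cc[on])
}

unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) c(0, 0) else v / n
}

# Greedy straight probe into a branch: walk up to `window` pixels from
# `from` starting at `first`, at each step preferring the unvisited
# neighbour most aligned with the current direction. Returns the unit
# vector from `from` to the probe's end.
probe_branch <- function(sk, visited, from, first, window) {
  pos <- first
  dir <- unit(first - from)
  local <- matrix(c(from, first), ncol = 2, byrow = TRUE)
  for (i in seq_len(window - 1)) {
    nb <- sk_neighbors(sk, pos)
    if (!nrow(nb)) break
    seen <- visited[cbind(nb[, 1], nb[, 2])] |
      (px_key(nb, nrow(sk)) %in% px_key(local, nrow(sk)))
    nb <- nb[!seen, , drop = FALSE]
    if (!nrow(nb)) break
    dots <- (nb[, 1] - pos[1]) * dir[1] + (nb[, 2] - pos[2]) * dir[2]
    dots <- dots / sqrt((nb[, 1] - pos[1])^2 + (nb[, 2] - pos[2])^2)
    best <- which(dots >= max(dots) - 1e-12)
    best <- best[order(nb[best, 1], nb[best, 2])][1]
    nxt <- nb[best, ]
    dir <- unit(nxt - pos)
    local <- rbind(local, nxt)
    pos <- nxt
  }
  unit(pos - from)
}

#' Trace a skeleton path from an endpoint, resolving branches by tangent
#'
#' Walks the skeleton from a given endpoint. At a junction (a pixel with
#' several unvisited skeleton neighbours) the walk continues along the
#' outgoing branch whose initial direction, probed over `window` pixels,
#' makes the smallest angle with the incoming tangent (the average of the
#' previous `window` step directions). This preserves the local flagellum
#' tangent, so two crossing filaments are each traced straight through the
#' junction. No pixel is revisited; the walk terminates at an endpoint.
#'
#' @param skeleton logical skeleton matrix (or a `medial_axis_map`).
#' @param start `(row, col)` of a skeleton endpoint.
#' @param window number of pixels over which tangents are averaged
#'   (default 5).
#' @return An object of class `skeleton_path`: list with `points` (ordered
#'   integer matrix) and `arclength` (cumulative arclength, 1 per axial and
#'   `sqrt(2)` per diagonal step).
#' @export
resolve_branches <- function(skeleton, start, window = 5) {
  sk <- if (inherits(skeleton, "medial_axis_map")) skeleton$skeleton
        else check_mask(skeleton)
  start <- as.integer(round(start))
  if (!sk[start[1], start[2]]) stop("`start` is not a skeleton pixel")
  if (nrow(sk_neighbors(sk, start)) > 1)
    stop("`start` must be a skeleton endpoint (at most one neighbour)")

  H <- nrow(sk)
  visited <- matrix(FALSE, H, ncol(sk))
  visited[start[1], start[2]] <- TRUE
  npx <- sum(sk)
  pts <- matrix(NA_integer_, npx, 2)
  steps <- matrix(NA_real_, npx, 2)
  pts[1, ] <- start
  n <- 1L
  cur <- start
  repeat {
    nb <- sk_neighbors(sk, cur)
    nb <- nb[!visited[cbind(nb[, 1], nb[, 2])], , drop = FALSE]
    if (!nrow(nb)) break
    if (nrow(nb) == 1) {
      nxt <- nb[1, ]
    } else {
      k <- min(window, n - 1L)
      tangent <- if (k >= 1) unit(colSums(steps[(n - k):(n - 1L), , drop = FALSE]))
                 else c(0, 0)
      ang <- vapply(seq_len(nrow(nb)), function(i) {
        bd <- probe_branch(sk, visited, cur, nb[i, ], window)
        if (all(tangent == 0)) 0 else acos(max(-1, min(1, sum(bd * tangent))))
      }, numeric(1))
      best <- which(ang <= min(ang) + 1e-9)
      best <- best[order(nb[best, 1], nb[best, 2])][1]
      nxt <- nb[best, ]
    }
    n <- n + 1L
    pts[n, ] <- nxt
    steps[n - 1L, ] <- unit(nxt - cur)
    visited[nxt[1], nxt[2]] <- TRUE
    cur <- nxt
  }
  pts <- pts[seq_len(n), , drop = FALSE]
  colnames(pts) <- c("row", "col")
  seg <- if (n > 1) sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-n, , drop = FALSE])^2)) else numeric(0)
  structure(list(points = pts, arclength = cumsum(c(0, seg))),
            class = "skeleton_path")
}

region_endpoints <- function(px, dim) {
  m <- px_to_mask(px, dim)
  nb <- count_neighbors(m)
  ep <- px[nb[cbind(px[, 1], px[, 2])] <= 1, , drop = FALSE]
  if (!nrow(ep)) ep <- px
  ep
}

# Longest tangent-consistent path through a region: walks from every region
# endpoint and keeps the longest path (ties go to the lexicographically
# smallest start). A region with a side branch (e.g. a residual body stub at
# flagellar width) is thus traced along its dominant filament arm, not the
# stub.
longest_region_path <- function(m, window = 5) {
  px <- skeleton_pixels(m)
  eps <- region_endpoints(px, dim(m))
  eps <- eps[px_order(eps), , drop = FALSE]
  best <- NULL
  for (i in seq_len(nrow(eps))) {
    nbk <- count_neighbors(m)[eps[i, 1], eps[i, 2]]
    if (nbk > 1) next  # non-endpoint fallback pixels of blob regions
    p <- resolve_branches(m, eps[i, ], window = window)
    if (is.null(best) || nrow(p$points) > nrow(best$points)) best <- p
  }
  if (is.null(best)) best <- resolve_branches_any(m, eps[1, ], window)
  best
}

# Plain greedy walk for degenerate regions with no endpoint pixel (small
# blobs or closed loops): starts at the pixel of lowest degree and follows
# lexicographically smallest unvisited neighbours.
resolve_branches_any <- function(m, start, window = 5) {
  px <- skeleton_pixels(m)
  deg <- count_neighbors(m)[cbind(px[, 1], px[, 2])]
  start <- px[order(deg, px[, 1], px[, 2])[1], ]
  visited <- matrix(FALSE, nrow(m), ncol(m))
  visited[start[1], start[2]] <- TRUE
  pts <- matrix(start, 1, 2, dimnames = list(NULL, c("row", "col")))
  cur <- start
  repeat {
    nbx <- sk_neighbors(m, cur)
    nbx <- nbx[!visited[cbind(nbx[, 1], nbx[, 2])], , drop = FALSE]
    if (!nrow(nbx)) break
    nxt <- nbx[px_order(nbx)[1], ]
    pts <- rbind(pts, nxt)
    visited[nxt[1], nxt[2]] <- TRUE
    cur <- nxt
  }
  n <- nrow(pts)
  seg <- if (n > 1) sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-n, , drop = FALSE])^2)) else numeric(0)
  structure(list(points = pts, arclength = cumsum(c(0, seg))), class = "skeleton_path")
}

#' Linear stitching of nearby skeleton segments
#'
#' Iteratively rejoins isolated segments of a thresholded medial axis
#' transform: while the closest pair of endpoints belonging to two distinct
#' regions is within `radius_px`, the pair is connected by a rasterised
#' straight bridge and the regions merged (smallest gap first; ties broken
#' lexicographically). Limiting the radius to the approximate flagellum
#' width restores connectivity across flagellar crossings without closing
#' properly-segmented regions; with nothing within the radius this is a
#' no-op.
#'
#' @param regions list of pixel-coordinate matrices (`(row, col)` integer
#'   rows).
#' @param radius_px maximum Euclidean gap to bridge. The pipeline default is
#'   twice the modal half-width, i.e. the approximate visible flagellum
#'   width.
#' @param dim image dimensions `(H, W)`; defaults to the bounding box.
#' @return list with `regions` (merged pixel sets) and `bridges` (list of
#'   bridge pixel matrices that were inserted).
#' @export
stitch_segments <- function(regions, radius_px, dim = NULL) {
  stopifnot(length(regions) >= 1, radius_px > 0)
  regions <- lapply(regions, px_mat)
  if (is.null(dim)) {
    allpx <- do.call(rbind, regions)
    dim <- c(max(allpx[, 1]), max(allpx[, 2]))
  }
  bridges <- list()
  repeat {
    if (length(regions) < 2) break
    eps <- lapply(regions, region_endpoints, dim = dim)
    best <- NULL
    for (i in seq_along(regions)) for (j in seq_along(regions)) {
      if (j <= i) next
      a <- eps[[i]]; b <- eps[[j]]
      d2 <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
      m <- which(d2 == min(d2), arr.ind = TRUE)
      # deterministic tie-break: lexicographic on (endpoint A, endpoint B)
      cand <- cbind(a[m[, 1], , drop = FALSE], b[m[, 2], , drop = FALSE])
      cand <- cand[order(cand[, 1], cand[, 2], cand[, 3], cand[, 4]), , drop = FALSE]
      gap <- sqrt(min(d2))
      if (is.null(best) || gap < best$gap - 1e-12 ||
          (abs(gap - best$gap) <= 1e-12 &&
           any(cand[1, ] != best$pair) &&
           paste(cand[1, ], collapse = ",") < paste(best$pair, collapse = ","))) {
        best <- list(gap = gap, i = i, j = j, pair = cand[1, ])
      }
    }
    if (is.null(best) || best$gap > radius_px + 1e-12) break
    bridge <- raster_segment(best$pair[1:2], best$pair[3:4])
    inner <- bridge[-c(1, nrow(bridge)), , drop = FALSE]
    merged <- rbind(regions[[best$i]], regions[[best$j]], inner)
    merged <- merged[!duplicated(merged), , drop = FALSE]
    bridges[[length(bridges) + 1L]] <- inner
    regions[[best$i]] <- merged
    regions[[best$j]] <- NULL
  }
  list(regions = regions, bridges = bridges)
}

#' Order an identified flagellar region into a centerline trace
#'
#' Walks the selected modal region from the attachment point to the distal
#' tip using tangent-preserving branch resolution, carrying the per-point
#' half-widths of the medial axis transform. If the region is disconnected
#' the component containing the attachment is traced and the trace is
#' flagged partial. Bridge pixels inserted by [stitch_segments()] have no
#' transform value; their widths are interpolated from neighbouring path
#' points.
#'
#' @param result a [modal_segment()] result (its `selected` region is
#'   traced).
#' @param attachment an attachment estimate ([attachment_from_modal()] or
#'   [derivative_segment()]).
#' @param mat the `medial_axis_map` of the frame.
#' @param window tangent window for branch resolution.
#' @param frame_index optional frame index stored in the trace.
#' @return An object of class `flagellum_trace`: `points` (ordered from
#'   attachment to tip), `widths_px`, `arclength_px` (cumulative),
#'   `length_px` (total arclength), `attachment`, `frame_index`, and flags
#'   `partial`, `low_confidence`.
#' @export
trace_flagellum <- function(result, attachment, mat, window = 5,
                            frame_index = NA_integer_) {
  stopifnot(inherits(result, "modal_result"), inherits(mat, "medial_axis_map"))
  px <- px_mat(result$selected)
  if (!nrow(px)) stop("empty selected region")
  dims <- dim(mat$values)
  partial <- FALSE
  low_conf <- isTRUE(attachment$low_confidence) || isTRUE(result$low_confidence)

  if (nrow(px) == 1) {
    tr <- structure(list(points = px, widths_px = mat$values[px],
                         arclength_px = 0, length_px = 0,
                         attachment = attachment, frame_index = frame_index,
                         partial = FALSE, low_confidence = TRUE),
                    class = "flagellum_trace")
    return(tr)
  }

  m <- px_to_mask(px, dims)
  lab <- cpp_label_components(m, 8L)
  ap <- as.integer(round(attachment$path_point %||% attachment$point))
  acomp <- if (m[ap[1], ap[2]]) lab[ap[1], ap[2]] else {
    # attachment off-region: use the component nearest to it
    d2 <- (px[, 1] - ap[1])^2 + (px[, 2] - ap[2])^2
    lab[px[which.min(d2), 1], px[which.min(d2), 2]]
  }
  if (max(lab) > 1) {
    partial <- TRUE
    m <- lab == acomp
    px <- px[lab[cbind(px[, 1], px[, 2])] == acomp, , drop = FALSE]
  }

  path <- longest_region_path(m, window = window)
  np <- nrow(path$points)
  if (sum((path$points[np, ] - ap)^2) < sum((path$points[1, ] - ap)^2)) {
    pts <- path$points[np:1, , drop = FALSE]
    seg <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-np, , drop = FALSE])^2))
    path <- structure(list(points = pts, arclength = cumsum(c(0, seg))),
                      class = "skeleton_path")
  }
  # start the trace at the (possibly trimmed) attachment point when it lies
  # near the head of the path
  k <- which(path$points[, 1] == ap[1] & path$points[, 2] == ap[2])[1]
  if (!is.na(k) && k > 1 && k <= 8) {
    pts <- path$points[k:np, , drop = FALSE]
    nk <- nrow(pts)
    seg <- if (nk > 1) sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nk, , drop = FALSE])^2)) else numeric(0)
    path <- structure(list(points = pts, arclength = cumsum(c(0, seg))),
                      class = "skeleton_path")
  }
  w <- mat$values[cbind(path$points[, 1], path$points[, 2])]
  if (any(w == 0) && any(w > 0)) {
    idx <- seq_along(w)
    w[w == 0] <- stats::approx(idx[w > 0], w[w > 0], xout = idx[w == 0],
                               rule = 2)$y
  }
  structure(list(points = path$points, widths_px = w,
                 arclength_px = path$arclength,
                 length_px = path$arclength[length(path$arclength)],
                 attachment = attachment, frame_index = frame_index,
                 partial = partial, low_confidence = low_conf),
            class = "flagellum_trace")
}

#' @export
print.flagellum_trace <- function(x, ...) {
  cat(sprintf("flagellum trace: %d points, arclength %.1f px%s%s\n",
              nrow(x$points), x$length_px,
              if (x$partial) " [partial]" else "",
              if (x$low_confidence) " [low confidence]" else ""))
  invisible(x)
}
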