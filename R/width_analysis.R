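# Width-profile analysis of the medial axis transform: the flagellum is the
# region of approximately constant width, identified either from the mode of
# the width distribution (default) or from an outlier in the derivative of
# the width profile.

#' Arclength-ordered width profile along a simple skeleton path
#'
#' Reads the medial axis transform values in arclength order along the
#' skeleton, starting from an endpoint. The skeleton must be a simple path
#' (at most two endpoints, no junctions); branched skeletons must first be
#' reduced with [resolve_branches()].
#'
#' @param mat a `medial_axis_map`.
#' @param start `(row, col)` of the endpoint to start from; defaults to the
#'   lexicographically smallest endpoint.
#' @return An object of class `width_profile`: `points` (ordered pixels),
#'   `arclength` (0 at the start, +1 per axial and +sqrt(2) per diagonal
#'   step), and `widths` (transform values, px).
#' @export
extract_width_profile <- function(mat, start = NULL) {
  stopifnot(inherits(mat, "medial_axis_map"))
  sk <- mat$skeleton
  npx <- sum(sk)
  if (npx == 0) stop("empty skeleton")
  eps <- skeleton_endpoints(sk)
  if (nrow(eps) == 0)
    stop("skeleton has no endpoints (closed loop); provide a start pixel via resolve_branches()")
  if (nrow(eps) > 2)
    stop("branched skeleton: resolve branches first (see resolve_branches())")
  if (is.null(start)) {
    start <- eps[px_order(eps)[1], ]
  } else {
    start <- as.integer(round(start))
    if (!any(eps[, 1] == start[1] & eps[, 2] == start[2]))
      stop("`start` is not a skeleton endpoint")
  }
  path <- resolve_branches(sk, start)
  if (nrow(path$points) != npx)
    stop("branched skeleton: resolve branches first (see resolve_branches())")
  structure(list(points = path$points, arclength = path$arclength,
                 widths = mat$values[cbind(path$points[, 1], path$points[, 2])]),
            class = "width_profile")
}

#' @export
print.width_profile <- function(x, ...) {
  cat(sprintf("width profile: %d samples over %.1f px arclength, widths %.2f-%.2f px\n",
              length(x$widths), max(x$arclength), min(x$widths), max(x$widths)))
  invisible(x)
}

#' Export a width profile as a data frame (or CSV)
#'
#' @param profile a `width_profile`.
#' @param path optional CSV path; when given the table is also written.
#' @return data frame with columns `arclength_px`, `width_px`, `row`, `col`.
#' @export
width_profile_table <- function(profile, path = NULL) {
  stopifnot(inherits(profile, "width_profile"))
  df <- data.frame(arclength_px = profile$arclength,
                   width_px = profile$widths,
                   row = profile$points[, 1], col = profile$points[, 2])
  if (!is.null(path)) write.csv(df, path, row.names = FALSE)
  df
}

#' Histogram of width values with modal width
#'
#' Bins the transform's width values into bins of `bin_width` centered on
#' integer multiples of `bin_width`. The modal width is the center of the
#' maximal-count bin; ties are broken toward the smaller width, since the
#' flagellum is the thin structure of interest.
#'
#' @param x a `width_profile`, a `medial_axis_map` (all skeleton widths), or
#'   a numeric vector of widths.
#' @param bin_width histogram bin width in pixels (default 1, matching the
#'   near-discrete values the transform takes on rasterised images).
#' @return list of class `width_histogram`: `centers`, `counts`,
#'   `modal_width`, `bin_width`.
#' @export
width_histogram <- function(x, bin_width = 1) {
  w <- if (inherits(x, "width_profile")) x$widths
       else if (inherits(x, "medial_axis_map")) x$values[x$skeleton]
       else as.numeric(x)
  if (!length(w)) stop("empty width profile")
  stopifnot(bin_width > 0)
  idx <- round(w / bin_width)
  tab <- table(idx)
  centers <- as.numeric(names(tab)) * bin_width
  counts <- as.integer(tab)
  modal <- min(centers[counts == max(counts)])
  # refined mode: mean of the widths inside the modal bin. On rasterised
  # images the transform takes near-discrete values (1, sqrt(2), 2, ...)
  # that scatter within a bin; the bin center alone biases the mode toward
  # its integer label, while the within-bin mean estimates the actual
  # flagellar half-width.
  refined <- mean(w[idx == modal / bin_width])
  structure(list(centers = centers, counts = counts, modal_width = modal,
                 modal_width_refined = refined, bin_width = bin_width),
            class = "width_histogram")
}

#' Identify the flagellar region by modal width analysis
#'
#' Finds the modal half-width of the cell from the medial axis transform and
#' selects the skeleton pixels whose width lies within `tolerance` of it.
#' The 8-connected components of these pixels are the candidate regions; the
#' flagellum is taken to be the largest of them (by pixel count, ties broken
#' toward the region containing the lexicographically smallest pixel).
#' Candidates smaller than `min_region_px` are treated as speckle and only
#' selected, with a low-confidence flag, if nothing larger exists.
#'
#' @param mat a `medial_axis_map`.
#' @param tolerance select pixels with `|width - modal_width| <= tolerance`
#'   (px); the default 1 absorbs the sqrt(2) rasterisation jitter of the
#'   transform.
#' @param bin_width histogram bin width passed to [width_histogram()].
#' @param min_region_px minimum candidate region size (default 5).
#' @return An object of class `modal_result`: `modal_width`, `bin_width`,
#'   `tolerance`, `selected` (pixel matrix), `candidate_regions` (list of
#'   pixel matrices, largest first), `low_confidence`, `dim`.
#'   Signals a `flagtrace_identification_failure` condition when no skeleton
#'   pixel lies within tolerance of the mode.
#' @export
modal_segment <- function(mat, tolerance = 1, bin_width = 1, min_region_px = 5) {
  stopifnot(inherits(mat, "medial_axis_map"))
  h <- width_histogram(mat, bin_width = bin_width)
  sel <- mat$skeleton & abs(mat$values - h$modal_width_refined) <= tolerance + 1e-9
  if (!any(sel))
    flag_failure("no skeleton pixels within tolerance of the modal width",
                 "flagtrace_identification_failure")
  lab <- cpp_label_components(sel, 8L)
  regions <- lapply(seq_len(max(lab)), function(i) {
    m <- which(lab == i, arr.ind = TRUE, useNames = FALSE)
    matrix(m, ncol = 2, dimnames = list(NULL, c("row", "col")))
  })
  ord <- order_regions(regions, min_region_px)
  structure(list(modal_width = h$modal_width_refined,
                 modal_bin_center = h$modal_width, bin_width = bin_width,
                 tolerance = tolerance, selected = ord$regions[[ord$pick]],
                 candidate_regions = ord$regions, low_confidence = ord$low_confidence,
                 dim = dim(mat$values)),
            class = "modal_result")
}

#' @export
print.modal_result <- function(x, ...) {
  cat(sprintf("modal width analysis: modal half-width %.2f px (+/- %.2f), %d candidate region(s)\n",
              x$modal_width, x$tolerance, length(x$candidate_regions)))
  cat(sprintf("  selected region: %d pixels%s\n", nrow(x$selected),
              if (x$low_confidence) " [low confidence]" else ""))
  invisible(x)
}

new_attachment_estimate <- function(point, arclength, method,
                                    low_confidence = FALSE, path_point = point) {
  structure(list(point = as.numeric(point),
                 arclength_at_attachment = as.numeric(arclength),
                 method = method, low_confidence = low_confidence,
                 path_point = as.numeric(path_point)),
            class = "attachment_estimate")
}

#' @export
print.attachment_estimate <- function(x, ...) {
  cat(sprintf("flagellar attachment (%s): (%.0f, %.0f) at arclength %.1f px%s\n",
              x$method, x$point[1], x$point[2], x$arclength_at_attachment,
              if (x$low_confidence) " [low confidence]" else ""))
  invisible(x)
}

#' Locate the flagellar attachment by derivative analysis
#'
#' Walks a width profile ordered from the flagellar tip and computes a
#' forward-difference approximation to the derivative of width with respect
#' to arclength, `d[i] = (w[i+step] - w[i]) / (s[i+step] - s[i])`. The first
#' position whose derivative is an outlier relative to the previously seen
#' derivatives (running median plus `outlier_k` times the running MAD,
#' floored at `mad_floor` to allow for rasterisation noise on near-constant
#' profiles) is returned as the attachment point: the place where the
#' constant flagellar width gives way to the widening cell body.
#'
#' @param profile a `width_profile` ordered from the flagellar tip (the
#'   endpoint with the smaller terminal width).
#' @param step forward-difference step in samples; 3 by default, which is
#'   markedly more reliable than 2 or 4 on beating-flagellum data.
#' @param outlier_k MAD multiplier of the outlier rule (default 3).
#' @param min_history minimum number of derivative samples before outliers
#'   are assessed (default 10).
#' @param mad_floor lower bound on the MAD scale (px per px, default 0.1).
#' @return An `attachment_estimate` with `method = "derivative"`. Signals a
#'   `flagtrace_identification_failure` when no outlier exists (the profile
#'   may contain no cell body).
#' @export
derivative_segment <- function(profile, step = 3, outlier_k = 3,
                               min_history = 10, mad_floor = 0.1) {
  stopifnot(inherits(profile, "width_profile"), step >= 1)
  n <- length(profile$widths)
  if (n <= step + min_history)
    flag_failure(sprintf("profile too short for derivative analysis (%d samples)", n),
                 "flagtrace_identification_failure")
  w <- profile$widths; s <- profile$arclength
  d <- (w[(1 + step):n] - w[1:(n - step)]) / (s[(1 + step):n] - s[1:(n - step)])
  for (i in (min_history + 1):length(d)) {
    hist <- d[1:(i - 1)]
    thr <- median(hist) + outlier_k * max(mad(hist), mad_floor)
    if (d[i] > thr) {
      return(new_attachment_estimate(profile$points[i, ], s[i], "derivative"))
    }
  }
  flag_failure("no width-derivative outlier found; profile may contain no cell body",
               "flagtrace_identification_failure")
}

#' Locate the flagellar attachment from a modal segmentation
#'
#' The selected modal region is ordered into a path; of its two endpoints,
#' the attachment is the one whose continuation along the full skeleton
#' (the next `lookahead` skeleton pixels beyond the region) has the larger
#' mean width — the body side. The other endpoint is the distal tip. If
#' neither endpoint has a wider continuation (a free filament with no
#' body), a deterministic endpoint is returned with a low-confidence flag.
#'
#' @param result a [modal_segment()] result.
#' @param mat the frame's `medial_axis_map` (supplies the full skeleton and
#'   widths).
#' @param lookahead how many skeleton pixels beyond the region to average
#'   (default 5). Regions shorter than `lookahead` are flagged low
#'   confidence.
#' @return An `attachment_estimate` with `method = "modal"`.
#' @export
attachment_from_modal <- function(result, mat, lookahead = 5) {
  stopifnot(inherits(result, "modal_result"), inherits(mat, "medial_axis_map"))
  px <- px_mat(result$selected)
  dims <- dim(mat$values)
  low_conf <- nrow(px) < lookahead
  if (nrow(px) == 1)
    return(new_attachment_estimate(px[1, ], 0, "modal", TRUE))

  m <- px_to_mask(px, dims)
  path <- longest_region_path(m)
  e1 <- path$points[1, ]
  e2 <- path$points[nrow(path$points), ]
  total <- path$arclength[length(path$arclength)]

  region_keys <- px_key(px, dims[1])
  side_width <- function(ep) {
    # mean width of the nearest `lookahead` skeleton pixels beyond the region
    frontier <- matrix(ep, ncol = 2)
    seen <- c(region_keys, px_key(frontier, dims[1]))
    got <- numeric(0)
    while (length(got) < lookahead && nrow(frontier)) {
      nxt <- do.call(rbind, lapply(seq_len(nrow(frontier)),
                                   function(i) sk_neighbors(mat$skeleton, frontier[i, ])))
      if (is.null(nxt) || !nrow(nxt)) break
      nxt <- nxt[!(px_key(nxt, dims[1]) %in% seen), , drop = FALSE]
      nxt <- nxt[!duplicated(px_key(nxt, dims[1])), , drop = FALSE]
      if (!nrow(nxt)) break
      nxt <- nxt[px_order(nxt), , drop = FALSE]
      take <- min(nrow(nxt), lookahead - length(got))
      got <- c(got, mat$values[cbind(nxt[seq_len(take), 1], nxt[seq_len(take), 2])])
      seen <- c(seen, px_key(nxt, dims[1]))
      frontier <- nxt
    }
    if (length(got)) mean(got) else -Inf
  }
  w1 <- side_width(e1); w2 <- side_width(e2)
  if (w1 == w2) {
    ep <- rbind(e1, e2)
    pick <- px_order(ep)[1]
    return(new_attachment_estimate(ep[pick, ], if (pick == 1) 0 else total,
                                   "modal", TRUE))
  }
  # The selected region reaches slightly into the body wherever the width
  # taper still falls within tolerance. Trim the body-side end back to the
  # flagellar plateau: drop trailing points whose width exceeds the maximum
  # width seen over the interior of the path (the plateau's own ceiling).
  # The attachment is taken as the outermost point whose width is within
  # half a bin of the flagellar plateau ceiling (the plateau's interior
  # maximum): the body-side end is trimmed back where the tolerance window
  # let body-taper pixels in, or extended along the full skeleton where
  # body adjacency inflated the transform and cut the region short.
  pw <- mat$values[cbind(path$points[, 1], path$points[, 2])]
  n <- nrow(path$points)
  j <- if (w1 > w2) 1L else n
  est <- path$points[j, ]
  arc <- path$arclength[j]
  if (n >= 15) {
    ceiling_w <- max(pw[6:(n - 5)]) + result$bin_width / 2
    if (w1 > w2) {
      while (j < 6L && pw[j] > ceiling_w + 1e-9) j <- j + 1L
    } else {
      while (j > n - 5L && pw[j] > ceiling_w + 1e-9) j <- j - 1L
    }
    est <- path$points[j, ]
    arc <- path$arclength[j]
    trimmed <- j != (if (w1 > w2) 1L else n)
    if (!trimmed) {
      prev <- if (w1 > w2) path$points[2, ] else path$points[n - 1, ]
      ext <- walk_skeleton_beyond(mat, est, prev, region_keys, dims,
                                  max_steps = 6)
      if (nrow(ext$points)) {
        wext <- mat$values[cbind(ext$points[, 1], ext$points[, 2])]
        k <- 0L
        while (k < nrow(ext$points) && wext[k + 1] <= ceiling_w + 1e-9)
          k <- k + 1L
        if (k > 0L) {
          est <- ext$points[k, ]
          arc <- arc + ext$arclength[k]
        }
      }
    }
  }
  new_attachment_estimate(est, arc, "modal", low_conf,
                          path_point = path$points[j, ])
}

# Greedy direction-preserving walk along the full skeleton from a region
# endpoint, excluding region pixels; returns up to `max_steps` points.
walk_skeleton_beyond <- function(mat, start, prev, region_keys, dims, max_steps = 6) {
  visited <- c(region_keys, px_key(matrix(start, 1, 2), dims[1]))
  cur <- as.numeric(start)
  dir <- unit(cur - as.numeric(prev))
  pts <- matrix(numeric(0), 0, 2)
  arcs <- numeric(0)
  total <- 0
  for (s in seq_len(max_steps)) {
    nb <- sk_neighbors(mat$skeleton, cur)
    if (!nrow(nb)) break
    nb <- nb[!(px_key(nb, dims[1]) %in% visited), , drop = FALSE]
    if (!nrow(nb)) break
    dots <- ((nb[, 1] - cur[1]) * dir[1] + (nb[, 2] - cur[2]) * dir[2]) /
      sqrt((nb[, 1] - cur[1])^2 + (nb[, 2] - cur[2])^2)
    best <- which(dots >= max(dots) - 1e-12)
    best <- best[order(nb[best, 1], nb[best, 2])][1]
    nxt <- nb[best, ]
    total <- total + sqrt(sum((nxt - cur)^2))
    dir <- unit(nxt - cur)
    pts <- rbind(pts, nxt)
    arcs <- c(arcs, total)
    visited <- c(visited, px_key(matrix(nxt, 1, 2), dims[1]))
    cur <- nxt
  }
  list(points = pts, arclength = arcs)
}
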