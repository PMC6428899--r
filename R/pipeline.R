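# Fully-automatic per-frame pipeline: binarise, medial axis transform,
# modal (or derivative) identification, trace; plus stack I/O and writers.

#' Pipeline configuration
#'
#' Collects every tunable of the identification pipeline with its default.
#' Frames are processed independently (no temporal prior); the identification
#' method defaults to modal analysis, which is more robust than the
#' derivative alternative.
#'
#' @param method `"modal"` (default) or `"derivative"`.
#' @param subtract_background `"none"` (default; suits clean or synthetic
#'   stacks) or `"median"` (temporal-median background subtraction for
#'   recordings with static clutter; requires the whole stack in memory).
#' @param threshold_method automatic threshold for [binarize()].
#' @param min_object_area_px,fill_hole_area_px mask cleanup sizes, px.
#' @param bin_width_px,modal_tolerance_px,min_region_px modal analysis
#'   settings, see [modal_segment()].
#' @param derivative_step,outlier_k derivative analysis settings, see
#'   [derivative_segment()].
#' @param stitch_radius_px gap-stitching radius; `NULL` (default) uses twice
#'   the frame's modal half-width, i.e. the approximate flagellum width.
#' @param tangent_window tangent-averaging window for branch resolution, px.
#' @param d_px evaluation distance tolerance (px).
#' @param success_mdr_max,success_fdr_max per-frame success thresholds (%).
#' @param frame_range optional integer vector of frames to process.
#' @param output_dir optional directory for CSV/TIFF/JSON outputs.
#' @param verbose log one line per frame.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(method = c("modal", "derivative"),
                            subtract_background = c("none", "median"),
                            threshold_method = "otsu",
                            min_object_area_px = 9,
                            fill_hole_area_px = 9,
                            bin_width_px = 1,
                            modal_tolerance_px = 1,
                            min_region_px = 5,
                            derivative_step = 3,
                            outlier_k = 3,
                            stitch_radius_px = NULL,
                            tangent_window = 5,
                            d_px = 3,
                            success_mdr_max = 10,
                            success_fdr_max = 10,
                            frame_range = NULL,
                            output_dir = NULL,
                            verbose = FALSE) {
  structure(list(
    method = match.arg(method),
    subtract_background = match.arg(subtract_background),
    threshold_method = threshold_method,
    min_object_area_px = min_object_area_px,
    fill_hole_area_px = fill_hole_area_px,
    bin_width_px = bin_width_px,
    modal_tolerance_px = modal_tolerance_px,
    min_region_px = min_region_px,
    derivative_step = derivative_step,
    outlier_k = outlier_k,
    stitch_radius_px = stitch_radius_px,
    tangent_window = tangent_window,
    d_px = d_px,
    success_mdr_max = success_mdr_max,
    success_fdr_max = success_fdr_max,
    frame_range = frame_range,
    output_dir = output_dir,
    verbose = verbose
  ), class = "pipeline_config")
}

# Mean width of up to `k` skeleton pixels reachable from an endpoint.
terminal_width <- function(mat, ep, k = 5) {
  path <- resolve_branches(mat$skeleton, ep, window = k)
  n <- min(k, nrow(path$points))
  mean(mat$values[cbind(path$points[1:n, 1], path$points[1:n, 2])])
}

#' Process a single frame
#'
#' Runs binarisation, the medial axis transform and flagellar identification
#' on one grayscale frame. Algorithmic failures (segmentation or
#' identification) are contained and reported in the result's status.
#'
#' @param frame numeric matrix.
#' @param config a [pipeline_config()].
#' @param frame_index index recorded in the result.
#' @return A `frame_result`: list with `frame_index`, `status` (`"ok"`,
#'   `"partial"` or `"failed"`), `trace` (a `flagellum_trace` or `NULL`),
#'   `modal_width`, and `reason` for failures.
#' @export
process_frame <- function(frame, config = pipeline_config(), frame_index = NA_integer_) {
  out <- tryCatch({
    mask <- binarize(frame,
                     min_object_area_px = config$min_object_area_px,
                     fill_hole_area_px = config$fill_hole_area_px,
                     threshold_method = config$threshold_method)
    mat <- medial_axis_transform(mask)
    if (config$method == "modal") {
      res <- modal_segment(mat, tolerance = config$modal_tolerance_px,
                           bin_width = config$bin_width_px,
                           min_region_px = config$min_region_px)
      radius <- config$stitch_radius_px %||% (2 * res$modal_width)
      st <- stitch_segments(res$candidate_regions, radius, dim = dim(mat$values))
      ord <- order_regions(st$regions, config$min_region_px)
      res$candidate_regions <- ord$regions
      res$selected <- ord$regions[[ord$pick]]
      res$low_confidence <- ord$low_confidence
      att <- attachment_from_modal(res, mat)
      trace <- trace_flagellum(res, att, mat, window = config$tangent_window,
                               frame_index = frame_index)
      modal_width <- res$modal_width
    } else {
      eps <- skeleton_endpoints(mat$skeleton)
      if (nrow(eps) < 2)
        flag_failure("skeleton has fewer than two endpoints",
                     "flagtrace_identification_failure")
      tw <- vapply(seq_len(nrow(eps)), function(i) terminal_width(mat, eps[i, ]),
                   numeric(1))
      tip <- eps[order(tw, eps[, 1], eps[, 2])[1], ]
      path <- resolve_branches(mat$skeleton, tip, window = config$tangent_window)
      profile <- structure(list(points = path$points, arclength = path$arclength,
                                widths = mat$values[cbind(path$points[, 1],
                                                          path$points[, 2])]),
                           class = "width_profile")
      att <- derivative_segment(profile, step = config$derivative_step,
                                outlier_k = config$outlier_k)
      i <- which(path$points[, 1] == att$point[1] & path$points[, 2] == att$point[2])[1]
      idx <- rev(seq_len(i))  # attachment -> tip
      pts <- path$points[idx, , drop = FALSE]
      seg <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
      trace <- structure(list(points = pts, widths_px = profile$widths[idx],
                              arclength_px = cumsum(c(0, seg)),
                              length_px = sum(seg), attachment = att,
                              frame_index = frame_index, partial = FALSE,
                              low_confidence = isTRUE(att$low_confidence)),
                         class = "flagellum_trace")
      modal_width <- width_histogram(mat, bin_width = config$bin_width_px)$modal_width
    }
    list(frame_index = frame_index,
         status = if (trace$partial) "partial" else "ok",
         trace = trace, modal_width = modal_width, reason = NA_character_)
  }, flagtrace_failure = function(e) {
    list(frame_index = frame_index, status = "failed", trace = NULL,
         modal_width = NA_real_, reason = conditionMessage(e))
  })
  structure(out, class = "frame_result")
}

# A frame source abstracts streaming access to a stack: at no point are more
# than a constant number of frames materialised (unless median background
# subtraction is requested).
frame_source <- function(input) {
  if (inherits(input, "phantom")) input <- input$frames
  if (is.matrix(input)) input <- list(input)
  if (is.list(input)) {
    stopifnot(all(vapply(input, is.matrix, logical(1))))
    return(list(n = length(input), get = function(i) input[[i]]))
  }
  if (is.character(input) && length(input) == 1 && dir.exists(input)) {
    input <- sort(list.files(input, pattern = "\\.(tif|tiff|png)$",
                             ignore.case = TRUE, full.names = TRUE))
  }
  if (is.character(input) && length(input) == 1) {
    if (!file.exists(input)) stop("cannot read input: ", input)
    info <- tiff::readTIFF(input, all = TRUE, payload = FALSE)
    n <- nrow(info)  # one row of metadata per page
    return(list(n = n, get = function(i) {
      fr <- tiff::readTIFF(input, all = i)[[1]]
      if (length(dim(fr)) == 3) fr <- apply(fr, c(1, 2), mean)
      fr * 255
    }))
  }
  if (is.character(input)) {
    files <- input
    if (!length(files)) stop("empty frame stack")
    if (!all(file.exists(files))) stop("cannot read input: missing frame files")
    return(list(n = length(files), get = function(i) {
      f <- files[i]
      fr <- if (grepl("\\.png$", f, ignore.case = TRUE)) {
        if (!requireNamespace("png", quietly = TRUE))
          stop("reading PNG frames requires the 'png' package")
        png::readPNG(f)
      } else tiff::readTIFF(f)
      if (length(dim(fr)) == 3) fr <- apply(fr, c(1, 2), mean)
      fr * 255
    }))
  }
  stop("unsupported input type for run_pipeline()")
}

#' Run the identification pipeline over a video stack
#'
#' Processes every frame of a stack independently and without user input:
#' binary mask, medial axis transform, modal (or derivative) width analysis,
#' centerline trace. Per-frame algorithm failures are contained (the frame
#' is marked failed, the run continues); unreadable input is a fatal error.
#'
#' @param input a multi-page TIFF path, a directory or vector of per-frame
#'   TIFF/PNG files, a list of numeric matrices, or a [make_phantom()]
#'   result.
#' @param config a [pipeline_config()]. When `config$output_dir` is set,
#'   writes `traces.csv` (frame, point_index, row, col, width_px,
#'   arclength_px), `attachments.csv` (frame, row, col, confidence), an
#'   overlay multi-page TIFF with the identified centerline in white, and a
#'   `manifest.json` echoing the configuration. Re-running with identical
#'   input and configuration reproduces the CSV outputs bit for bit.
#' @return list of `frame_result`s (class `pipeline_result`).
#' @export
run_pipeline <- function(input, config = pipeline_config()) {
  src <- frame_source(input)
  idx <- config$frame_range %||% seq_len(src$n)
  if (src$n == 0 || !length(idx)) stop("empty frame stack: nothing to process")
  if (any(idx < 1 | idx > src$n)) stop("frame_range outside the stack")

  pre <- identity
  if (config$subtract_background == "median") {
    stack <- lapply(idx, src$get)
    stack <- subtract_background(stack)
    src <- list(n = length(stack), get = function(i) stack[[i]])
    idx <- seq_along(stack)
  }

  keep_overlay <- !is.null(config$output_dir)
  overlays <- if (keep_overlay) vector("list", length(idx))
  results <- vector("list", length(idx))
  for (j in seq_along(idx)) {
    i <- idx[j]
    frame <- src$get(i)
    fr <- process_frame(frame, config, frame_index = i)
    results[[j]] <- fr
    if (config$verbose) {
      message(sprintf("frame %d: %s%s%s", i, fr$status,
                      if (!is.na(fr$modal_width))
                        sprintf(", modal half-width %.1f px", fr$modal_width) else "",
                      if (!is.null(fr$trace))
                        sprintf(", trace %.1f px", fr$trace$length_px) else ""))
    }
    if (keep_overlay) {
      ov <- frame
      if (!is.null(fr$trace))
        ov[fr$trace$points] <- 255
      overlays[[j]] <- pmin(pmax(ov, 0), 255) / 255
    }
  }
  class(results) <- "pipeline_result"

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(trace_table(results), file.path(config$output_dir, "traces.csv"),
              row.names = FALSE)
    write.csv(attachment_table(results),
              file.path(config$output_dir, "attachments.csv"), row.names = FALSE)
    tiff::writeTIFF(overlays, file.path(config$output_dir, "overlay.tif"),
                    bits.per.sample = 8)
    jsonlite::write_json(
      list(package = "flagtrace",
           version = as.character(utils::packageVersion("flagtrace")),
           config = config[!vapply(config, is.null, logical(1))],
           n_frames = length(results)),
      file.path(config$output_dir, "manifest.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  results
}

#' @export
print.pipeline_result <- function(x, ...) {
  st <- vapply(x, function(f) f$status, character(1))
  cat(sprintf("pipeline run: %d frames (%d ok, %d partial, %d failed)\n",
              length(x), sum(st == "ok"), sum(st == "partial"), sum(st == "failed")))
  invisible(x)
}

#' Traced centerlines of a pipeline run as a long table
#'
#' @param results a `pipeline_result`.
#' @return data frame with columns `frame`, `point_index`, `row`, `col`,
#'   `width_px`, `arclength_px`.
#' @export
trace_table <- function(results) {
  rows <- lapply(results, function(fr) {
    if (is.null(fr$trace)) return(NULL)
    t_ <- fr$trace
    data.frame(frame = fr$frame_index, point_index = seq_len(nrow(t_$points)),
               row = t_$points[, 1], col = t_$points[, 2],
               width_px = t_$widths_px, arclength_px = t_$arclength_px)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(frame = integer(0), point_index = integer(0),
                                      row = integer(0), col = integer(0),
                                      width_px = numeric(0), arclength_px = numeric(0))
  out
}

#' Attachment points of a pipeline run
#'
#' @param results a `pipeline_result`.
#' @return data frame with columns `frame`, `row`, `col`, `confidence`.
#' @export
attachment_table <- function(results) {
  rows <- lapply(results, function(fr) {
    if (is.null(fr$trace)) return(NULL)
    a <- fr$trace$attachment
    data.frame(frame = fr$frame_index, row = a$point[1], col = a$point[2],
               confidence = if (isTRUE(a$low_confidence)) "low" else "normal")
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(frame = integer(0), row = numeric(0),
                                      col = numeric(0), confidence = character(0))
  out
}
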