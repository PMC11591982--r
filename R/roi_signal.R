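#' @title Palm region-of-interest signal extraction
#' @description Turns per-frame hand landmarks and frames into a normalized
#'   per-channel mean trace over the palm quadrilateral.
#' @name roi_signal
NULL

# Signed area (shoelace); 0 for degenerate polygons.
polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  abs(sum(x * ys - xs * y)) / 2
}

# Even-odd (ray crossing) point-in-polygon test on pixel centers, 0-based
# pixel coordinates. Returns an h x w logical matrix.
polygon_pixel_mask <- function(poly, width, height) {
  px <- rep(0:(width - 1), each = height)
  py <- rep(0:(height - 1), times = width)
  inside <- rep(FALSE, length(px))
  nv <- nrow(poly)
  j <- nv
  for (i in seq_len(nv)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  matrix(inside, nrow = height, ncol = width)
}

#' Per-frame RGB channel means
#'
#' @param rgb Numeric matrix, one row per frame, columns R, G, B.
#' @param fps Sampling rate (frames/s).
#' @return An object of class `rgb_trace`.
#' @export
rgb_trace <- function(rgb, fps) {
  rgb <- as.matrix(rgb)
  if (ncol(rgb) != 3L) stop_invalid("`rgb` must have 3 columns")
  if (!is_scalar_num(fps) || fps <= 0) stop_invalid("`fps` must be > 0")
  colnames(rgb) <- c("r", "g", "b")
  structure(list(rgb = rgb, fps = fps), class = "rgb_trace")
}

#' Palm ROI polygon from hand landmarks
#'
#' The palm quadrilateral runs through hand landmarks 1 (THUMB_CMC),
#' 5 (INDEX_FINGER_MCP), 17 (PINKY_MCP) and 0 (WRIST), in that cyclic order,
#' converted from normalized image coordinates to 0-based pixel coordinates.
#'
#' @param landmarks 21x2 matrix of (x, y) in normalized \[0,1\] coordinates,
#'   rows indexed 0-20 in the standard hand-landmark order.
#' @param width,height Frame dimensions in pixels.
#' @return 4x2 matrix of polygon vertices in pixel coordinates.
#' @export
roi_polygon <- function(landmarks, width, height) {
  landmarks <- as.matrix(landmarks)
  if (nrow(landmarks) != 21L || ncol(landmarks) != 2L) {
    stop_invalid("`landmarks` must be a 21x2 matrix")
  }
  if (!all(is.finite(landmarks))) stop_invalid("landmark coordinates must be finite")
  # 1-based rows: landmark k lives at row k + 1
  poly <- landmarks[c(2L, 6L, 18L, 1L), , drop = FALSE]
  poly[, 1] <- poly[, 1] * (width - 1)
  poly[, 2] <- poly[, 2] * (height - 1)
  if (polygon_area(poly) <= .Machine$double.eps * max(width, height)^2) {
    palmbp_stop("ROI polygon is degenerate (collinear or coincident landmarks)",
                "degenerate_roi")
  }
  poly
}

#' Mean R, G, B inside the ROI, per frame
#'
#' Averages each color channel over pixels whose centers fall strictly
#' inside the polygon (even-odd rule).
#'
#' @param frames List of height x width x 3 arrays.
#' @param polygon 4x2 (or n x 2) polygon in pixel coordinates.
#' @param fps Sampling rate of the sequence.
#' @return An [rgb_trace()] with one row per frame (zero rows if `frames` is
#'   empty).
#' @export
channel_means <- function(frames, polygon, fps) {
  if (length(frames) == 0L) {
    return(rgb_trace(matrix(numeric(0), ncol = 3), fps))
  }
  d <- dim(frames[[1]])
  mask <- polygon_pixel_mask(as.matrix(polygon), d[2], d[1])
  if (!any(mask)) palmbp_stop("ROI polygon has an empty pixel interior", "degenerate_roi")
  idx <- which(mask)
  out <- t(vapply(frames, function(fr) {
    c(mean(fr[, , 1][idx]), mean(fr[, , 2][idx]), mean(fr[, , 3][idx]))
  }, numeric(3)))
  rgb_trace(out, fps)
}

#' Z-score a channel trace over the capture window
#'
#' Each channel is independently centered to mean zero and scaled to unit
#' variance (population convention, dividing by n), the preprocessing that
#' independent component analysis expects. A constant channel maps to all
#' zeros.
#'
#' @param trace An [rgb_trace()] with at least 2 frames.
#' @return The normalized [rgb_trace()].
#' @export
normalize_trace <- function(trace) {
  stopifnot(inherits(trace, "rgb_trace"))
  n <- nrow(trace$rgb)
  if (n < 2L) stop_invalid("normalization needs at least 2 frames")
  z <- apply(trace$rgb, 2, function(v) {
    m <- mean(v)
    s <- sqrt(mean((v - m)^2))
    if (s == 0) rep(0, length(v)) else (v - m) / s
  })
  rgb_trace(z, trace$fps)
}

#' Read per-frame landmarks from JSON
#'
#' Expects `{"frames":[{"points":[[x,y], ... 21]}, ...]}` with normalized
#' coordinates.
#'
#' @param path JSON file path.
#' @return List of 21x2 landmark matrices, one per frame.
#' @export
read_landmarks <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyMatrix = TRUE, simplifyDataFrame = FALSE)
  if (is.null(doc$frames)) stop_invalid("landmark JSON must have a `frames` array")
  lapply(doc$frames, function(fr) {
    m <- as.matrix(fr$points)
    if (nrow(m) != 21L || ncol(m) != 2L) {
      stop_invalid("each landmark frame must hold 21 (x, y) points")
    }
    m
  })
}

#' @rdname read_landmarks
#' @param landmarks List of 21x2 matrices.
#' @export
write_landmarks <- function(landmarks, path) {
  doc <- list(frames = lapply(landmarks, function(m) list(points = unname(as.matrix(m)))))
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}
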