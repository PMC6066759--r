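# Marker tracking: find the two colored guide-wire markers in a camera
# frame and derive the wire's 2-D pose (tip + unit direction).
#
# A frame is an H x W x 3 numeric array of 8-bit RGB values (0..255).
# Pixel (row r, col c) has image coordinates (x = c - 1, y = r - 1):
# 0-based, x rightward, y downward, matching the geometry module.

#' Construct a camera frame
#'
#' @param pixels H x W x 3 array of RGB values in `[0, 255]`.
#' @param frame_id integer frame identifier.
#' @param timestamp acquisition time in seconds.
#' @return A `camera_frame` object (list with `pixels`, `frame_id`,
#'   `timestamp`).
#' @export
camera_frame <- function(pixels, frame_id = 0L, timestamp = 0) {
  pixels <- check_pixels(pixels)
  structure(list(pixels = pixels, frame_id = as.integer(frame_id),
                 timestamp = as.numeric(timestamp)),
            class = "camera_frame")
}

check_pixels <- function(pixels) {
  if (length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    ft_stop("frame pixels must be an H x W x 3 array",
            "fluorotrack_invalid_input")
  if (any(dim(pixels)[1:2] < 16L))
    ft_stop("frame must be at least 16 x 16", "fluorotrack_invalid_input")
  if (any(pixels < 0 | pixels > 255) || any(!is.finite(pixels)))
    ft_stop("channel values must lie in [0, 255]",
            "fluorotrack_invalid_input")
  pixels
}

frame_pixels <- function(frame) {
  if (inherits(frame, "camera_frame")) frame$pixels else check_pixels(frame)
}

#' Marker color specification
#'
#' An axis-aligned box threshold in RGB: a pixel matches when every
#' channel lies within `tol` of `target`. The two roles must be
#' separable: targets must differ by more than `2 * tol` in at least one
#' channel across a spec pair.
#'
#' @param target length-3 RGB triple in `[0, 255]`.
#' @param tol per-channel absolute tolerance (>= 0).
#' @param role `"proximal"` or `"distal"` (position along the wire).
#' @return A `color_spec` object.
#' @export
color_spec <- function(target, tol = 30, role = c("proximal", "distal")) {
  role <- match.arg(role)
  ft_assert_finite(target, "target color")
  if (length(target) != 3L || any(target < 0) || any(target > 255))
    ft_stop("target must be an RGB triple in [0, 255]",
            "fluorotrack_invalid_input")
  if (tol < 0) ft_stop("tol must be >= 0", "fluorotrack_invalid_input")
  structure(list(target = as.numeric(target), tol = as.numeric(tol),
                 role = role), class = "color_spec")
}

#' Segment a frame by marker color
#'
#' @param frame a [camera_frame()] or H x W x 3 array.
#' @param spec a [color_spec()].
#' @return A logical H x W mask, `TRUE` where every channel of the pixel
#'   is within `spec$tol` of `spec$target`. An all-`FALSE` mask is valid.
#' @export
segment_color <- function(frame, spec) {
  px <- frame_pixels(frame)
  abs(px[, , 1] - spec$target[1]) <= spec$tol &
    abs(px[, , 2] - spec$target[2]) <= spec$tol &
    abs(px[, , 3] - spec$target[3]) <= spec$tol
}

#' Label 8-connected components of a binary mask
#'
#' Components are numbered in row-major discovery order, so component 1
#' is the one whose top-left pixel (smallest `(row, col)` lexicographic)
#' comes first -- this makes downstream tie-breaking deterministic.
#'
#' @param mask logical matrix.
#' @return An integer matrix of the same shape; 0 is background.
#' @export
label_components <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  labels <- matrix(0L, H, W)
  fg <- which(mask, arr.ind = TRUE)
  if (!nrow(fg)) return(labels)
  fg <- fg[order(fg[, 1], fg[, 2]), , drop = FALSE]  # row-major seeds
  next_label <- 0L
  for (k in seq_len(nrow(fg))) {
    r <- fg[k, 1]; c <- fg[k, 2]
    if (labels[r, c] != 0L) next
    next_label <- next_label + 1L
    labels[r, c] <- next_label
    stack_r <- r; stack_c <- c
    while (length(stack_r)) {
      cr <- stack_r[length(stack_r)]; cc <- stack_c[length(stack_c)]
      stack_r <- stack_r[-length(stack_r)]
      stack_c <- stack_c[-length(stack_c)]
      nr <- pmax(1L, cr - 1L):pmin(H, cr + 1L)
      nc <- pmax(1L, cc - 1L):pmin(W, cc + 1L)
      for (rr in nr) for (ccc in nc) {
        if (mask[rr, ccc] && labels[rr, ccc] == 0L) {
          labels[rr, ccc] <- next_label
          stack_r <- c(stack_r, rr); stack_c <- c(stack_c, ccc)
        }
      }
    }
  }
  labels
}

#' Locate the colored wire markers in a frame
#'
#' Each spec's color mask is decomposed into 8-connected components; the
#' largest component with at least `min_area` pixels yields that role's
#' detection, with the intensity-unweighted centroid of its pixels. A
#' role with no sufficiently large component raises
#' `fluorotrack_markers_not_found` (the occlusion failure mode). In
#' `strict` mode an exact area tie between the two largest components
#' raises `fluorotrack_ambiguous_marker`; otherwise the component whose
#' top-left pixel comes first in `(row, col)` order wins.
#'
#' @param frame a [camera_frame()] or H x W x 3 array.
#' @param specs list of two [color_spec()]s, one proximal and one distal.
#' @param min_area minimum component pixel count (default 10).
#' @param strict raise on area ties instead of breaking them.
#' @return A list of detections, each a list with `role`,
#'   `centroid` (`c(x, y)`, sub-pixel) and `area` (pixel count).
#' @export
locate_markers <- function(frame, specs, min_area = 10L, strict = FALSE) {
  roles <- vapply(specs, function(s) s$role, character(1))
  if (!setequal(roles, c("proximal", "distal")))
    ft_stop("specs must contain one proximal and one distal entry",
            "fluorotrack_invalid_input")
  lapply(specs, function(spec) {
    mask <- segment_color(frame, spec)
    labels <- label_components(mask)
    n <- max(labels)
    areas <- if (n > 0L) tabulate(labels[labels > 0L], nbins = n) else integer(0)
    keep <- which(areas >= min_area)
    if (!length(keep))
      ft_stop(sprintf("no %s marker component of area >= %d (occluded?)",
                      spec$role, min_area),
              "fluorotrack_markers_not_found")
    best_area <- max(areas[keep])
    cands <- keep[areas[keep] == best_area]
    if (strict && length(cands) > 1L)
      ft_stop(sprintf("%d %s components tie at area %d",
                      length(cands), spec$role, best_area),
              "fluorotrack_ambiguous_marker")
    best <- min(cands)  # smallest label = earliest (row, col) top-left
    idx <- which(labels == best, arr.ind = TRUE)
    list(role = spec$role,
         centroid = c(mean(idx[, "col"]) - 1, mean(idx[, "row"]) - 1),
         area = best_area)
  })
}

#' Derive the wire's 2-D pose from the two marker centroids
#'
#' The wire direction points from the proximal to the distal marker; the
#' tip lies `tip_offset` pixels beyond the distal marker along that
#' direction (the marker-to-tip distance is a per-plane calibration
#' input -- markers are treated as rigidly collinear with the tip).
#'
#' @param proximal,distal detections from [locate_markers()] or bare
#'   `c(x, y)` centroids.
#' @param tip_offset distance from the distal centroid to the wire tip,
#'   in pixels.
#' @return A `wire_pose` list with `tip` (`c(x, y)`) and `direction`
#'   (unit 2-vector).
#' @details Centroids separated by 1 px or less raise
#'   `fluorotrack_degenerate_pose`.
#' @export
wire_pose_from_markers <- function(proximal, distal, tip_offset = 0) {
  p <- as_centroid(proximal); d <- as_centroid(distal)
  v <- d - p
  len <- sqrt(sum(v^2))
  if (len <= 1)
    ft_stop("marker centroids coincide (separation <= 1 px)",
            "fluorotrack_degenerate_pose")
  dir <- v / len
  structure(list(tip = d + tip_offset * dir, direction = dir),
            class = "wire_pose")
}

as_centroid <- function(m) {
  p <- if (is.list(m)) m$centroid else m
  ft_assert_finite(p, "centroid")
  if (length(p) != 2L)
    ft_stop("centroid must have length 2", "fluorotrack_invalid_input")
  as.numeric(p)
}

#' Read / write camera frames and masks as PNG
#'
#' Frames are 8-bit RGB; masks are written as 0/255 grayscale.
#'
#' @param path PNG file path.
#' @return `read_frame_png`: a [camera_frame()].
#' @export
read_frame_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1:3, drop = FALSE]
  else img <- array(rep(img, 3L), c(dim(img), 3L))
  camera_frame(round(img * 255))
}

#' @rdname read_frame_png
#' @param frame a [camera_frame()] or H x W x 3 array.
#' @export
write_frame_png <- function(frame, path) {
  png::writePNG(frame_pixels(frame) / 255, path)
  invisible(path)
}

#' @rdname read_frame_png
#' @param mask logical matrix from [segment_color()].
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' Write marker detections as JSON records
#'
#' One record per detection: `{frame_id, role, centroid: [x, y], area}`.
#'
#' @param detections list from [locate_markers()].
#' @param frame_id integer frame identifier stored with each record.
#' @param path JSON file path.
#' @export
write_detections <- function(detections, frame_id, path) {
  recs <- lapply(detections, function(d)
    list(frame_id = as.integer(frame_id), role = d$role,
         centroid = d$centroid, area = d$area))
  jsonlite::write_json(recs, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
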