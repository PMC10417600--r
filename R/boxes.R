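#' Default frame size of the chamber cameras
#'
#' Width and height in pixels of the overhead camera frames (702 x 480 by
#' default, matching the low-cost CCD cameras used in the chamber). Pixel
#' coordinates have their origin at the top-left corner, x growing rightward
#' and y downward.
#'
#' @return integer vector \code{c(width, height)}.
#' @export
default_frame_size <- function() c(width = 702L, height = 480L)

#' Validate bounding boxes
#'
#' Checks the box invariants: \code{x_min < x_max}, \code{y_min < y_max}, all
#' coordinates non-negative and within the frame, and area at least
#' \code{min_area}.
#'
#' @param boxes data frame with columns \code{x_min,y_min,x_max,y_max}.
#' @param frame_size \code{c(width, height)} in pixels.
#' @param min_area minimum admissible box area in square pixels; degenerate
#'   (near-zero-area) boxes below it are rejected.
#' @return logical vector, \code{TRUE} for valid rows.
#' @export
valid_boxes <- function(boxes, frame_size = default_frame_size(),
                        min_area = 1e-6) {
  with(boxes,
       is.finite(x_min) & is.finite(y_min) & is.finite(x_max) & is.finite(y_max) &
       x_min < x_max & y_min < y_max &
       x_min >= 0 & y_min >= 0 &
       x_max <= frame_size[[1]] & y_max <= frame_size[[2]] &
       (x_max - x_min) * (y_max - y_min) >= min_area)
}

#' Centroid of bounding boxes
#'
#' The arithmetic midpoint of each box, the point feature consumed by the
#' unrest index and the occupancy counts.
#'
#' @param boxes data frame (or one-row list) with columns
#'   \code{x_min,y_min,x_max,y_max}.
#' @return data frame with columns \code{x}, \code{y} in pixels.
#' @examples
#' centroid(data.frame(x_min = 0, y_min = 0, x_max = 10, y_max = 20))
#' @export
centroid <- function(boxes) {
  data.frame(x = (boxes$x_min + boxes$x_max) / 2,
             y = (boxes$y_min + boxes$y_max) / 2)
}

#' Intersection-over-union of two box sets
#'
#' @param a,b data frames of boxes (columns \code{x_min,y_min,x_max,y_max});
#'   the result is the \code{nrow(a)} x \code{nrow(b)} IoU matrix.
#' @return numeric matrix of IoU values in \[0, 1\].
#' @export
box_iou <- function(a, b) {
  ix <- pmax(0, outer(a$x_max, b$x_max, pmin) - outer(a$x_min, b$x_min, pmax))
  iy <- pmax(0, outer(a$y_max, b$y_max, pmin) - outer(a$y_min, b$y_min, pmax))
  inter <- ix * iy
  area_a <- (a$x_max - a$x_min) * (a$y_max - a$y_min)
  area_b <- (b$x_max - b$x_min) * (b$y_max - b$y_min)
  inter / (outer(area_a, area_b, `+`) - inter)
}
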