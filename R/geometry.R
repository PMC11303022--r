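#' Rectangle constructor
#'
#' Rectangles are half-open pixel regions `[x0, x1) x [y0, y1)` in screen
#' coordinates (origin top-left, x rightward, y downward).
#'
#' @param x0,y0,x1,y1 Corner coordinates in pixels; `x1 > x0`, `y1 > y0`.
#' @return A named numeric vector of class `"gb_rect"`.
#' @export
gb_rect <- function(x0, y0, x1, y1) {
  stopifnot(is.numeric(x0), is.numeric(y0), is.numeric(x1), is.numeric(y1),
            x1 > x0, y1 > y0)
  structure(c(x0 = x0, y0 = y0, x1 = x1, y1 = y1), class = "gb_rect")
}

#' Test whether points fall inside a rectangle
#'
#' Membership uses the half-open convention: a point on the right or bottom
#' edge is outside, so a point on the shared boundary of two adjacent
#' rectangles belongs to at most one of them.
#'
#' @param x,y Numeric vectors of pixel coordinates (recycled together).
#' @param rect A rectangle from [gb_rect()].
#' @return Logical vector.
#' @export
in_rect <- function(x, y, rect) {
  x >= rect[["x0"]] & x < rect[["x1"]] & y >= rect[["y0"]] & y < rect[["y1"]]
}

rect_center <- function(rect) {
  c(x = (rect[["x0"]] + rect[["x1"]]) / 2, y = (rect[["y0"]] + rect[["y1"]]) / 2)
}

#' Screen and region-of-interest geometry
#'
#' Describes the monitor and the three regions of interest used by the
#' paradigm: one ROI over each of the two simultaneously presented scenes,
#' and a central ROI covering the pre-stimulus fixation video. Defaults
#' match a 1280 x 1024 monitor with 500 x 430 px stimuli centred vertically
#' and placed symmetrically left and right of the midline.
#'
#' @param width_px,height_px Monitor size in pixels.
#' @param stim_width_px,stim_height_px Stimulus size in pixels.
#' @param inner_gap_px Horizontal gap between the two ROIs, in pixels.
#' @param center_size_px Side length of the square central fixation ROI.
#' @return An object of class `"screen_geometry"`: a list with `width_px`,
#'   `height_px` and rectangles `left_roi`, `right_roi`, `center_roi`.
#' @examples
#' geom <- screen_geometry()
#' in_rect(300, 500, geom$left_roi)
#' @export
screen_geometry <- function(width_px = 1280L, height_px = 1024L,
                            stim_width_px = 500L, stim_height_px = 430L,
                            inner_gap_px = 160L, center_size_px = 200L) {
  stopifnot(width_px > 0, height_px > 0,
            2 * stim_width_px + inner_gap_px <= width_px,
            stim_height_px <= height_px)
  y0 <- (height_px - stim_height_px) / 2
  lx1 <- width_px / 2 - inner_gap_px / 2
  rx0 <- width_px / 2 + inner_gap_px / 2
  cy0 <- (height_px - center_size_px) / 2
  cx0 <- (width_px - center_size_px) / 2
  geom <- list(
    width_px = width_px, height_px = height_px,
    left_roi = gb_rect(lx1 - stim_width_px, y0, lx1, y0 + stim_height_px),
    right_roi = gb_rect(rx0, y0, rx0 + stim_width_px, y0 + stim_height_px),
    center_roi = gb_rect(cx0, cy0, cx0 + center_size_px, cy0 + center_size_px)
  )
  class(geom) <- "screen_geometry"
  validate_geometry(geom)
  geom
}

validate_geometry <- function(geom) {
  for (nm in c("left_roi", "right_roi", "center_roi")) {
    r <- geom[[nm]]
    if (r[["x0"]] < 0 || r[["y0"]] < 0 ||
        r[["x1"]] > geom$width_px || r[["y1"]] > geom$height_px) {
      stop(sprintf("ROI '%s' does not lie inside the screen", nm))
    }
  }
  if (geom$left_roi[["x1"]] > geom$right_roi[["x0"]]) {
    stop("left and right ROIs must be disjoint")
  }
  invisible(geom)
}

#' @export
print.screen_geometry <- function(x, ...) {
  cat(sprintf("Screen %d x %d px\n", x$width_px, x$height_px))
  for (nm in c("left_roi", "right_roi", "center_roi")) {
    r <- x[[nm]]
    cat(sprintf("  %-10s [%g, %g) x [%g, %g)\n", nm,
                r[["x0"]], r[["x1"]], r[["y0"]], r[["y1"]]))
  }
  invisible(x)
}
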