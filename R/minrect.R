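#' Minimum-area rotated bounding rectangle of a binary mask
#'
#' Fits the smallest-area rectangle, at any orientation, that encloses every
#' foreground pixel of a binary mask. The rectangle supplies both the two
#' side lengths and the in-plane orientation that later drives the upright
#' re-alignment of the mushroom; an axis-aligned box carries no angle, which
#' is why the rotated variant is used throughout.
#'
#' The fit runs rotating calipers over the convex hull of the foreground
#' pixel centers: every hull-edge orientation (plus the axis-aligned
#' orientation) is a candidate, and the candidate minimising the rectangle
#' area wins. Side lengths are reported as the pixel-center extent plus one
#' pixel, so a filled axis-aligned `40 x 20` block measures `40 x 20`.
#'
#' Coordinate and angle conventions, used everywhere in the package: the
#' image origin is the top-left corner, x increases rightward (columns), y
#' increases downward (rows); `angle_deg` is measured from the image x-axis
#' to the rectangle's long side and normalised into `[-90, 90)`.
#'
#' @param mask A binary [label_mask()] (or any matrix where foreground is
#'   `> 0`).
#' @return An object of class `rotated_rect`: a list with fields `center_x`,
#'   `center_y`, `long_side`, `short_side` (pixels, `long_side >=
#'   short_side`) and `angle_deg`.
#' @examples
#' m <- matrix(0L, 60, 60); m[20:39, 10:49] <- 1L
#' min_bounding_rect(m)   # 40 x 20, angle 0
#' @export
min_bounding_rect <- function(mask) {
  idx <- which(unclass(mask) > 0, arr.ind = TRUE)
  if (nrow(idx) < 3L) stop(degenerate_geometry_error("fewer than 3 foreground pixels"))
  x <- as.numeric(idx[, 2L])
  y <- as.numeric(idx[, 1L])
  hull <- grDevices::chull(x, y)
  hx <- x[hull]; hy <- y[hull]
  nh <- length(hull)
  if (nh < 3L || polygon_area(hx, hy) < .Machine$double.eps) {
    stop(degenerate_geometry_error("foreground pixels are collinear"))
  }
  # candidate orientations: each hull edge, plus axis alignment so the
  # fitted area can never exceed the naive axis-aligned box
  ex <- c(diff(hx), hx[1L] - hx[nh], 1)
  ey <- c(diff(hy), hy[1L] - hy[nh], 0)
  len <- sqrt(ex^2 + ey^2)
  ok <- len > 0
  ux <- ex[ok] / len[ok]; uy <- ey[ok] / len[ok]

  best <- NULL
  best_area <- Inf
  for (i in seq_along(ux)) {
    pu <- hx * ux[i] + hy * uy[i]          # along the edge
    pv <- -hx * uy[i] + hy * ux[i]         # along the edge normal
    w <- max(pu) - min(pu)
    h <- max(pv) - min(pv)
    area <- (w + 1) * (h + 1)
    if (area < best_area - 1e-9) {
      best_area <- area
      cu <- (max(pu) + min(pu)) / 2
      cv <- (max(pv) + min(pv)) / 2
      best <- list(
        center_x = cu * ux[i] - cv * uy[i],
        center_y = cu * uy[i] + cv * ux[i],
        w = w + 1, h = h + 1,
        ang_u = atan2(uy[i], ux[i]) * 180 / pi
      )
    }
  }
  if (best$w >= best$h) {
    long <- best$w; short <- best$h; ang <- best$ang_u
  } else {
    long <- best$h; short <- best$w; ang <- best$ang_u + 90
  }
  rotated_rect(best$center_x, best$center_y, long, short, ang)
}

#' @param center_x,center_y Rectangle center, pixels.
#' @param long_side,short_side Side lengths, pixels.
#' @param angle_deg Orientation of the long side, degrees from the image
#'   x-axis, any value (normalised into `[-90, 90)`).
#' @rdname min_bounding_rect
#' @export
rotated_rect <- function(center_x, center_y, long_side, short_side, angle_deg) {
  if (!(long_side >= short_side && short_side > 0)) {
    stop("rotated_rect requires long_side >= short_side > 0", call. = FALSE)
  }
  structure(
    list(
      center_x = as.numeric(center_x), center_y = as.numeric(center_y),
      long_side = as.numeric(long_side), short_side = as.numeric(short_side),
      angle_deg = normalize_angle(angle_deg)
    ),
    class = "rotated_rect"
  )
}

#' @export
print.rotated_rect <- function(x, ...) {
  cat(sprintf(
    "<rotated_rect> %.1f x %.1f px at (%.1f, %.1f), long side %.1f deg from x-axis\n",
    x$long_side, x$short_side, x$center_x, x$center_y, x$angle_deg
  ))
  invisible(x)
}

#' Normalise an angle into [-90, 90)
#'
#' Rectangle orientations are only defined modulo 180 degrees; every angle
#' the package reports lives in `[-90, 90)`.
#'
#' @param angle_deg Angle(s) in degrees.
#' @return Angle(s) in `[-90, 90)`.
#' @export
normalize_angle <- function(angle_deg) {
  ((angle_deg + 90) %% 180) - 90
}

polygon_area <- function(px, py) {
  n <- length(px)
  j <- c(n, seq_len(n - 1L))
  abs(sum(px[j] * py - px * py[j])) / 2
}

degenerate_geometry_error <- function(why) {
  structure(
    class = c("mushgrade_degenerate_geometry", "error", "condition"),
    list(message = paste0("degenerate geometry: ", why), call = NULL)
  )
}
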