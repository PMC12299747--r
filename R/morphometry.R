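#' Cap measurement from its fitted rectangle
#'
#' The cap of *Stropharia rugoso-annulata* is reliably wider than tall, so
#' the long side of its minimum-area rectangle is the diameter `D1` and the
#' short side the height `H`. The tilt is the angle the cap's H-axis
#' deviates from image vertical — because the H-axis is perpendicular to
#' the long side, this equals the rectangle's `angle_deg`. When the cap is
#' nearly square the D1 > H rule cannot orient the mushroom; the fit is
#' still returned but an ambiguity warning (condition class
#' `mushgrade_ambiguity`) is raised so callers can fall back to the stalk
#' axis (see [measure_mushroom()]).
#'
#' @param cap_rect A `rotated_rect` fitted on the cap mask.
#' @param tie_tol Side-length difference (pixels) below which the cap is
#'   considered too square to orient; default 1 px.
#' @return A list with `D1`, `H` (pixels), `tilt_deg` and `ambiguous`.
#' @export
measure_cap <- function(cap_rect, tie_tol = 1) {
  stopifnot(inherits(cap_rect, "rotated_rect"))
  ambiguous <- (cap_rect$long_side - cap_rect$short_side) < tie_tol
  if (ambiguous) {
    warning(ambiguity_warning(sprintf(
      "cap nearly square (D1 - H = %.2f px < %g px): orientation unreliable",
      cap_rect$long_side - cap_rect$short_side, tie_tol
    )))
  }
  list(
    D1 = cap_rect$long_side,
    H = cap_rect$short_side,
    tilt_deg = cap_rect$angle_deg,
    ambiguous = ambiguous
  )
}

#' Rotate a label mask upright
#'
#' Rotates a mask so that a structure tilted by `tilt_deg` becomes upright
#' (cap H-axis vertical). Labels are resampled nearest-neighbour so they
#' stay categorical, and the canvas is expanded so no foreground pixel is
#' clipped; the background fills with class 0. `tilt_deg = 0` returns the
#' input unchanged.
#'
#' @param mask A [label_mask()].
#' @param tilt_deg Tilt recovered by [measure_cap()], degrees.
#' @return A [label_mask()], generally of larger dimensions.
#' @export
rotate_upright <- function(mask, tilt_deg) {
  mask <- label_mask(mask)
  if (abs(normalize_angle(tilt_deg)) < 1e-9) return(mask)
  # EBImage treats matrix dim 1 as x; in this package's y-down row/column
  # frame its rotation sign is therefore already the inverse of tilt_deg
  rot <- EBImage::rotate(unmask(mask), normalize_angle(tilt_deg),
                         filter = "none", bg.col = 0)
  rot <- round(rot)
  storage.mode(rot) <- "integer"
  label_mask(matrix(rot, nrow(rot), ncol(rot)))
}

#' Stalk measurement from its rectangle after upright rotation
#'
#' Once the mushroom is upright, the stalk's length `L` is the rectangle
#' side whose axis lies closer to image vertical, and the diameter `D2` is
#' the perpendicular side. The rule is directional, not magnitude-based: a
#' squat stalk wider than long still gets its near-vertical side as `L`.
#' At the exact 45-degree tie both sides are equally close to vertical; the
#' tie breaks to `L = long_side` (the anatomically common case) and an
#' ambiguity warning is raised.
#'
#' @param stalk_rect A `rotated_rect` fitted on the upright stalk mask.
#' @return A list with `L` and `D2` (pixels).
#' @export
measure_stalk <- function(stalk_rect) {
  stopifnot(inherits(stalk_rect, "rotated_rect"))
  dev_long <- 90 - abs(stalk_rect$angle_deg)    # long-side axis vs vertical
  dev_short <- abs(stalk_rect$angle_deg)        # short-side axis vs vertical
  if (abs(dev_long - dev_short) < 1e-9) {
    warning(ambiguity_warning(
      "stalk rectangle at 45 degrees: both sides equally close to vertical; taking L = long side"
    ))
    return(list(L = stalk_rect$long_side, D2 = stalk_rect$short_side))
  }
  if (dev_long < dev_short) {
    list(L = stalk_rect$long_side, D2 = stalk_rect$short_side)
  } else {
    list(L = stalk_rect$short_side, D2 = stalk_rect$long_side)
  }
}

#' Grading ratios from cap and stalk dimensions
#'
#' The two quantitative grading indexes: RDHP, the cap diameter-to-height
#' ratio `D1 / H`, and RLDS, the stalk length-to-diameter ratio `L / D2`.
#' Both are unitless, so no pixel-to-millimetre calibration is needed.
#'
#' @param cap Result of [measure_cap()] (or any list with `D1`, `H`).
#' @param stalk Result of [measure_stalk()] (or any list with `L`, `D2`).
#' @return A list with `D1`, `H`, `L`, `D2`, `RDHP`, `RLDS`.
#' @export
compute_ratios <- function(cap, stalk) {
  stopifnot(cap$D1 > 0, cap$H > 0, stalk$L > 0, stalk$D2 > 0)
  list(
    D1 = cap$D1, H = cap$H, L = stalk$L, D2 = stalk$D2,
    RDHP = cap$D1 / cap$H,
    RLDS = stalk$L / stalk$D2
  )
}

#' Measure one mushroom from its label mask
#'
#' The full mask-to-measurement chain: the largest connected component of
#' each class is isolated, the cap's minimum-area rectangle gives `D1`, `H`
#' and the tilt, the whole mask is rotated upright, the stalk is re-fitted
#' on the rotated mask and read off by the vertical-side rule, and the
#' RDHP/RLDS ratios are formed. When the cap is too square to orient
#' (within `tie_tol`), the stalk's long axis is used as the vertical
#' reference instead and a warning is recorded.
#'
#' @param mask A [label_mask()] containing both cap (1) and stalk (2)
#'   pixels. Broken specimens should be screened out first with
#'   [detect_broken()].
#' @param tie_tol Cap squareness tolerance in pixels, see [measure_cap()].
#' @return A one-row tibble: `D1_px`, `H_px`, `L_px`, `D2_px`, `tilt_deg`,
#'   `RDHP`, `RLDS`, `warnings` (semicolon-joined, `""` when clean).
#' @examples
#' spec <- fixture_spec(D1 = 60, H = 30, L = 40, D2 = 20, rotation_deg = 25)
#' fx <- render_mushroom(spec)
#' measure_mushroom(fx$mask)
#' @export
measure_mushroom <- function(mask, tie_tol = 1) {
  mask <- label_mask(mask)
  warnings <- character(0)
  note <- function(msg) warnings <<- c(warnings, msg)

  cap_bin <- extract_component_mask(mask, 1L)
  stalk_bin <- extract_component_mask(mask, 2L)

  cap_rect <- min_bounding_rect(cap_bin)
  cap <- withCallingHandlers(
    measure_cap(cap_rect, tie_tol = tie_tol),
    mushgrade_ambiguity = function(w) {
      note(conditionMessage(w)); invokeRestart("muffleWarning")
    }
  )
  tilt <- cap$tilt_deg
  if (cap$ambiguous) {
    # square cap: borrow the vertical reference from the stalk's long axis
    stalk_rect0 <- min_bounding_rect(stalk_bin)
    tilt <- normalize_angle(stalk_rect0$angle_deg - 90)
    note("tilt taken from stalk long axis (square cap fallback)")
  }

  upright <- rotate_upright(mask, tilt)
  stalk_up <- extract_component_mask(upright, 2L)
  stalk_rect <- min_bounding_rect(stalk_up)
  stalk <- withCallingHandlers(
    measure_stalk(stalk_rect),
    mushgrade_ambiguity = function(w) {
      note(conditionMessage(w)); invokeRestart("muffleWarning")
    }
  )

  r <- compute_ratios(cap, stalk)
  tibble::tibble(
    D1_px = r$D1, H_px = r$H, L_px = r$L, D2_px = r$D2,
    tilt_deg = tilt, RDHP = r$RDHP, RLDS = r$RLDS,
    warnings = paste(warnings, collapse = "; ")
  )
}

ambiguity_warning <- function(msg) {
  structure(
    class = c("mushgrade_ambiguity", "warning", "condition"),
    list(message = msg, call = NULL)
  )
}
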