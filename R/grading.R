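#' Grade criteria for the two grading indexes
#'
#' Three appearance grades are defined by bands of the two quantitative
#' indexes. The defaults encode the published criteria: RDHP bands
#' first 1.5–2.5, second 1.0–1.5, third 0–1.0, and RLDS bands first 0–1.5,
#' second 1.5–2.5, third above 2.5. All bands are half-open `[lo, hi)`, so
#' boundary ownership is deterministic: an index value of exactly 1.5 falls
#' in the band that starts at 1.5. The RLDS bands must tile `(0, Inf)`; the
#' RDHP bands may stop at a finite top (2.5 by default), above which the
#' RDHP grade is `none` and the RLDS-prevails rule decides alone.
#'
#' @param rdhp,rlds Named lists mapping grade (`"1"`, `"2"`, `"3"`) to a
#'   `c(lo, hi)` interval. Defaults are the published bands.
#' @return A `grade_criteria` object (validated).
#' @examples
#' crit <- grade_criteria()
#' classify_index(2.0, crit$rdhp)   # 1
#' assign_grade(2.0, 3.0, crit)     # RLDS prevails: grade 3, conflict
#' @export
grade_criteria <- function(
    rdhp = list(`1` = c(1.5, 2.5), `2` = c(1.0, 1.5), `3` = c(0, 1.0)),
    rlds = list(`1` = c(0, 1.5), `2` = c(1.5, 2.5), `3` = c(2.5, Inf))) {
  crit <- structure(list(rdhp = lapply(rdhp, as.numeric),
                         rlds = lapply(rlds, as.numeric)),
                    class = "grade_criteria")
  validate_criteria(crit)
  crit
}

validate_criteria <- function(crit) {
  for (index in c("rdhp", "rlds")) {
    iv <- crit[[index]]
    if (!setequal(names(iv), c("1", "2", "3"))) {
      stop(invalid_criteria_error(sprintf("%s must define grades 1, 2, 3", index)))
    }
    if (!all(vapply(iv, length, 0L) == 2L) ||
        !all(vapply(iv, function(b) b[1L] < b[2L], NA))) {
      stop(invalid_criteria_error(sprintf("%s bounds must satisfy lo < hi", index)))
    }
    ord <- iv[order(vapply(iv, `[`, 0, 1L))]
    lo <- vapply(ord, `[`, 0, 1L)
    hi <- vapply(ord, `[`, 0, 2L)
    if (lo[1L] != 0) {
      stop(invalid_criteria_error(sprintf("%s bands must start at 0", index)))
    }
    if (any(hi[-3L] != lo[-1L])) {
      stop(invalid_criteria_error(sprintf("%s bands overlap or leave gaps", index)))
    }
    if (index == "rlds" && is.finite(hi[3L])) {
      stop(invalid_criteria_error("rlds bands must cover (0, Inf)"))
    }
  }
  invisible(crit)
}

#' @export
print.grade_criteria <- function(x, ...) {
  fmt <- function(b) {
    if (is.infinite(b[2L])) sprintf(">= %g", b[1L]) else sprintf("[%g, %g)", b[1L], b[2L])
  }
  cat("<grade_criteria>\n")
  for (g in c("1", "2", "3")) {
    cat(sprintf("  grade %s: RDHP %s, RLDS %s\n", g, fmt(x$rdhp[[g]]), fmt(x$rlds[[g]])))
  }
  invisible(x)
}

#' Classify a grading-index value into a grade band
#'
#' Locates the half-open band `[lo, hi)` containing each value. Values that
#' fall in no band (possible only above the RDHP top under the default
#' criteria) return `NA`, meaning grade `none`.
#'
#' @param value Positive index value(s).
#' @param intervals One index's band list, e.g. `grade_criteria()$rdhp`.
#' @return Integer grade 1/2/3, or `NA` for none. Vectorised over `value`.
#' @export
classify_index <- function(value, intervals) {
  stopifnot(all(value > 0))
  grades <- as.integer(names(intervals))
  out <- rep(NA_integer_, length(value))
  for (i in seq_along(intervals)) {
    b <- intervals[[i]]
    out[value >= b[1L] & value < b[2L]] <- grades[i]
  }
  out
}

#' Assign an appearance grade from the two indexes
#'
#' Each index is classified into its own band; when the two disagree (or
#' RDHP falls in no band) the RLDS grade prevails — RLDS is the dominant
#' index in the published criteria. The `conflict` flag records every
#' disagreement.
#'
#' @param rdhp,rlds Index values (vectorised, recycled to common length).
#' @param criteria A [grade_criteria()] object.
#' @return A tibble with columns `rdhp_grade` (integer or NA), `rlds_grade`,
#'   `grade` and `conflict`.
#' @export
assign_grade <- function(rdhp, rlds, criteria = grade_criteria()) {
  stopifnot(inherits(criteria, "grade_criteria"))
  n <- max(length(rdhp), length(rlds))
  rdhp <- rep_len(rdhp, n); rlds <- rep_len(rlds, n)
  rg <- classify_index(rdhp, criteria$rdhp)
  lg <- classify_index(rlds, criteria$rlds)
  conflict <- is.na(rg) | rg != lg
  tibble::tibble(
    rdhp_grade = rg,
    rlds_grade = lg,
    grade = lg,           # RLDS prevails whenever the two disagree
    conflict = conflict
  )
}

#' Detect broken specimens from a label mask
#'
#' A specimen is broken — and must bypass the air-blown grading entirely —
#' when (a) the cap class is absent, (b) the stalk class is absent, or (c)
#' either class fragments into more than one connected component, each
#' holding at least `min_fraction` of that class's pixels (small speckle
#' does not count as a fragment).
#'
#' @param mask A [label_mask()].
#' @param min_fraction Minimum fraction of a class's pixels a component must
#'   hold to count as a fragment; default 0.10.
#' @return A list with `broken` (logical) and `reason` (`""` when intact;
#'   otherwise which test fired, e.g. `"cap absent"`, `"stalk fragmented"`).
#' @export
detect_broken <- function(mask, min_fraction = 0.1) {
  mask <- label_mask(mask)
  for (part in c("cap", "stalk")) {
    cls <- if (part == "cap") 1L else 2L
    areas <- component_areas(mask, cls)
    if (length(areas) == 0L) {
      return(list(broken = TRUE, reason = paste(part, "absent")))
    }
    big <- sum(areas >= min_fraction * sum(areas))
    if (big > 1L) {
      return(list(broken = TRUE, reason = paste(part, "fragmented")))
    }
  }
  list(broken = FALSE, reason = "")
}

invalid_criteria_error <- function(msg) {
  structure(
    class = c("mushgrade_invalid_criteria", "error", "condition"),
    list(message = msg, call = NULL)
  )
}

# --- config (de)serialisation -------------------------------------------

criteria_to_list <- function(criteria) {
  enc <- function(iv) lapply(iv, function(b) {
    list(lo = b[1L], hi = if (is.infinite(b[2L])) ".inf" else b[2L])
  })
  list(rdhp = enc(criteria$rdhp), rlds = enc(criteria$rlds))
}

criteria_from_list <- function(x) {
  dec <- function(iv) lapply(iv, function(b) {
    hi <- if (identical(b$hi, ".inf")) Inf else as.numeric(b$hi)
    c(as.numeric(b$lo), hi)
  })
  grade_criteria(rdhp = dec(x$rdhp), rlds = dec(x$rlds))
}
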