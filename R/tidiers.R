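#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy and summarise a grade batch
#'
#' `tidy()` returns the per-image rows as a plain tibble; `glance()`
#' returns one row of batch-level summaries: image counts, per-grade
#' totals, broken and failed counts, and — when the manifest carried a
#' `true_grade` column — the per-grade correct counts and the grading
#' accuracy (mean of per-grade correct rates, percent).
#'
#' @param x A `grade_batch` from [run_pipeline()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy grade_batch
#' @export
tidy.grade_batch <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @rdname tidy.grade_batch
#' @method glance grade_batch
#' @export
glance.grade_batch <- function(x, ...) {
  graded <- x[!is.na(x$grade) & x$grade != "broken", ]
  out <- tibble::tibble(
    n_images = nrow(x),
    n_graded = nrow(graded),
    n_broken = sum(!is.na(x$grade) & x$grade == "broken"),
    n_failed = sum(!is.na(x$error)),
    n_grade1 = sum(graded$grade == "1"),
    n_grade2 = sum(graded$grade == "2"),
    n_grade3 = sum(graded$grade == "3"),
    n_conflict = sum(graded$conflict)
  )
  if ("true_grade" %in% names(x)) {
    tg <- graded$true_grade
    total <- vapply(as.character(1:3), function(g) sum(tg == g), 0L)
    correct <- vapply(as.character(1:3), function(g) {
      sum(tg == g & graded$grade == g)
    }, 0L)
    if (all(total > 0)) {
      out$accuracy_pct <- as.numeric(grading_accuracy(total, correct))
    } else {
      out$accuracy_pct <- NA_real_
    }
    out$n_correct <- sum(correct)
  }
  out
}

#' Plot a grade batch
#'
#' Scatter of the two grading indexes with the grade-band boundaries drawn
#' as reference lines, points coloured by assigned grade. The RLDS axis
#' decides the grade whenever the two indexes disagree, so vertical bands
#' are the operative ones.
#'
#' @param object A `grade_batch`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot grade_batch
#' @export
autoplot.grade_batch <- function(object, ...) {
  graded <- tibble::as_tibble(object)
  graded <- graded[!is.na(graded$grade) & graded$grade != "broken", ]
  crit <- attr(object, "config")$criteria
  rlds_cuts <- unique(unlist(crit$rlds))
  rlds_cuts <- rlds_cuts[is.finite(rlds_cuts) & rlds_cuts > 0]
  rdhp_cuts <- unique(unlist(crit$rdhp))
  rdhp_cuts <- rdhp_cuts[is.finite(rdhp_cuts) & rdhp_cuts > 0]
  ggplot2::ggplot(graded, ggplot2::aes(x = .data$RLDS, y = .data$RDHP,
                                       colour = .data$grade)) +
    ggplot2::geom_vline(xintercept = rlds_cuts, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_hline(yintercept = rdhp_cuts, linetype = "dotted",
                        colour = "grey80") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(
      x = "RLDS (stalk length / diameter)",
      y = "RDHP (cap diameter / height)",
      colour = "grade",
      title = "Grading indexes and assigned grades",
      subtitle = "dashed: RLDS band bounds (decisive); dotted: RDHP band bounds"
    ) +
    ggplot2::theme_minimal()
}

#' Tidy a blow trajectory
#'
#' `tidy()` lays the computed quantities out one row per term with units;
#' `glance()` gives the one-row wide form.
#'
#' @param x A `blow_trajectory` from [blow_trajectory()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy blow_trajectory
#' @export
tidy.blow_trajectory <- function(x, ...) {
  tibble::tibble(
    term = c("S_tube", "F", "Vy1", "a", "Vy2", "dt1", "X"),
    value = c(x$S_tube, x$F, x$Vy1, x$a, x$Vy2, x$dt1, x$X),
    unit = c("m^2", "N", "m/s", "m/s^2", "m/s", "s", "m")
  )
}

#' @rdname tidy.blow_trajectory
#' @method glance blow_trajectory
#' @export
glance.blow_trajectory <- function(x, ...) {
  tibble::tibble(
    mode = x$mode, S_tube = x$S_tube, F = x$F,
    displaceable = x$displaceable, Vy1 = x$Vy1, a = x$a, Vy2 = x$Vy2,
    dt1 = x$dt1, X = x$X, stalled = x$stalled
  )
}

#' Plot a blow trajectory's displacement against mass
#'
#' Shows how the downstream displacement grows for heavier specimens: the
#' fixed impulse gives a heavy mushroom less cross-belt speed, so it takes
#' longer to reach the edge and the belt carries it farther. The evaluated
#' specimen is marked.
#'
#' @param object A `blow_trajectory`.
#' @param mass_range Mass axis range, kg.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot blow_trajectory
#' @export
autoplot.blow_trajectory <- function(object, mass_range = NULL, ...) {
  p0 <- object$params
  if (is.null(mass_range)) mass_range <- c(0.5, 2) * p0$m
  masses <- seq(mass_range[1L], mass_range[2L], length.out = 80)
  xs <- vapply(masses, function(m) {
    p <- p0; p$m <- m
    suppressWarnings(blow_trajectory(p, object$mode)$X)
  }, 0)
  df <- tibble::tibble(mass_g = masses * 1e3, X_mm = xs * 1e3)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mass_g, y = .data$X_mm)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(
      data = tibble::tibble(mass_g = p0$m * 1e3, X_mm = object$X * 1e3),
      colour = "red", size = 2
    ) +
    ggplot2::labs(x = "mushroom mass (g)", y = "lateral displacement X (mm)",
                  title = "Air-blow displacement vs specimen mass",
                  subtitle = paste("mode:", object$mode)) +
    ggplot2::theme_minimal()
}

#' Plot a label mask
#'
#' Raster view of a label mask in the standard palette (cap green, stalk
#' red, background near-black).
#'
#' @param object A [label_mask()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot label_mask
#' @export
autoplot.label_mask <- function(object, ...) {
  m <- unclass(object)
  df <- tibble::tibble(
    x = rep(seq_len(ncol(m)), each = nrow(m)),
    y = rep(seq_len(nrow(m)), times = ncol(m)),
    class = factor(as.vector(m), levels = 0:2,
                   labels = c("background", "cap", "stalk"))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$class)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(
      values = c(background = "grey10", cap = "#00cc00", stalk = "#cc0000")
    ) +
    ggplot2::scale_y_reverse() +   # image convention: y increases downward
    ggplot2::coord_fixed() +
    ggplot2::theme_void() +
    ggplot2::labs(fill = NULL)
}

#' @importFrom rlang .data
NULL
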