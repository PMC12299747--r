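#' Pipeline configuration
#'
#' Validated container tying the whole batch flow together: where masks or
#' images come from, which segmentation backend produces masks, the grade
#' criteria, the broken-detection threshold, the air-blow physics, metric
#' flags and the seed. Unknown keys are rejected so a typo in a config file
#' cannot silently change behaviour.
#'
#' @param backend `"file"`, `"reference"`, or a segmenter function (see
#'   [segmenter_backend()]).
#' @param criteria A [grade_criteria()] object.
#' @param min_fraction Broken-detection fragment threshold, see
#'   [detect_broken()].
#' @param tie_tol Cap squareness tolerance, pixels.
#' @param airblow An [air_blow_params()] object.
#' @param include_background Background handling for segmentation metrics.
#' @param seed Integer seed recorded with every report.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(backend = "file", criteria = grade_criteria(),
                            min_fraction = 0.1, tie_tol = 1,
                            airblow = air_blow_params(),
                            include_background = TRUE, seed = 1L) {
  stopifnot(inherits(criteria, "grade_criteria"),
            inherits(airblow, "air_blow_params"),
            min_fraction > 0, min_fraction < 1, tie_tol >= 0)
  structure(
    list(backend = backend, criteria = criteria, min_fraction = min_fraction,
         tie_tol = tie_tol, airblow = airblow,
         include_background = isTRUE(include_background),
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Read or write a pipeline configuration as YAML
#'
#' @param path A YAML file. Recognised top-level keys: `backend`,
#'   `criteria`, `min_fraction`, `tie_tol`, `airblow`, `include_background`,
#'   `seed`; anything else is an error.
#' @return `read_pipeline_config()` returns a [pipeline_config()];
#'   `write_pipeline_config()` returns `path` invisibly.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("backend", "criteria", "min_fraction", "tie_tol", "airblow",
             "include_background", "seed")
  extra <- setdiff(names(raw), known)
  if (length(extra)) {
    stop(sprintf("unknown config keys: %s", paste(extra, collapse = ", ")),
         call. = FALSE)
  }
  args <- list()
  if (!is.null(raw$backend)) args$backend <- raw$backend
  if (!is.null(raw$criteria)) args$criteria <- criteria_from_list(raw$criteria)
  if (!is.null(raw$min_fraction)) args$min_fraction <- raw$min_fraction
  if (!is.null(raw$tie_tol)) args$tie_tol <- raw$tie_tol
  if (!is.null(raw$airblow)) args$airblow <- do.call(air_blow_params, raw$airblow)
  if (!is.null(raw$include_background)) args$include_background <- raw$include_background
  if (!is.null(raw$seed)) args$seed <- raw$seed
  do.call(pipeline_config, args)
}

#' @param config A [pipeline_config()].
#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(list(
    backend = if (is.function(config$backend)) "file" else config$backend,
    criteria = criteria_to_list(config$criteria),
    min_fraction = config$min_fraction,
    tie_tol = config$tie_tol,
    airblow = unclass(config$airblow),
    include_background = config$include_background,
    seed = config$seed
  ), path)
  invisible(path)
}

#' Run the segment-then-grade pipeline over a batch
#'
#' For each manifest row: obtain a label mask (from the `mask` column — a
#' [label_mask()] or PNG path — or by segmenting the `image` column through
#' the configured backend), screen for broken specimens, measure the intact
#' ones, and assign a grade. Broken specimens bypass grading and are
#' reported as grade `"broken"`. Per-image failures are caught, logged in
#' the `error` column and skipped; the batch only fails if every image
#' fails.
#'
#' @param manifest A data frame with an `image_id` column and a `mask`
#'   and/or `image` column (list-columns of objects, or path columns). A
#'   `true_grade` column, if present, is carried through so [glance()] can
#'   report accuracy.
#' @param config A [pipeline_config()].
#' @return A `grade_batch` tibble: one row per image with the measurement
#'   columns of [measure_mushroom()], `rdhp_grade`, `rlds_grade`, `grade`
#'   (`"1"`, `"2"`, `"3"` or `"broken"`), `conflict`, `broken_reason`,
#'   `warnings` and `error`.
#' @examples
#' man <- generate_dataset(6, seed = 7)
#' run_pipeline(man)
#' @export
run_pipeline <- function(manifest, config = pipeline_config()) {
  stopifnot(is.data.frame(manifest), nrow(manifest) > 0,
            inherits(config, "pipeline_config"))
  if (!"image_id" %in% names(manifest)) {
    manifest$image_id <- sprintf("img_%04d", seq_len(nrow(manifest)))
  }
  has_truth <- "true_grade" %in% names(manifest)
  segment <- segmenter_backend(config$backend)

  grade_one <- function(row) {
    mask <- fetch_mask(row, segment)
    br <- detect_broken(mask, config$min_fraction)
    if (br$broken) {
      return(tibble::tibble(grade = "broken", broken_reason = br$reason,
                            conflict = FALSE, warnings = ""))
    }
    warn <- character(0)
    meas <- withCallingHandlers(
      measure_mushroom(mask, tie_tol = config$tie_tol),
      warning = function(w) {
        warn <<- c(warn, conditionMessage(w)); invokeRestart("muffleWarning")
      }
    )
    g <- assign_grade(meas$RDHP, meas$RLDS, config$criteria)
    dplyr::bind_cols(
      meas[setdiff(names(meas), "warnings")],
      tibble::tibble(
        rdhp_grade = g$rdhp_grade, rlds_grade = g$rlds_grade,
        grade = as.character(g$grade), conflict = g$conflict,
        broken_reason = "",
        warnings = paste(unique(c(meas$warnings[nzchar(meas$warnings)], warn)),
                         collapse = "; ")
      )
    )
  }

  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    out <- tryCatch(grade_one(row), error = function(e) {
      tibble::tibble(grade = NA_character_, broken_reason = "",
                     conflict = NA, warnings = "", error = conditionMessage(e))
    })
    out$image_id <- manifest$image_id[i]
    if (has_truth) out$true_grade <- manifest$true_grade[i]
    out
  })
  report <- dplyr::relocate(dplyr::bind_rows(rows), "image_id")
  if (!"error" %in% names(report)) report$error <- NA_character_
  n_failed <- sum(!is.na(report$error))
  if (n_failed == nrow(report)) {
    stop("all images failed; first error: ", report$error[1L], call. = FALSE)
  }
  structure(report,
            class = c("grade_batch", class(tibble::tibble())),
            config = config)
}

fetch_mask <- function(row, segment) {
  get1 <- function(col) {
    v <- row[[col]]
    if (is.null(v)) return(NULL)
    if (is.list(v)) v[[1L]] else v
  }
  mask <- get1("mask")
  if (!is.null(mask)) {
    if (is.character(mask)) return(segment(image = NULL, mask_path = mask))
    return(label_mask(mask))
  }
  img <- get1("image")
  if (is.null(img)) stop("manifest row has neither mask nor image", call. = FALSE)
  if (is.character(img)) img <- png::readPNG(img)
  segment(image = img, mask_path = NULL)
}

#' Write a batch report to disk
#'
#' Emits the machine-readable JSON report, the tabular CSV summary, and —
#' optionally — per-image overlay PNGs showing the colourised mask with the
#' fitted cap rectangle outline, named by assigned grade.
#'
#' @param report A `grade_batch` from [run_pipeline()].
#' @param dir Output directory (created if missing).
#' @param overlays Also write overlay PNGs; requires the masks, so pass the
#'   originating `manifest`.
#' @param manifest The manifest used to produce `report` (only needed for
#'   overlays).
#' @return The directory path, invisibly.
#' @export
write_report <- function(report, dir, overlays = FALSE, manifest = NULL) {
  stopifnot(inherits(report, "grade_batch"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as.data.frame(report), file.path(dir, "report.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(summary = as.list(generics::glance(report)),
         images = report),
    file.path(dir, "report.json"),
    dataframe = "rows", auto_unbox = TRUE, digits = NA, na = "null"
  )
  if (overlays) {
    stopifnot(is.data.frame(manifest))
    segment <- segmenter_backend(attr(report, "config")$backend)
    for (i in seq_len(nrow(report))) {
      j <- match(report$image_id[i], manifest$image_id)
      if (is.na(j) || !is.na(report$error[i])) next
      mask <- fetch_mask(manifest[j, ], segment)
      img <- colorize_mask(mask)
      if (report$grade[i] != "broken") {
        rect <- min_bounding_rect(extract_component_mask(mask, 1L))
        img <- draw_rect_outline(img, rect)
      }
      png::writePNG(img, file.path(dir, sprintf("%s_grade_%s.png",
                                                report$image_id[i],
                                                report$grade[i])))
    }
  }
  invisible(dir)
}

# white outline of a rotated rectangle, drawn by dense point sampling
draw_rect_outline <- function(img, rect) {
  th <- rect$angle_deg * pi / 180
  u <- c(cos(th), sin(th)); v <- c(-sin(th), cos(th))
  hl <- rect$long_side / 2; hs <- rect$short_side / 2
  corners <- rbind(
    c(rect$center_x, rect$center_y) + hl * u + hs * v,
    c(rect$center_x, rect$center_y) - hl * u + hs * v,
    c(rect$center_x, rect$center_y) - hl * u - hs * v,
    c(rect$center_x, rect$center_y) + hl * u - hs * v
  )
  for (e in 1:4) {
    p1 <- corners[e, ]; p2 <- corners[e %% 4 + 1, ]
    t <- seq(0, 1, length.out = ceiling(2 * sqrt(sum((p2 - p1)^2))) + 2)
    xs <- round(p1[1L] + t * (p2[1L] - p1[1L]))
    ys <- round(p1[2L] + t * (p2[2L] - p1[2L]))
    ok <- xs >= 1 & xs <= dim(img)[2L] & ys >= 1 & ys <= dim(img)[1L]
    for (k in 1:3) img[cbind(ys[ok], xs[ok], k)] <- 1
  }
  img
}
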