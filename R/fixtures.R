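#' Specify a synthetic mushroom fixture
#'
#' The synthetic renderer is the package's ground-truthed test bed: it
#' draws a mushroom of exactly known dimensions and pose, so every
#' downstream measurement can be checked against the rendering parameters.
#' The cap is a half-ellipse of width `D1` and height `H` (satisfying the
#' cap-shape assumption D1 >= H); the stalk is a `D2 x L` rectangle
#' attached beneath the cap's midpoint with a 2 px overlap so the two parts
#' never fragment at the seam. The composite is rotated in-plane by
#' `rotation_deg` and centred at `center`. Broken variants and mild
#' blur/brightness noise emulate field imperfections.
#'
#' @param D1,H Cap diameter and height, pixels; `D1 >= H > 0` required.
#' @param L,D2 Stalk length and diameter, pixels.
#' @param rotation_deg In-plane rotation, degrees (angle of the cap's long
#'   axis from the image x-axis, y down).
#' @param center Length-2 `c(x, y)` position on the canvas; default canvas
#'   centre.
#' @param canvas Length-2 `c(width, height)` in pixels.
#' @param broken_mode `"none"`, `"no_cap"`, `"no_stalk"`, or `"fragmented"`
#'   (stalk split in two by a 3 px gap).
#' @param blur_sigma Gaussian blur applied to the rendered image (not the
#'   ground-truth mask); 0 disables.
#' @param brightness_delta Additive brightness shift of the image in
#'   `[-1, 1]`; 0 disables.
#' @param seed Integer recorded with the fixture (rendering itself is
#'   deterministic).
#' @return A `fixture_spec` object.
#' @export
fixture_spec <- function(D1, H, L, D2, rotation_deg = 0, center = canvas / 2,
                         canvas = c(192, 192),
                         broken_mode = c("none", "no_cap", "no_stalk", "fragmented"),
                         blur_sigma = 0, brightness_delta = 0, seed = 0L) {
  broken_mode <- match.arg(broken_mode)
  stopifnot(D1 > 0, H > 0, L > 0, D2 > 0, length(canvas) == 2L, length(center) == 2L)
  if (D1 < H) stop("cap-shape assumption violated: D1 must be >= H", call. = FALSE)
  structure(
    list(D1 = D1, H = H, L = L, D2 = D2, rotation_deg = rotation_deg,
         center = as.numeric(center), canvas = as.integer(canvas),
         broken_mode = broken_mode, blur_sigma = blur_sigma,
         brightness_delta = brightness_delta, seed = as.integer(seed)),
    class = "fixture_spec"
  )
}

#' Render a synthetic mushroom
#'
#' Rasterises a [fixture_spec()] by testing each pixel centre against the
#' cap/stalk geometry in the shape's own frame (so any rotation angle is
#' rendered exactly, without resampling). The ground-truth mask is rendered
#' before noise; the RGB image uses the standard palette (cap green, stalk
#' red) and then receives the requested blur/brightness noise. Rendering is
#' fully deterministic: the same spec always yields identical output.
#'
#' @param spec A [fixture_spec()].
#' @return A list with `image` (RGB array), `mask` ([label_mask()]), and
#'   `record` — a one-row tibble with the spec parameters, `true_RDHP`,
#'   `true_RLDS` and `true_grade` (`"broken"` for broken variants, else
#'   `"1"`/`"2"`/`"3"` from [assign_grade()]).
#' @export
render_mushroom <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  w <- spec$canvas[1L]; h <- spec$canvas[2L]
  th <- spec$rotation_deg * pi / 180
  a <- spec$D1 / 2; b <- spec$H          # cap semi-axes
  hw <- spec$D2 / 2                      # stalk half width
  y_top <- -spec$H; y_bot <- spec$L - 2  # shape-frame vertical extent (y down)
  mid <- (y_top + y_bot) / 2             # shape centre offset from junction

  # clip check: extreme corners of the shape's bounding box, rotated to canvas
  xmax <- max(a, hw)
  corners <- rbind(c(-xmax, y_top - mid), c(xmax, y_top - mid),
                   c(-xmax, y_bot - mid), c(xmax, y_bot - mid))
  cx <- corners[, 1L] * cos(th) - corners[, 2L] * sin(th) + spec$center[1L]
  cy <- corners[, 1L] * sin(th) + corners[, 2L] * cos(th) + spec$center[2L]
  if (any(cx < 1 | cx > w | cy < 1 | cy > h)) {
    stop(structure(
      class = c("mushgrade_out_of_canvas", "error", "condition"),
      list(message = "fixture does not fit the canvas at this pose", call = NULL)
    ))
  }

  # inverse-map every pixel centre into the upright shape frame
  X <- matrix(rep(seq_len(w), each = h), h, w)
  Y <- matrix(rep(seq_len(h), times = w), h, w)
  dx <- X - spec$center[1L]; dy <- Y - spec$center[2L]
  qx <- dx * cos(th) + dy * sin(th)
  qy <- (-dx * sin(th) + dy * cos(th)) + mid   # junction at qy = 0, cap above

  # half-open pixel membership: a region of width D covers on average D
  # pixel centers, so measured sides (center extent + 1 px) are unbiased
  in_cap <- (qx / a)^2 + (qy / b)^2 <= 1 & qy > -b & qy <= 0
  in_stalk <- qx > -hw & qx <= hw & qy > -2 & qy <= y_bot
  if (spec$broken_mode == "no_cap") in_cap[] <- FALSE
  if (spec$broken_mode == "no_stalk") in_stalk[] <- FALSE
  if (spec$broken_mode == "fragmented") {
    gap_at <- (spec$L - 4) / 2          # mid-stalk, clear of the cap seam
    in_stalk[abs(qy - gap_at) <= 1.5] <- FALSE
  }

  lab <- matrix(0L, h, w)
  lab[in_cap] <- 1L
  lab[in_stalk] <- 2L                   # stalk wins the 2 px seam overlap
  mask <- label_mask(lab)

  img <- colorize_mask(mask)
  if (spec$blur_sigma > 0) {
    for (k in 1:3) img[, , k] <- EBImage::gblur(img[, , k], spec$blur_sigma)
  }
  if (spec$brightness_delta != 0) {
    img <- pmin(pmax(img + spec$brightness_delta, 0), 1)
  }

  true_rdhp <- spec$D1 / spec$H
  true_rlds <- spec$L / spec$D2
  true_grade <- if (spec$broken_mode != "none") {
    "broken"
  } else {
    as.character(assign_grade(true_rdhp, true_rlds)$grade)
  }
  record <- tibble::tibble(
    D1 = spec$D1, H = spec$H, L = spec$L, D2 = spec$D2,
    rotation_deg = spec$rotation_deg, broken_mode = spec$broken_mode,
    true_RDHP = true_rdhp, true_RLDS = true_rlds, true_grade = true_grade,
    seed = spec$seed
  )
  list(image = img, mask = mask, record = record)
}

#' Generate a reproducible synthetic dataset
#'
#' Samples `n` fixtures with an (as close as possible to) exact grade mix,
#' mirroring a balanced three-grade dataset. Dimensions are drawn uniformly
#' from `ranges`; the grading-index values are drawn uniformly inside the
#' target grade's band, inset by `band_margin` from each boundary so the
#' intended grade is unambiguous. Because the renderer enforces the cap
#' assumption D1 >= H, grade-3 fixtures (whose nominal RDHP band lies below
#' 1) carry a grade-2 RDHP and reach grade 3 through the RLDS-prevails
#' conflict rule — the same route the criteria define for real specimens.
#'
#' @param n Number of fixtures.
#' @param grade_mix Length-3 vector of grade proportions (normalised).
#' @param ranges Named list of sampling bounds: `H`, `D2` (pixels),
#'   `rotation` (degrees), and `rlds3_hi`, the top of the sampled grade-3
#'   RLDS range (the band itself is unbounded).
#' @param canvas Canvas size in pixels (square).
#' @param band_margin Inset from each band boundary when sampling index
#'   values.
#' @param broken_frac Fraction of fixtures rendered broken (modes cycled);
#'   default 0.
#' @param noise A list with `blur_sigma` and `brightness_delta` applied to
#'   every fixture's image; default none.
#' @param seed Single integer driving all sampling.
#' @param dir If non-`NULL`, images and masks are written there as PNGs and
#'   the manifest gains `image` and `mask` path columns.
#' @return A manifest tibble with one row per fixture: `image_id`, the true
#'   dimensions and pose, `true_RDHP`, `true_RLDS`, `true_grade`, `seed`,
#'   and a `mask` list-column of [label_mask()]s (replaced by file paths
#'   when `dir` is given, with an `image` path column alongside).
#' @examples
#' man <- generate_dataset(9, seed = 1)
#' table(man$true_grade)
#' @export
generate_dataset <- function(n, grade_mix = c(1, 1, 1) / 3,
                             ranges = list(H = c(54, 90), D2 = c(30, 48),
                                           rotation = c(0, 360), rlds3_hi = 3.5),
                             canvas = 384, band_margin = 0.05,
                             broken_frac = 0, noise = NULL, seed = 1L,
                             dir = NULL) {
  stopifnot(n > 0, length(grade_mix) == 3L, all(grade_mix >= 0), sum(grade_mix) > 0)
  crit <- grade_criteria()
  rdhp_bands <- list(`1` = crit$rdhp[["1"]], `2` = crit$rdhp[["2"]],
                     `3` = crit$rdhp[["2"]])   # grade 3: D1 >= H forces a band >= 1
  rlds_bands <- crit$rlds
  rlds_bands[["3"]][2L] <- ranges$rlds3_hi

  # largest-remainder apportionment: counts within 1 of the requested mix
  quota <- n * grade_mix / sum(grade_mix)
  counts <- floor(quota)
  rem <- n - sum(counts)
  if (rem > 0) {
    counts[order(quota - floor(quota), decreasing = TRUE)[seq_len(rem)]] <-
      counts[order(quota - floor(quota), decreasing = TRUE)[seq_len(rem)]] + 1
  }
  grades <- rep(1:3, times = counts)

  n_broken <- round(broken_frac * n)
  broken_modes <- rep("none", n)
  if (n_broken > 0) {
    broken_modes[seq_len(n_broken)] <-
      rep_len(c("no_cap", "no_stalk", "fragmented"), n_broken)
  }

  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  perm <- sample.int(n)
  grades <- grades[perm]

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    g <- as.character(grades[i])
    rdhp <- runif(1, rdhp_bands[[g]][1L] + band_margin, rdhp_bands[[g]][2L] - band_margin)
    rlds <- runif(1, rlds_bands[[g]][1L] + band_margin,
                  rlds_bands[[g]][2L] - if (g == "3") 0 else band_margin)
    if (g == "1") rlds <- max(rlds, 0.5)   # keep the stalk long enough to raster
    H <- runif(1, ranges$H[1L], ranges$H[2L])
    D2 <- runif(1, ranges$D2[1L], ranges$D2[2L])
    rot <- runif(1, ranges$rotation[1L], ranges$rotation[2L])
    spec <- fixture_spec(
      D1 = rdhp * H, H = H, L = rlds * D2, D2 = D2, rotation_deg = rot,
      canvas = c(canvas, canvas), broken_mode = broken_modes[i],
      blur_sigma = if (is.null(noise)) 0 else noise$blur_sigma %||% 0,
      brightness_delta = if (is.null(noise)) 0 else noise$brightness_delta %||% 0,
      seed = seed
    )
    fx <- render_mushroom(spec)
    rows[[i]] <- dplyr::mutate(
      fx$record,
      image_id = sprintf("fx_%04d", i), .before = 1
    )
    rows[[i]]$mask <- list(fx$mask)
    if (!is.null(dir)) rows[[i]]$.image <- list(fx$image)
  }
  manifest <- dplyr::bind_rows(rows)

  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    manifest$image <- file.path(dir, paste0(manifest$image_id, ".png"))
    mask_paths <- file.path(dir, paste0(manifest$image_id, "_mask.png"))
    for (i in seq_len(n)) {
      png::writePNG(manifest$.image[[i]], manifest$image[i])
      write_label_mask(manifest$mask[[i]], mask_paths[i])
    }
    manifest$mask <- mask_paths
    manifest$.image <- NULL
    utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  }
  manifest
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_set <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
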