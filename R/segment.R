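#' Colour rules for the reference segmenter
#'
#' The reference segmenter classifies pixels by colour distance to a
#' per-class reference colour. The default palette is the one the whole
#' package uses to visualise masks: cap green, stalk red, background black.
#' Rules must not overlap: each class's reference colour must be farther
#' than `2 * tol` from every other's.
#'
#' @param cap,stalk,background Reference RGB colours in `[0, 1]`.
#' @param tol Maximum Euclidean RGB distance for a pixel to match a class.
#' @return A `color_rules` object.
#' @export
color_rules <- function(cap = c(0, 1, 0), stalk = c(1, 0, 0),
                        background = c(0, 0, 0), tol = 0.45) {
  refs <- rbind(background = background, cap = cap, stalk = stalk)
  stopifnot(ncol(refs) == 3, all(refs >= 0 & refs <= 1), tol > 0)
  d <- as.matrix(stats::dist(refs))
  if (any(d[upper.tri(d)] <= 2 * tol)) {
    stop("color rules overlap: reference colors closer than 2 * tol", call. = FALSE)
  }
  structure(list(refs = refs, tol = tol), class = "color_rules")
}

#' Segment an RGB image into a label mask by colour rules
#'
#' A deterministic stand-in for a trained instance-segmentation network,
#' sufficient for images rendered (or recoloured) with distinguishable cap
#' and stalk colours — in particular the synthetic fixtures. Each pixel is
#' assigned the class whose reference colour is nearest within `tol`
#' (otherwise background), then each object class is cleaned by one
#' iteration of 3x3 morphological closing to remove speckle. Any external
#' segmenter can replace this stage: the downstream pipeline only consumes
#' the [label_mask()] contract.
#'
#' @param image An `h x w x 3` RGB array in `[0, 1]`.
#' @param rules A [color_rules()] object.
#' @param clean Apply the 3x3 closing (default `TRUE`); disable for exact
#'   round-trip checks.
#' @return A [label_mask()] of the same dimensions as `image`. Raises an
#'   empty-output warning (class `mushgrade_empty_class_warning`) for each
#'   object class that matches zero pixels.
#' @export
reference_segment <- function(image, rules = color_rules(), clean = TRUE) {
  stopifnot(length(dim(image)) == 3L, dim(image)[3L] == 3L)
  h <- dim(image)[1L]; w <- dim(image)[2L]
  px <- matrix(image, h * w, 3L)
  d2 <- sapply(seq_len(nrow(rules$refs)), function(i) {
    colSums((t(px) - rules$refs[i, ])^2)
  })
  cls <- max.col(-d2, ties.method = "first") - 1L   # 0 bg, 1 cap, 2 stalk
  cls[sqrt(d2[cbind(seq_along(cls), cls + 1L)]) > rules$tol] <- 0L
  lab <- matrix(cls, h, w)
  if (clean) {
    kern <- matrix(1L, 3L, 3L)
    for (k in 1:2) {
      closed <- EBImage::closing(lab == k, kern)
      lab[lab == k] <- 0L
      lab[closed > 0 & lab == 0L] <- k
    }
  }
  for (k in 1:2) {
    if (!any(lab == k)) {
      warning(structure(
        class = c("mushgrade_empty_class_warning", "warning", "condition"),
        list(message = sprintf("reference_segment: class %d matched no pixels", k),
             call = NULL)
      ))
    }
  }
  label_mask(lab)
}

#' Render a label mask as an RGB visualisation
#'
#' Cap pixels are drawn green, stalk pixels red, background black — the
#' standard mask colouring. On noiseless input the operation is exactly
#' inverted by [reference_segment()].
#'
#' @param mask A [label_mask()].
#' @return An `h x w x 3` RGB array in `[0, 1]`.
#' @export
colorize_mask <- function(mask) {
  mask <- label_mask(mask)
  m <- unmask(mask)
  img <- array(0, c(nrow(m), ncol(m), 3L))
  img[, , 1][m == 2L] <- 1   # stalk red
  img[, , 2][m == 1L] <- 1   # cap green
  img
}

#' Build a segmenter backend
#'
#' A segmenter is any function `f(image, mask_path)` returning a
#' [label_mask()]; [run_pipeline()] accepts one directly. Two backends are
#' bundled: `"reference"` wraps [reference_segment()] and `"file"` loads a
#' pre-computed mask from the PNG label-map path carried by the manifest
#' (the route by which an external trained network plugs in).
#'
#' @param backend `"reference"` or `"file"`, or a function used as-is.
#' @param rules [color_rules()] for the reference backend.
#' @return A segmenter function.
#' @export
segmenter_backend <- function(backend = c("file", "reference"), rules = color_rules()) {
  if (is.function(backend)) return(backend)
  backend <- match.arg(backend)
  switch(backend,
    reference = function(image, mask_path = NULL) reference_segment(image, rules),
    file = function(image = NULL, mask_path) read_label_mask(mask_path)
  )
}
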