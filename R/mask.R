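#' Label masks
#'
#' A label mask is the contract between the segmentation stage and the
#' morphometry stage: an integer matrix with one row per image row (y,
#' increasing downward) and one column per image column (x), holding the
#' per-pixel class: `0` background, `1` cap, `2` stalk.
#'
#' @param x An integer (or coercible) matrix of class labels in `{0, 1, 2}`.
#' @return An integer matrix of class `label_mask`.
#' @examples
#' m <- matrix(0L, 10, 10)
#' m[2:5, 3:8] <- 1L
#' label_mask(m)
#' @export
label_mask <- function(x) {
  if (!is.matrix(x)) stop("`x` must be a matrix", call. = FALSE)
  if (nrow(x) < 1L || ncol(x) < 1L) {
    stop("label mask must have positive dimensions", call. = FALSE)
  }
  storage.mode(x) <- "integer"
  if (anyNA(x) || !all(x %in% 0:2)) {
    stop("label mask values must all be in {0, 1, 2}", call. = FALSE)
  }
  structure(x, class = c("label_mask", "matrix", "array"))
}

#' @export
print.label_mask <- function(x, ...) {
  tab <- tabulate(as.integer(x) + 1L, nbins = 3L)
  cat(sprintf(
    "<label_mask> %d x %d px (background %d, cap %d, stalk %d)\n",
    ncol(x), nrow(x), tab[1L], tab[2L], tab[3L]
  ))
  invisible(x)
}

# strip the class so EBImage and arithmetic see a plain matrix
unmask <- function(mask) {
  m <- unclass(mask)
  storage.mode(m) <- "integer"
  m
}

#' Read or write a label mask as an 8-bit PNG label map
#'
#' Masks are exchanged on disk as single-channel 8-bit PNGs whose raw pixel
#' values are the class labels themselves (0 background, 1 cap, 2 stalk).
#' The encoding is lossless: a written mask reads back identically.
#'
#' @param path Path to a PNG file.
#' @return `read_label_mask()` returns a [label_mask()]; `write_label_mask()`
#'   returns `path` invisibly.
#' @export
read_label_mask <- function(path) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 3L) px <- px[, , 1L]  # tolerate grey written as RGB
  label_mask(matrix(as.integer(round(px * 255)), nrow(px), ncol(px)))
}

#' @param mask A [label_mask()].
#' @rdname read_label_mask
#' @export
write_label_mask <- function(mask, path) {
  mask <- label_mask(mask)
  png::writePNG(unmask(mask) / 255, path)
  invisible(path)
}

#' Extract the largest connected component of one class
#'
#' Selects the pixels of a single class and keeps only the largest
#' 8-connected component, suppressing speckle from imperfect segmentation.
#' The total class pixel count and the number of components are attached as
#' attributes `n_pixels` and `n_components` (the latter feeds broken-specimen
#' detection).
#'
#' @param mask A [label_mask()].
#' @param class_id Class to extract: `1` (cap) or `2` (stalk).
#' @return A binary `label_mask` (values 0/1) of the largest component, with
#'   attributes `n_pixels` and `n_components`.
#' @export
extract_component_mask <- function(mask, class_id) {
  mask <- label_mask(mask)
  stopifnot(length(class_id) == 1L, class_id %in% 1:2)
  bin <- unmask(mask) == class_id
  n_pixels <- sum(bin)
  if (n_pixels == 0L) {
    stop(empty_class_error(class_id))
  }
  lab <- EBImage::bwlabel(bin)
  sizes <- tabulate(as.integer(lab))
  keep <- which.max(sizes)
  out <- label_mask(matrix(as.integer(lab == keep), nrow(mask), ncol(mask)))
  attr(out, "n_pixels") <- n_pixels
  attr(out, "n_components") <- length(sizes)
  out
}

# per-class component areas (for broken detection); 0-length when class absent
component_areas <- function(mask, class_id) {
  bin <- unmask(mask) == class_id
  if (!any(bin)) return(integer(0))
  tabulate(as.integer(EBImage::bwlabel(bin)))
}

empty_class_error <- function(class_id) {
  structure(
    class = c("mushgrade_empty_class", "error", "condition"),
    list(
      message = sprintf("no pixels carry class %d", class_id),
      call = NULL
    )
  )
}
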