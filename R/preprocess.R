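#' Convert an RGB image to its monochrome (intensity) channel
#'
#' The intensity of a pixel is the arithmetic mean of its R, G and B values.
#' The same convention is used for segmentation and for the intensity/texture
#' features, so there is a single greyscale definition across the package.
#'
#' @param img an `rgb_image`, or a bare H x W x 3 array.
#' @return an H x W numeric matrix with values in `[0, 255]`.
#' @export
to_monochrome <- function(img) {
  px <- if (inherits(img, c("rgb_image", "flour_roi", "pyramid_region"))) img$pixels else img
  g <- (px[, , 1, drop = FALSE] + px[, , 2, drop = FALSE] + px[, , 3, drop = FALSE]) / 3
  matrix(g, dim(px)[1], dim(px)[2])
}

#' Otsu's threshold of a grey image
#'
#' Grey values are rounded into 256 bins and the threshold `t` maximising the
#' between-class variance of the (<= t) / (> t) split is returned. Ties are
#' broken towards the smallest `t` so the result is deterministic.
#'
#' @param grey numeric matrix of grey values in `[0, 255]`.
#' @param sample_id used in the error message for degenerate images.
#' @return integer threshold in `[0, 255]`.
#' @export
otsu_threshold <- function(grey, sample_id = "image") {
  g <- pmin(pmax(as.integer(round(grey)), 0L), 255L)
  counts <- tabulate(g + 1L, nbins = 256L)
  if (sum(counts > 0L) < 2L)
    stop(sprintf("degenerate segmentation: '%s' has a single grey level", sample_id),
         call. = FALSE)
  p <- counts / sum(counts)
  omega <- cumsum(p)                 # P(class <= t)
  mu <- cumsum(p * (0:255))          # partial mean
  mu_t <- mu[256]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  which.max(sigma_b) - 1L            # which.max takes the first (smallest) maximiser
}

#' Fill interior holes of a binary mask
#'
#' Background pixels that cannot reach the image border through a
#' 4-connected background path are holes and become foreground. Foreground
#' pixels are never removed, so the operation is idempotent.
#'
#' @param mask logical matrix, `TRUE` = foreground.
#' @return logical matrix of the same shape.
#' @export
fill_holes <- function(mask) {
  if (!is.matrix(mask) || !is.logical(mask)) stop("mask must be a logical matrix", call. = FALSE)
  if (!any(mask)) stop("mask has no foreground pixels", call. = FALSE)
  h <- nrow(mask); w <- ncol(mask)
  bg <- !mask
  reach <- matrix(FALSE, h, w)
  reach[1, ] <- bg[1, ]; reach[h, ] <- bg[h, ]
  reach[, 1] <- reach[, 1] | bg[, 1]; reach[, w] <- reach[, w] | bg[, w]
  repeat {   # propagate border-connected background one 4-neighbour step per pass
    grown <- reach
    grown[-1, ] <- grown[-1, ] | reach[-h, ]
    grown[-h, ] <- grown[-h, ] | reach[-1, ]
    grown[, -1] <- grown[, -1] | reach[, -w]
    grown[, -w] <- grown[, -w] | reach[, -1]
    grown <- grown & bg
    if (identical(grown, reach)) break
    reach <- grown
  }
  !reach
}

#' Center of mass of a binary mask
#'
#' @param mask logical matrix with at least one foreground pixel.
#' @return numeric `(row, col)` pair: the mean foreground coordinate.
#' @export
center_of_mass <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("mask has no foreground pixels", call. = FALSE)
  c(row = mean(idx[, 1]), col = mean(idx[, 2]))
}

#' Grow the largest all-foreground square around a center
#'
#' Starting from the pixel nearest `center`, the square side is grown one
#' pixel ring at a time (side + 2, re-centred, clamped into the image) while
#' every covered pixel is foreground. The procedure is deterministic.
#'
#' @param mask logical matrix.
#' @param center numeric `(row, col)`; must land on a foreground pixel after
#'   rounding.
#' @return list with `row`, `col` (top-left, 1-based) and `side`.
#' @export
grow_square <- function(mask, center) {
  h <- nrow(mask); w <- ncol(mask)
  r <- as.integer(round(center[1])); cc <- as.integer(round(center[2]))
  if (r < 1L || r > h || cc < 1L || cc > w || !mask[r, cc])
    stop("square growth center does not lie on foreground", call. = FALSE)
  # summed-area table for O(1) all-foreground checks
  m2 <- apply(mask * 1L, 2, cumsum)
  if (h == 1L) m2 <- matrix(m2, nrow = 1L)
  sat <- rbind(0L, cbind(0L, t(apply(m2, 1, cumsum))))
  boxsum <- function(r0, r1, c0, c1)
    sat[r1 + 1L, c1 + 1L] - sat[r0, c1 + 1L] - sat[r1 + 1L, c0] + sat[r0, c0]
  place <- function(s) {
    r0 <- min(max(r - (s - 1L) %/% 2L, 1L), h - s + 1L)
    c0 <- min(max(cc - (s - 1L) %/% 2L, 1L), w - s + 1L)
    c(r0, c0)
  }
  best <- c(r, cc, 1L)
  s <- 1L
  while (s + 1L <= min(h, w)) {
    s2 <- s + 1L
    p <- place(s2)
    if (boxsum(p[1], p[1] + s2 - 1L, p[2], p[2] + s2 - 1L) == s2 * s2) {
      best <- c(p, s2); s <- s2
    } else break
  }
  list(row = best[1], col = best[2], side = best[3])
}

#' Extract the square region of interest from a flour image
#'
#' Pipeline: monochrome conversion, Otsu thresholding, foreground mask
#' (pixels brighter than the threshold by default -- flour is brighter than
#' the scanner background), hole filling, center of mass, square growth, and
#' a crop of the original RGB pixels.
#'
#' @param img an `rgb_image`.
#' @param invert_foreground set `TRUE` when the object is darker than the
#'   background.
#' @return an object of class `flour_roi`: `pixels` (S x S x 3), `origin`
#'   (top-left `(row, col)` in parent coordinates), `side`, `sample_id`,
#'   plus the parent's `cultivar_id` and `label`.
#' @export
extract_roi <- function(img, invert_foreground = FALSE) {
  stopifnot(inherits(img, "rgb_image"))
  grey <- to_monochrome(img)
  t <- otsu_threshold(grey, img$sample_id)
  # Otsu's low class is (<= t), so the inverted polarity keeps <= t
  mask <- if (invert_foreground) grey <= t else grey > t
  if (!any(mask))
    stop(sprintf("segmentation of '%s' produced an empty foreground", img$sample_id),
         call. = FALSE)
  mask <- fill_holes(mask)
  cm <- center_of_mass(mask)
  box <- grow_square(mask, cm)
  if (box$side < 8L)
    stop(sprintf("ROI of '%s' is %dx%d; at least 8x8 is required",
                 img$sample_id, box$side, box$side), call. = FALSE)
  rows <- box$row:(box$row + box$side - 1L)
  cols <- box$col:(box$col + box$side - 1L)
  structure(
    list(pixels = img$pixels[rows, cols, , drop = FALSE],
         origin = c(row = box$row, col = box$col), side = box$side,
         sample_id = img$sample_id, cultivar_id = img$cultivar_id,
         label = img$label),
    class = "flour_roi")
}

#' @export
print.flour_roi <- function(x, ...) {
  cat(sprintf("<flour_roi> %s  side=%d origin=(%d,%d)\n",
              x$sample_id, x$side, x$origin[1], x$origin[2]))
  invisible(x)
}
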