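#' Partition a ROI into the 3-level spatial pyramid
#'
#' Level 0 is the ROI itself; Level 1 splits it into four quadrants; Level 2
#' splits each quadrant again, giving 1 + 4 + 16 = 21 regions. Odd side
#' lengths use a floor split: the first tile gets `floor(S/2)` rows/columns
#' and the second the remainder. Tiles are ordered row-major (top-left,
#' top-right, bottom-left, bottom-right); Level-2 tiles are grouped by their
#' Level-1 parent, so tile `p * 4 + q` of Level 2 is quadrant `q` of Level-1
#' tile `p`.
#'
#' @param roi a `flour_roi` (or any object with S x S x 3 `pixels`); side
#'   must be at least 8.
#' @return an object of class `pyramid_set`: a list with `regions` (21
#'   `pyramid_region` objects in deterministic order: level ascending, then
#'   tile index) plus the ROI provenance.
#' @export
pyramid_partition <- function(roi) {
  px <- roi$pixels
  d <- dim(px)
  if (is.null(d) || length(d) != 3L) stop("roi must carry H x W x 3 pixels", call. = FALSE)
  if (d[1] < 8L || d[2] < 8L)
    stop(sprintf("ROI side %dx%d is below the 8-pixel minimum", d[1], d[2]), call. = FALSE)
  sid <- roi$sample_id %||% "sample"

  region <- function(rows, cols, level, tile)
    structure(list(pixels = px[rows, cols, , drop = FALSE], level = level,
                   tile_index = tile, sample_id = sid),
              class = "pyramid_region")
  halves <- function(n) {
    k <- n %/% 2L
    list(seq_len(k), (k + 1L):n)
  }

  rh <- halves(d[1]); ch <- halves(d[2])
  regions <- vector("list", 21L)
  regions[[1]] <- region(seq_len(d[1]), seq_len(d[2]), 0L, 0L)
  k <- 2L
  l1 <- list()
  for (i in 1:2) for (j in 1:2) {   # row-major level-1 quadrants
    tile <- (i - 1L) * 2L + (j - 1L)
    regions[[k]] <- region(rh[[i]], ch[[j]], 1L, tile)
    l1[[tile + 1L]] <- list(rows = rh[[i]], cols = ch[[j]])
    k <- k + 1L
  }
  for (p in 0:3) {
    pr <- l1[[p + 1L]]
    rr <- halves(length(pr$rows)); cr <- halves(length(pr$cols))
    for (i in 1:2) for (j in 1:2) {
      q <- (i - 1L) * 2L + (j - 1L)
      regions[[k]] <- region(pr$rows[rr[[i]]], pr$cols[cr[[j]]], 2L, p * 4L + q)
      k <- k + 1L
    }
  }
  structure(list(regions = regions, sample_id = sid,
                 cultivar_id = roi$cultivar_id %||% NA_character_,
                 label = roi$label %||% NA_character_),
            class = "pyramid_set")
}

#' @export
print.pyramid_set <- function(x, ...) {
  cat(sprintf("<pyramid_set> %s  %d regions (levels %s)\n", x$sample_id,
              length(x$regions),
              paste(sort(unique(vapply(x$regions, `[[`, 0L, "level"))), collapse = ",")))
  invisible(x)
}

#' Concatenate 21 per-region feature vectors into the flat SPP descriptor
#'
#' The concatenated spatial-pyramid baseline describes a sample by one long
#' vector: 21 regions x 55 features = 1155 values, in pyramid order. Names
#' are suffixed `_L<level>_T<tile>`.
#'
#' @param vectors list of 21 numeric feature vectors of length 55, in
#'   `pyramid_set` order, or a `pyramid_features` table (see
#'   [pyramid_feature_rows()]).
#' @return named numeric vector of length 1155.
#' @export
spp_concat <- function(vectors) {
  if (is.data.frame(vectors)) {
    meta <- vectors[c("level", "tile_index")]
    ord <- order(meta$level, meta$tile_index)
    vecs <- lapply(ord, function(i) {
      v <- as.numeric(vectors[i, feature_names()])
      names(v) <- feature_names()
      v
    })
    lv <- meta$level[ord]; ti <- meta$tile_index[ord]
  } else {
    vecs <- vectors
    lv <- rep(0:2, c(1L, 4L, 16L))
    ti <- c(0L, 0:3, 0:15)
  }
  if (length(vecs) != 21L)
    stop("spp_concat needs exactly 21 feature vectors, got ", length(vecs), call. = FALSE)
  if (any(vapply(vecs, length, 0L) != 55L))
    stop("every feature vector must have length 55", call. = FALSE)
  out <- unlist(vecs, use.names = FALSE)
  names(out) <- unlist(lapply(seq_along(vecs), function(i)
    paste0(names(vecs[[i]]) %||% feature_names(), "_L", lv[i], "_T", ti[i])))
  out
}

#' Dump pyramid tiles to PNG files for inspection
#'
#' Files are named `{sample_id}_L{level}_T{tile}.png`.
#'
#' @param pyr a `pyramid_set`.
#' @param dir output directory (created if missing).
#' @return character vector of written paths, invisibly.
#' @export
dump_pyramid <- function(pyr, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(pyr$regions, function(rg) {
    p <- file.path(dir, sprintf("%s_L%d_T%d.png", pyr$sample_id, rg$level, rg$tile_index))
    png::writePNG(pmin(pmax(rg$pixels / 255, 0), 1), target = p)
    p
  }, character(1))
  invisible(paths)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
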