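#' Names of the 55 region descriptors, in canonical order
#'
#' Thirty colour features (HSV then CIE L*a*b* pixel moments and histogram
#' statistics), six intensity features, ten rotation-invariant uniform LBP
#' bins, five grey-level co-occurrence statistics and four FFT power-spectrum
#' statistics.
#'
#' @return character vector of length 55.
#' @export
feature_names <- function() {
  c("meanH", "StdH", "meanS", "stdS", "MeanV", "stdV",
    "stdHistH", "kurtHistH", "skewHistH",
    "stdHistS", "kurtHistS", "skewHistS",
    "stdHistV", "kurtHistV", "skewHistV",
    "meanL", "stdL", "meanA", "stdA", "meanB", "stdB",
    "stdHistL", "kurtHistL", "skewHistL",
    "stdHistA", "kurtHistA", "skewHistA",
    "stdHistB", "kurtHistB", "skewHistB",
    "meanInten", "StdInten", "entropyInten",
    "stdHistInten", "kurtHistInten", "skewHistInten",
    paste0("lbp_", 0:9),
    "entCoMatrix", "ineCoMatrix", "eneCoMatrix", "corCoMatrix", "homCoMatrix",
    "eneFFT", "entFFT", "ineFFT", "homFFT")
}

# --- shared helpers ---------------------------------------------------------

region_pixels <- function(region) {
  px <- if (inherits(region, c("pyramid_region", "flour_roi", "rgb_image"))) region$pixels else region
  if (is.null(dim(px)) || length(dim(px)) != 3L || dim(px)[3] != 3L)
    stop("region must carry H x W x 3 pixels", call. = FALSE)
  px
}

# population standard deviation: the descriptor set treats each region as a
# complete pixel population, not a sample from one
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

# std / excess kurtosis / skewness of a vector treated as a data series
# (moment-based; all three are 0 for a constant series)
series_moments <- function(x) {
  m <- mean(x); d <- x - m
  v <- mean(d * d)
  if (v == 0) return(c(std = 0, kurt = 0, skew = 0))
  c(std = sqrt(v), kurt = mean(d^4) / v^2 - 3, skew = mean(d^3) / v^1.5)
}

# 256-bin histogram counts of values over a fixed channel range [lo, hi)
chan_hist <- function(x, lo, hi) {
  b <- floor((x - lo) / (hi - lo) * 256)
  b[b > 255] <- 255L; b[b < 0] <- 0L
  tabulate(b + 1L, nbins = 256L)
}

region_intensity <- function(region) to_monochrome(region_pixels(region))

# --- colour -----------------------------------------------------------------

#' Colour features of a region (30 values)
#'
#' RGB pixels are converted to HSV (H, S, V each scaled to `[0, 1]`) and to
#' CIE L*a*b* (sRGB input, D65 white, 2 degree observer; L* in `[0, 100]`,
#' a*/b* on their native signed scale). For each of the six channels the
#' pixel mean and pixel standard deviation are computed, plus the standard
#' deviation, excess kurtosis and skewness of the channel's 256-bin histogram
#' counts (the bin-count sequence treated as data, which is distinct from the
#' pixel-level moments). Histogram ranges are fixed per channel: `[0, 1]` for
#' H/S/V, `[0, 100]` for L*, `[-128, 128]` for a*/b*.
#'
#' @param region a `pyramid_region`, `flour_roi`, `rgb_image` or raw array.
#' @return named numeric vector of length 30.
#' @export
color_features <- function(region) {
  px <- region_pixels(region)
  n <- dim(px)[1] * dim(px)[2]
  if (n < 4L) stop("colour features need at least 4 pixels", call. = FALSE)
  r <- as.vector(px[, , 1]); g <- as.vector(px[, , 2]); b <- as.vector(px[, , 3])
  hsv <- grDevices::rgb2hsv(rbind(r, g, b), maxColorValue = 255)
  lab <- grDevices::convertColor(cbind(r, g, b) / 255, from = "sRGB", to = "Lab")
  chans <- list(H = hsv[1, ], S = hsv[2, ], V = hsv[3, ],
                L = lab[, 1], A = lab[, 2], B = lab[, 3])
  rng <- list(H = c(0, 1), S = c(0, 1), V = c(0, 1),
              L = c(0, 100), A = c(-128, 128), B = c(-128, 128))
  out <- numeric(0)
  for (grp in list(c("H", "S", "V"), c("L", "A", "B"))) {
    for (ch in grp) {
      x <- chans[[ch]]
      out <- c(out, mean(x), pop_sd(x))
    }
    for (ch in grp) {
      hm <- series_moments(chan_hist(chans[[ch]], rng[[ch]][1], rng[[ch]][2]))
      out <- c(out, hm[["std"]], hm[["kurt"]], hm[["skew"]])
    }
  }
  names(out) <- feature_names()[1:30]
  out
}

# --- intensity --------------------------------------------------------------

#' Intensity features of a region (6 values)
#'
#' Intensity is the per-pixel mean of R, G and B. Features: pixel mean, pixel
#' standard deviation, Shannon entropy (bits) of the normalised 256-bin
#' intensity histogram, and the standard deviation / excess kurtosis /
#' skewness of the histogram bin-count sequence.
#'
#' @inheritParams color_features
#' @return named numeric vector of length 6.
#' @export
intensity_features <- function(region) {
  I <- region_intensity(region)
  if (length(I) < 4L) stop("intensity features need at least 4 pixels", call. = FALSE)
  counts <- tabulate(pmin(pmax(as.integer(round(I)), 0L), 255L) + 1L, nbins = 256L)
  p <- counts / sum(counts)
  p <- p[p > 0]
  hm <- series_moments(counts)
  out <- c(mean(I), pop_sd(I), -sum(p * log2(p)), hm[["std"]], hm[["kurt"]], hm[["skew"]])
  names(out) <- feature_names()[31:36]
  out
}

# --- LBP --------------------------------------------------------------------

#' Rotation-invariant uniform LBP histogram of a region (10 values)
#'
#' Eight-neighbour, radius-1 local binary patterns on the intensity image,
#' using the discrete 8-connected neighbourhood. A neighbour scores 1 when it
#' is strictly brighter than the centre (so a flat region codes as the
#' all-zeros pattern). Patterns with at most two 0/1 transitions around the
#' circle are "uniform" and binned by their number of ones (bins 0..8); all
#' other patterns share bin 9. The histogram is normalised to sum to 1 over
#' the interior pixels.
#'
#' @inheritParams color_features
#' @return named numeric vector of length 10 (`lbp_0` .. `lbp_9`).
#' @export
lbp_features <- function(region) {
  I <- region_intensity(region)
  h <- nrow(I); w <- ncol(I)
  if (h < 3L || w < 3L) stop("LBP needs a region of at least 3 x 3 pixels", call. = FALSE)
  ctr <- I[2:(h - 1), 2:(w - 1), drop = FALSE]
  # neighbours in circular order starting east, counter-clockwise
  sh <- list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1), c(0, -1), c(1, -1), c(1, 0), c(1, 1))
  bits <- lapply(sh, function(s)
    I[2:(h - 1) + s[1], 2:(w - 1) + s[2], drop = FALSE] > ctr)
  ones <- Reduce(`+`, bits)
  trans <- Reduce(`+`, lapply(1:8, function(k) bits[[k]] != bits[[k %% 8 + 1]]))
  code <- ifelse(trans <= 2, ones, 9L)
  cnt <- tabulate(as.vector(code) + 1L, nbins = 10L)
  out <- cnt / sum(cnt)
  names(out) <- paste0("lbp_", 0:9)
  out
}

# --- GLCM -------------------------------------------------------------------

glcm_matrix_sparse <- function(I) {
  g <- pmin(pmax(as.integer(round(I)), 0L), 255L)
  dim(g) <- dim(I)
  w <- ncol(g)
  if (w < 2L) stop("GLCM needs at least 2 columns", call. = FALSE)
  a <- g[, -w, drop = FALSE]; b <- g[, -1, drop = FALSE]
  cnt <- tabulate(a * 256L + b + 1L, nbins = 65536L) +
         tabulate(b * 256L + a + 1L, nbins = 65536L)   # symmetric accumulation
  nz <- which(cnt > 0L)
  list(i = (nz - 1L) %/% 256L, j = (nz - 1L) %% 256L, p = cnt[nz] / sum(cnt[nz]))
}

#' Grey-level co-occurrence matrix of a region
#'
#' Offset distance 1 at angle 0 (horizontal neighbours), 256 grey levels (no
#' re-quantisation), symmetric accumulation, normalised to sum to 1.
#'
#' @inheritParams color_features
#' @return a 256 x 256 matrix summing to 1.
#' @export
glcm_matrix <- function(region) {
  sp <- glcm_matrix_sparse(region_intensity(region))
  m <- matrix(0, 256, 256)
  m[cbind(sp$i + 1L, sp$j + 1L)] <- sp$p
  m
}

#' Co-occurrence texture statistics of a region (5 values)
#'
#' From the symmetric, normalised 256-level GLCM at offset (0, +1):
#' entropy `-sum p log2 p`, inertia (contrast) `sum (i-j)^2 p`, energy
#' `sum p^2`, correlation `sum (i-mu_i)(j-mu_j) p / (sigma_i sigma_j)` and
#' homogeneity `sum p / (1 + (i-j)^2)`. A constant region has a single
#' co-occurrence cell: entropy and inertia 0, energy and homogeneity 1, and
#' correlation defined as 1 (degenerate perfectly-matched pairs).
#'
#' @inheritParams color_features
#' @return named numeric vector of length 5.
#' @export
glcm_features <- function(region) {
  sp <- glcm_matrix_sparse(region_intensity(region))
  i <- sp$i; j <- sp$j; p <- sp$p
  mui <- sum(i * p); muj <- sum(j * p)
  si <- sqrt(sum((i - mui)^2 * p)); sj <- sqrt(sum((j - muj)^2 * p))
  out <- c(-sum(p * log2(p)),
           sum((i - j)^2 * p),
           sum(p^2),
           if (si * sj > 0) sum((i - mui) * (j - muj) * p) / (si * sj) else 1,
           sum(p / (1 + (i - j)^2)))
  names(out) <- feature_names()[47:51]
  out
}

# --- FFT --------------------------------------------------------------------

#' FFT power-spectrum statistics of a region (4 values)
#'
#' The 2-D DFT of the mean-subtracted intensity image is taken; `P` is the
#' squared magnitude spectrum with the DC bin removed, folded over Hermitian
#' symmetry (each conjugate pair contributes once with its combined mass, so
#' a pure single-frequency tone concentrates all mass in one bin) and
#' normalised to sum to 1. With `d(u,v)` the Euclidean distance of a bin from
#' the zero-frequency origin: energy `sum P^2`, entropy `-sum P log2 P`,
#' inertia `sum d^2 P`, homogeneity `sum P / (1 + d^2)`. A spectrally empty
#' (constant) region returns all four as 0.
#'
#' @inheritParams color_features
#' @return named numeric vector of length 4.
#' @export
fft_features <- function(region) {
  I <- region_intensity(region)
  h <- nrow(I); w <- ncol(I)
  if (h < 2L || w < 2L) stop("FFT features need a region of at least 2 x 2 pixels", call. = FALSE)
  P <- Mod(stats::fft(I - mean(I)))^2
  P[1, 1] <- 0
  tot <- sum(P)
  nm <- feature_names()[52:55]
  if (tot <= 1e-12 * length(P)) {
    out <- c(0, 0, 0, 0); names(out) <- nm
    return(out)
  }
  k1 <- rep(0:(h - 1), times = w); k2 <- rep(0:(w - 1), each = h)
  c1 <- (h - k1) %% h; c2 <- (w - k2) %% w          # conjugate bin index
  self <- k1 == c1 & k2 == c2
  keep <- self | (k1 < c1) | (k1 == c1 & k2 < c2)   # one representative per pair
  pv <- as.vector(P)
  conj <- pv[c1 + 1L + c2 * h]                      # mass of each bin's conjugate
  folded <- pv[keep] + ifelse(self[keep], 0, conj[keep])
  folded <- folded / sum(folded)
  u <- ifelse(k1[keep] <= h / 2, k1[keep], k1[keep] - h)
  v <- ifelse(k2[keep] <= w / 2, k2[keep], k2[keep] - w)
  d2 <- u^2 + v^2
  drop0 <- folded > 0 & d2 > 0    # DC representative carries no mass but guard anyway
  folded <- folded[drop0]; d2 <- d2[drop0]
  out <- c(sum(folded^2),
           -sum(folded * log2(folded)),
           sum(d2 * folded),
           sum(folded / (1 + d2)))
  names(out) <- nm
  out
}

# --- full descriptor --------------------------------------------------------

#' Full 55-feature descriptor of a region
#'
#' Concatenates [color_features()], [intensity_features()], [lbp_features()],
#' [glcm_features()] and [fft_features()] in canonical order.
#'
#' @inheritParams color_features
#' @return named numeric vector of length 55; provenance (`sample_id`,
#'   `level`, `tile_index`) is attached as attributes when the region
#'   carries it.
#' @export
extract_all <- function(region) {
  out <- c(color_features(region), intensity_features(region),
           lbp_features(region), glcm_features(region), fft_features(region))
  stopifnot(identical(names(out), feature_names()))
  if (inherits(region, "pyramid_region")) {
    attr(out, "sample_id") <- region$sample_id
    attr(out, "level") <- region$level
    attr(out, "tile_index") <- region$tile_index
  }
  out
}

#' Feature table of one pyramid (21 rows)
#'
#' @param pyr a `pyramid_set`.
#' @return data.frame with provenance columns `sample_id`, `cultivar_id`,
#'   `level`, `tile_index`, `label` followed by the 55 features.
#' @export
pyramid_feature_rows <- function(pyr) {
  stopifnot(inherits(pyr, "pyramid_set"))
  feats <- t(vapply(pyr$regions, function(rg) unname(extract_all(rg)), numeric(55)))
  colnames(feats) <- feature_names()
  cbind(data.frame(sample_id = pyr$sample_id,
                   cultivar_id = pyr$cultivar_id,
                   level = vapply(pyr$regions, `[[`, 0L, "level"),
                   tile_index = vapply(pyr$regions, `[[`, 0L, "tile_index"),
                   label = pyr$label,
                   stringsAsFactors = FALSE),
        as.data.frame(feats))
}

#' Feature table of a whole image set
#'
#' Runs ROI extraction, pyramid partition and feature extraction for every
#' image and stacks the per-region rows (21 per sample).
#'
#' @param images list of `rgb_image` objects (or already-extracted
#'   `flour_roi`s, in which case ROI extraction is skipped).
#' @param invert_foreground passed to [extract_roi()].
#' @return data.frame, 21 rows per sample.
#' @export
feature_table <- function(images, invert_foreground = FALSE) {
  rows <- lapply(images, function(img) {
    roi <- if (inherits(img, "flour_roi")) img else extract_roi(img, invert_foreground)
    pyramid_feature_rows(pyramid_partition(roi))
  })
  do.call(rbind, rows)
}

#' Write / read a feature table as CSV with header validation
#'
#' @param tab feature table as produced by [feature_table()].
#' @param path CSV path.
#' @return `path` / the validated data.frame.
#' @export
write_feature_table <- function(tab, path) {
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "cultivar_id", "level", "tile_index", "label", feature_names())
  missing <- setdiff(need, names(tab))
  if (length(missing))
    stop("feature table is missing columns: ", paste(missing, collapse = ","), call. = FALSE)
  tab
}
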