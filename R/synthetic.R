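#' Configuration of the synthetic flour-image generator
#'
#' The defaults reproduce the design of the study dataset the pipeline is
#' meant for: 14 malting + 8 naked cultivars, five images each, hence 110
#' images (70 malting, 40 naked). Each image is a bright circular flour patch
#' on a dark scanner-like background so ROI extraction is exercised. Classes
#' differ in mean colour -- a gap of 3 units on each of L*, a*, b*, i.e.
#' three cultivar-offset standard deviations per channel -- and in the
#' density of dark elongated "husk fragment" speckles (malting flour carries
#' more husk debris than naked flour).
#'
#' @param n_cultivars_malting,n_cultivars_naked cultivar counts (14, 8).
#' @param images_per_cultivar images per cultivar (5).
#' @param image_side image side in pixels (256).
#' @param class_lab_means named list of L*a*b* class mean triples.
#' @param cultivar_offset_sigma sd (L*a*b* units) of the per-cultivar colour
#'   offset shared by a cultivar's images (1.0).
#' @param grain_noise_sigma sd of per-pixel granular L* noise (3.0); a*/b*
#'   receive a third of it.
#' @param husk_density speckles per 10^4 foreground pixels, named per class.
#' @param husk_length,husk_width speckle axis ranges in pixels.
#' @param background_margin dark border width in pixels (24).
#' @param hard_cultivar if `TRUE`, one naked cultivar's colour offset is
#'   placed at the malting class mean, mimicking a hull-less cultivar bred
#'   from malting stock whose flour looks malting-like.
#' @param seed integer seed; the entire dataset is a deterministic function
#'   of the config.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(n_cultivars_malting = 14L, n_cultivars_naked = 8L,
                         images_per_cultivar = 5L, image_side = 256L,
                         class_lab_means = list(malting = c(72, 4, 18),
                                                naked = c(75, 1, 15)),
                         cultivar_offset_sigma = 1.0, grain_noise_sigma = 3.0,
                         husk_density = c(malting = 3.5, naked = 1.0),
                         husk_length = c(6, 14), husk_width = c(1, 3),
                         background_margin = 24L, hard_cultivar = FALSE,
                         seed = 1L) {
  cfg <- list(n_cultivars_malting = as.integer(n_cultivars_malting),
              n_cultivars_naked = as.integer(n_cultivars_naked),
              images_per_cultivar = as.integer(images_per_cultivar),
              image_side = as.integer(image_side),
              class_lab_means = class_lab_means,
              cultivar_offset_sigma = cultivar_offset_sigma,
              grain_noise_sigma = grain_noise_sigma,
              husk_density = husk_density,
              husk_length = husk_length, husk_width = husk_width,
              background_margin = as.integer(background_margin),
              hard_cultivar = isTRUE(hard_cultivar),
              seed = as.integer(seed))
  with(cfg, {
    if (n_cultivars_malting < 1L || n_cultivars_naked < 1L || images_per_cultivar < 1L)
      stop("cultivar and image counts must be positive", call. = FALSE)
    if (image_side < 32L) stop("image_side must be at least 32", call. = FALSE)
    if (any(husk_density < 0) || grain_noise_sigma < 0 || cultivar_offset_sigma < 0)
      stop("densities and noise levels must be non-negative", call. = FALSE)
    if (background_margin < 2L || background_margin > image_side %/% 3L)
      stop("background_margin must be in [2, image_side/3]", call. = FALSE)
  })
  structure(cfg, class = "synth_config")
}

#' @rdname synth_config
#' @param path YAML file with config overrides.
#' @export
synth_config_yaml <- function(path) {
  do.call(synth_config, yaml::read_yaml(path))
}

lab_to_rgb255 <- function(lab) {
  rgb <- grDevices::convertColor(lab, from = "Lab", to = "sRGB", clip = TRUE)
  rgb * 255
}

# stamp one dark elongated ellipse into the Lab channel matrices (by ref-ish:
# returns modified list)
stamp_husk <- function(chan, cy, cx, len, wid, theta, husk_lab) {
  h <- nrow(chan$L); w <- ncol(chan$L)
  half <- ceiling(len / 2)
  rr <- max(1L, floor(cy - half)):min(h, ceiling(cy + half))
  cc <- max(1L, floor(cx - half)):min(w, ceiling(cx + half))
  dy <- outer(rr - cy, rep(1, length(cc)))
  dx <- outer(rep(1, length(rr)), cc - cx)
  a <- dx * cos(theta) + dy * sin(theta)
  b <- -dx * sin(theta) + dy * cos(theta)
  inside <- (a / (len / 2))^2 + (b / (wid / 2))^2 <= 1
  if (any(inside)) {
    for (k in c("L", "A", "B")) {
      sub <- chan[[k]][rr, cc]
      sub[inside] <- husk_lab[[k]]
      chan[[k]][rr, cc] <- sub
    }
  }
  chan
}

#' Generate a labelled synthetic flour-image dataset
#'
#' For each cultivar a colour offset is drawn once; each image is the class
#' mean plus that offset, per-pixel Gaussian granular noise, a Poisson number
#' of dark elongated husk speckles at the class density, converted from
#' L*a*b* to sRGB, and surrounded by a dark background margin (the flour
#' patch is a centred disk). Fully deterministic given the config seed.
#'
#' @param cfg a [synth_config()].
#' @return list with `images` (list of `rgb_image`) and `manifest`
#'   (data.frame `sample_id,cultivar_id,label,path`; `path` is `NA` until the
#'   images are written).
#' @export
generate_dataset <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed)
  cultivars <- data.frame(
    cultivar_id = c(sprintf("B%02d", seq_len(cfg$n_cultivars_malting)),
                    sprintf("N%02d", seq_len(cfg$n_cultivars_naked))),
    label = rep(c("malting", "naked"),
                c(cfg$n_cultivars_malting, cfg$n_cultivars_naked)),
    stringsAsFactors = FALSE)
  images <- list(); manifest <- NULL
  husk_lab <- list(L = 35, A = 8, B = 16)
  for (ci in seq_len(nrow(cultivars))) {
    cv <- cultivars[ci, ]
    base <- cfg$class_lab_means[[cv$label]]
    offset <- stats::rnorm(3, 0, cfg$cultivar_offset_sigma)
    if (cfg$hard_cultivar && cv$cultivar_id == "N01")
      offset <- cfg$class_lab_means$malting - base   # malting-like naked cultivar
    for (ii in seq_len(cfg$images_per_cultivar)) {
      sid <- sprintf("%s_A%d", cv$cultivar_id, ii - 1L)
      images[[length(images) + 1L]] <-
        synth_image(cfg, base + offset, cv$label, husk_lab, sid, cv$cultivar_id)
      manifest <- rbind(manifest,
                        data.frame(sample_id = sid, cultivar_id = cv$cultivar_id,
                                   label = cv$label, path = NA_character_,
                                   stringsAsFactors = FALSE))
    }
  }
  list(images = images, manifest = manifest)
}

synth_image <- function(cfg, lab_mean, label, husk_lab, sample_id, cultivar_id) {
  n <- cfg$image_side
  npx <- n * n
  chan <- list(
    L = matrix(lab_mean[1] + stats::rnorm(npx, 0, cfg$grain_noise_sigma), n, n),
    A = matrix(lab_mean[2] + stats::rnorm(npx, 0, cfg$grain_noise_sigma / 3), n, n),
    B = matrix(lab_mean[3] + stats::rnorm(npx, 0, cfg$grain_noise_sigma / 3), n, n))
  # husk speckles over the flour disk
  ctr <- (n + 1) / 2
  rad <- n / 2 - cfg$background_margin
  area <- pi * rad^2
  dens <- cfg$husk_density[[label]]
  n_husk <- if (dens > 0) stats::rpois(1, dens * area / 1e4) else 0L
  if (n_husk > 0) for (s in seq_len(n_husk)) {
    ang <- stats::runif(1, 0, 2 * pi)
    r <- rad * sqrt(stats::runif(1))
    chan <- stamp_husk(chan,
                       cy = ctr + r * sin(ang), cx = ctr + r * cos(ang),
                       len = stats::runif(1, cfg$husk_length[1], cfg$husk_length[2]),
                       wid = stats::runif(1, cfg$husk_width[1], cfg$husk_width[2]),
                       theta = stats::runif(1, 0, pi), husk_lab = husk_lab)
  }
  rgb <- lab_to_rgb255(cbind(as.vector(chan$L), as.vector(chan$A), as.vector(chan$B)))
  px <- array(0, c(n, n, 3))
  px[, , 1] <- rgb[, 1]; px[, , 2] <- rgb[, 2]; px[, , 3] <- rgb[, 3]
  # dark background outside the flour disk (slightly noisy scanner backing)
  dy <- outer(seq_len(n) - ctr, rep(1, n)); dx <- t(dy)
  bg <- dy^2 + dx^2 > rad^2
  nbg <- sum(bg)
  for (k in 1:3) {
    pk <- px[, , k]
    pk[bg] <- pmin(pmax(25 + stats::rnorm(nbg, 0, 2), 0), 255)
    px[, , k] <- pk
  }
  px <- round(pmin(pmax(px, 0), 255))
  rgb_image(px, sample_id = sample_id, cultivar_id = cultivar_id, label = label)
}

#' Corrupt one Level-1 quadrant of an image with a localized artifact
#'
#' Injects dense dark speckle noise (or a box blur) confined to one quadrant
#' under the same floor-split boundaries the pyramid uses, leaving all other
#' pixels bit-identical. This builds the motivating scenario for sub-region
#' voting: a spatially localized contamination can flip at most 1 Level-1 and
#' 4 Level-2 votes, a weighted score shift of at most `w1 + 4 w2`.
#'
#' @param img an `rgb_image` or `flour_roi`.
#' @param quadrant 0..3, row-major.
#' @param kind `"speckle"` or `"blur"`.
#' @param seed seed for the speckle placement.
#' @param fraction fraction of quadrant pixels hit by speckle (0.25).
#' @return object of the same class with the corrupted pixels.
#' @export
localized_artifact <- function(img, quadrant, kind = c("speckle", "blur"),
                               seed = 1L, fraction = 0.25) {
  kind <- match.arg(kind)
  stopifnot(quadrant %in% 0:3)
  px <- img$pixels
  h <- dim(px)[1]; w <- dim(px)[2]
  rh <- if (quadrant %/% 2L == 0L) seq_len(h %/% 2L) else (h %/% 2L + 1L):h
  cw <- if (quadrant %% 2L == 0L) seq_len(w %/% 2L) else (w %/% 2L + 1L):w
  block <- px[rh, cw, , drop = FALSE]
  if (kind == "speckle") {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(seed)
    npx <- length(rh) * length(cw)
    hit <- sample.int(npx, max(1L, round(fraction * npx)))
    dark <- matrix(stats::runif(length(hit) * 3, 10, 60), ncol = 3)
    for (k in 1:3) {
      bk <- block[, , k]
      bk[hit] <- dark[, k]
      block[, , k] <- bk
    }
  } else {
    for (k in 1:3) block[, , k] <- box_blur(block[, , k], 2L)
  }
  px[rh, cw, ] <- round(pmin(pmax(block, 0), 255))
  out <- img
  out$pixels <- px
  out
}

box_blur <- function(m, r) {
  h <- nrow(m); w <- ncol(m)
  out <- m
  for (i in seq_len(h)) {
    rr <- max(1, i - r):min(h, i + r)
    out[i, ] <- colMeans(m[rr, , drop = FALSE])
  }
  m2 <- out
  for (j in seq_len(w)) {
    cc <- max(1, j - r):min(w, j + r)
    out[, j] <- rowMeans(m2[, cc, drop = FALSE])
  }
  out
}
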