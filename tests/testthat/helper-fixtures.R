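# shared fixture builders: every fixture is generated in code, none on disk

# H x W x 3 array with all channels equal to `value` (or per-channel triple)
const_rgb <- function(h, w, value) {
  v <- rep(value, length.out = 3)
  px <- array(0, c(h, w, 3))
  for (k in 1:3) px[, , k] <- v[k]
  px
}

# seeded random RGB array
rand_rgb <- function(h, w, seed = 1) {
  withr::with_seed(seed, array(sample(0:255, h * w * 3, TRUE), c(h, w, 3)))
}

# rgb_image around an arbitrary pixel array
as_img <- function(px, sample_id = "t", label = NA_character_,
                   cultivar_id = "c1") {
  rgb_image(px, sample_id = sample_id, cultivar_id = cultivar_id, label = label)
}

# grey matrix -> replicated 3-channel array (intensity == grey)
grey_rgb <- function(m) {
  px <- array(0, c(nrow(m), ncol(m), 3))
  for (k in 1:3) px[, , k] <- m
  px
}

# circular foreground mask
disk_mask <- function(n, r, ctr = (n + 1) / 2) {
  d2 <- outer((seq_len(n) - ctr)^2, rep(1, n)) + t(outer((seq_len(n) - ctr)^2, rep(1, n)))
  d2 <= r^2
}

# small synthetic dataset feature table, memoised per options
small_ftab <- local({
  cache <- list()
  function(n_malt = 3, n_naked = 3, per = 2, side = 96, seed = 7, ...) {
    key <- paste(n_malt, n_naked, per, side, seed, ..., sep = "_")
    if (is.null(cache[[key]])) {
      cfg <- synth_config(n_cultivars_malting = n_malt, n_cultivars_naked = n_naked,
                          images_per_cultivar = per, image_side = side,
                          background_margin = 16, seed = seed, ...)
      cache[[key]] <<- feature_table(generate_dataset(cfg)$images)
    }
    cache[[key]]
  }
})

# a trained-model shell whose base learner returns scripted labels; used to
# test the voting arithmetic in isolation
scripted_model <- function(labels_by_tile, classes = c("A", "B"),
                           w = vote_weights(), majority = "A",
                           level0_label = classes[1]) {
  cl <- structure(list(
    name = "scripted",
    fit = function(X, y, meta = NULL) NULL,
    predict = function(state, X, meta = NULL) {
      if (nrow(meta) == 1L && meta$level == 0L)
        return(factor(level0_label, levels = classes))
      key <- paste0(meta$level, "_", meta$tile_index)
      factor(labels_by_tile[key], levels = classes)
    }), class = "sppe_classifier")
  structure(list(classifier = cl, state = NULL,
                 center = stats::setNames(rep(0, 55), feature_names()),
                 scale = stats::setNames(rep(1, 55), feature_names()),
                 weights = w, classes = classes, majority = majority,
                 mode = "sppe"),
            class = "sppe_model")
}

# feature-table skeleton for one sample: 21 rows of zero features
skeleton_rows <- function(sample_id = "s1", label = "A") {
  lv <- rep(0:2, c(1, 4, 16))
  ti <- c(0L, 0:3, 0:15)
  feats <- matrix(0, 21, 55, dimnames = list(NULL, feature_names()))
  cbind(data.frame(sample_id = sample_id, cultivar_id = "c", level = lv,
                   tile_index = ti, label = label, stringsAsFactors = FALSE),
        as.data.frame(feats))
}
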