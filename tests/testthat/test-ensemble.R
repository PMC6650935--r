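# --- independent oracle -------------------------------------------------------

# explicit-loop Kennard-Stone reimplementation for small point sets
ks_oracle <- function(X, n_train) {
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd); sdv[sdv == 0] <- 1
  Z <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  n <- nrow(Z)
  D <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) D[i, j] <- sqrt(sum((Z[i, ] - Z[j, ])^2))
  best <- c(NA, NA); bd <- -1
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    if (D[i, j] > bd + 1e-12) { bd <- D[i, j]; best <- c(i, j) }
  sel <- best
  while (length(sel) < n_train) {
    cand <- setdiff(1:n, sel)
    dm <- vapply(cand, function(c) min(D[c, sel]), numeric(1))
    sel <- c(sel, cand[which(dm >= max(dm) - 1e-12)][1])
  }
  sort(sel)
}

# ------------------------------------------------------------------------------

test_that("vote_weights validates and defaults to equal level influence", {
  w <- vote_weights()
  expect_equal(4 * w$w1, 16 * w$w2)
  expect_equal(4 * w$w1, 4 / 3)
  expect_error(vote_weights(0, 1 / 12), "positive")
})

test_that("build_dataset shapes sppe/traditional/spp views with the stated counts", {
  ftab <- rbind(skeleton_rows("s1", "A"), skeleton_rows("s2", "B"),
                skeleton_rows("s3", "A"))
  sppe <- build_dataset(ftab, "sppe")
  expect_equal(nrow(sppe), 60)                  # 20 rows per sample
  expect_equal(as.vector(table(sppe$sample_id)), rep(20L, 3))
  expect_true(all(sppe$level >= 1))
  expect_true(all(sppe$label == ftab$label[match(sppe$sample_id, ftab$sample_id)]))
  trad <- build_dataset(ftab, "traditional")
  expect_equal(dim(trad)[1], 3)
  expect_true(all(trad$level == 0))
  spp <- build_dataset(ftab, "spp")
  expect_equal(nrow(spp), 3)
  expect_length(grep("_L[0-2]_T", names(spp)), 1155)
  expect_error(build_dataset(ftab[-1, ], "sppe"), "missing pyramid")
})

test_that("Kennard-Stone picks extremes first and reports the canonical proportions", {
  sp <- kennard_stone_split(matrix(c(0, 1, 10), ncol = 1), 2)
  expect_identical(sp$train, c(1L, 3L))
  expect_identical(sp$test, 2L)
  # 110 -> 90/20 proportions
  withr::with_seed(8, X <- matrix(stats::rnorm(110 * 4), 110))
  sp <- kennard_stone_split(X, 90)
  expect_length(sp$train, 90)
  expect_length(sp$test, 20)
  expect_equal(round(100 * length(sp$train) / 110, 1), 81.8)
  expect_equal(round(100 * length(sp$test) / 110, 1), 18.2)
  expect_error(kennard_stone_split(X, 110), "n_train")
})

test_that("Kennard-Stone equals the explicit-loop oracle on small point sets", {
  withr::with_seed(31, {
    for (i in 1:10) {
      n <- sample(5:12, 1)
      X <- matrix(stats::rnorm(n * 3), n)
      n_train <- sample(2:(n - 1), 1)
      expect_identical(kennard_stone_split(X, n_train)$train, ks_oracle(X, n_train))
    }
    # duplicate rows: ties broken towards the smallest index
    X <- rbind(c(0, 0), c(0, 0), c(5, 5), c(0, 0))
    expect_identical(kennard_stone_split(X, 3)$train, ks_oracle(X, 3))
  })
})

test_that("weighted vote: unanimity, forced ties and the documented tie-break", {
  rows <- skeleton_rows("s1", "A")
  key <- paste0(rows$level, "_", rows$tile_index)[rows$level >= 1]
  unanimous <- stats::setNames(rep("A", 20), key)
  m <- scripted_model(unanimous)
  res <- predict_sample(m, rows)
  expect_equal(res$label, "A")
  expect_equal(unname(res$score["A"]), 8 / 3)   # 4/3 + 16/12
  expect_equal(sum(res$score), 4 * (1 / 3) + 16 * (1 / 12))
  # 4 level-1 votes A vs 16 level-2 votes B: exact 4/3 vs 4/3 tie,
  # resolved by the model's own level-0 prediction
  split_vote <- stats::setNames(ifelse(grepl("^1_", key), "A", "B"), key)
  m2 <- scripted_model(split_vote, level0_label = "B")
  res2 <- predict_sample(m2, rows)
  expect_equal(unname(res2$score), c(4 / 3, 4 / 3))
  expect_equal(res2$label, "B")
  m2a <- scripted_model(split_vote, level0_label = "A")
  expect_equal(predict_sample(m2a, rows)$label, "A")
  # 3 L1 + 4 L2 for A vs 1 L1 + 12 L2 for B: tie at 4/3; w2 = 1/13 breaks it
  l1 <- key[grepl("^1_", key)]; l2 <- key[grepl("^2_", key)]
  votes <- stats::setNames(c(rep("A", 3), "B", rep("A", 4), rep("B", 12)),
                           c(l1[1:3], l1[4], l2[1:4], l2[5:16]))
  m3 <- scripted_model(votes, level0_label = "B")
  res3 <- predict_sample(m3, rows)
  expect_equal(unname(res3$score["A"]), 3 / 3 + 4 / 12)
  expect_equal(unname(res3$score["B"]), 1 / 3 + 12 / 12)
  expect_equal(res3$label, "B")                 # level-0 tie-break
  m4 <- scripted_model(votes, w = vote_weights(1 / 3, 1 / 13), level0_label = "B")
  expect_equal(predict_sample(m4, rows)$label, "A")
  # score mass conservation under arbitrary weights
  expect_equal(sum(predict_sample(m4, rows)$score), 4 / 3 + 16 / 13)
})

test_that("flipping all four level-1 votes moves the score by exactly 4/3", {
  rows <- skeleton_rows("s1", "A")
  key <- paste0(rows$level, "_", rows$tile_index)[rows$level >= 1]
  base <- stats::setNames(ifelse(grepl("^1_", key), "A", "B"), key)
  flipped <- base
  flipped[grepl("^1_", key)] <- "B"
  sA <- predict_sample(scripted_model(base), rows)$score
  sB <- predict_sample(scripted_model(flipped), rows)$score
  expect_equal(unname(sA["A"] - sB["A"]), 4 / 3)
})

test_that("sppe_fit validates labels and classes", {
  ftab <- rbind(skeleton_rows("s1", "A"), skeleton_rows("s2", "A"))
  expect_error(sppe_fit(ftab, make_classifier("tree")), "single class")
  ftab$label <- NA_character_
  expect_error(sppe_fit(ftab, make_classifier("tree")), "label")
})

test_that("LOSO never leaks held-out sub-regions into training (spy classifier)", {
  ftab <- small_ftab(n_malt = 2, n_naked = 2, per = 2, side = 64, seed = 13)
  log <- new.env()
  log$folds <- list()
  spy <- structure(list(
    name = "spy",
    fit = function(X, y, meta = NULL) {
      list(train_ids = unique(meta$sample_id), lvl = levels(y))
    },
    predict = function(state, X, meta = NULL) {
      log$folds[[length(log$folds) + 1]] <-
        list(train = state$train_ids, test = unique(meta$sample_id))
      factor(rep(state$lvl[1], nrow(X)), levels = state$lvl)
    }), class = "sppe_classifier")
  for (k in list(NULL, 3L)) {
    log$folds <- list()
    ev <- loso_evaluate(ftab, spy, "sppe", k = k, seed = 2)
    expect_gt(length(log$folds), 0)
    for (f in log$folds) expect_length(intersect(f$train, f$test), 0)
    # every sample predicted exactly once
    expect_setequal(ev$predictions$sample_id, unique(ftab$sample_id))
  }
})

test_that("LOSO separates a clearly separable two-class synthetic set perfectly", {
  ftab <- small_ftab(n_malt = 3, n_naked = 3, per = 2, side = 64, seed = 19)
  ev <- loso_evaluate(ftab, make_classifier("tree"), "sppe")
  expect_equal(ev$metrics$accuracy, 1)
  expect_equal(nrow(ev$predictions), 12)
  # grouped 4-fold is also clean and trains on whole samples only
  ev2 <- loso_evaluate(ftab, make_classifier("knn"), "sppe", k = 4, seed = 3)
  expect_setequal(unname(unlist(ev2$folds)), unique(ftab$sample_id))
})

test_that("baseline modes classify via single rows and score the winner 1", {
  ftab <- small_ftab(n_malt = 3, n_naked = 3, per = 2, side = 64, seed = 19)
  for (mode in c("traditional", "spp")) {
    model <- sppe_fit(ftab, make_classifier("tree"), mode)
    pred <- predict(model, ftab)
    expect_equal(nrow(pred), 12)
    expect_true(all(rowSums(pred[paste0("score_", model$classes)]) == 1))
    expect_true(all(pred$prediction %in% model$classes))
  }
})

test_that("all four injected learners satisfy the fit/predict contract", {
  ftab <- small_ftab(n_malt = 2, n_naked = 2, per = 2, side = 64, seed = 23)
  sp <- kennard_stone_split(
    as.matrix(ftab[ftab$level == 0, feature_names()]), 6,
    ids = unique(ftab$sample_id))
  train <- ftab[ftab$sample_id %in% sp$train, ]
  test <- ftab[ftab$sample_id %in% sp$test, ]
  for (cl in c("knn", "tree", "forest", "logistic")) {
    model <- sppe_fit(train, make_classifier(cl, seed = 5), "sppe")
    pred <- predict(model, test)
    expect_true(all(pred$prediction %in% model$classes), info = cl)
    expect_equal(nrow(pred), 2, info = cl)
  }
})

test_that("forest training is deterministic under its seed", {
  ftab <- small_ftab(n_malt = 2, n_naked = 2, per = 2, side = 64, seed = 23)
  p1 <- predict(sppe_fit(ftab, make_classifier("forest", seed = 9, ntree = 15), "sppe"), ftab)
  p2 <- predict(sppe_fit(ftab, make_classifier("forest", seed = 9, ntree = 15), "sppe"), ftab)
  expect_identical(p1, p2)
})

test_that("model archives round-trip", {
  ftab <- small_ftab(n_malt = 2, n_naked = 2, per = 2, side = 64, seed = 23)
  model <- sppe_fit(ftab, make_classifier("tree"), "sppe")
  dir <- withr::local_tempdir()
  save_model(model, dir)
  expect_true(file.exists(file.path(dir, "meta.json")))
  back <- load_model(dir)
  expect_identical(predict(back, ftab), predict(model, ftab))
})
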