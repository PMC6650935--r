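#' Voting weights of the sub-region ensemble
#'
#' Each Level-1 member votes with weight `w1` (default 1/3) and each Level-2
#' member with weight `w2` (default 1/12), so by default the four Level-1
#' tiles and the sixteen Level-2 tiles carry equal total influence
#' (4 x 1/3 = 16 x 1/12 = 4/3).
#'
#' @param w1,w2 positive member weights.
#' @return an object of class `vote_weights`.
#' @export
vote_weights <- function(w1 = 1 / 3, w2 = 1 / 12) {
  if (!(w1 > 0 && w2 > 0)) stop("vote weights must be positive", call. = FALSE)
  structure(list(w1 = w1, w2 = w2), class = "vote_weights")
}

#' Shape a per-region feature table into a modelling dataset
#'
#' @param ftab feature table (21 rows per sample, see [feature_table()]).
#' @param mode `"sppe"` keeps the 20 Level-1/2 rows per sample (the
#'   sub-region dataset); `"traditional"` keeps the single Level-0 row per
#'   sample; `"spp"` concatenates all 21 region vectors into one
#'   1155-dimensional row per sample.
#' @return data.frame with provenance columns and feature columns.
#' @export
build_dataset <- function(ftab, mode = c("sppe", "traditional", "spp")) {
  mode <- match.arg(mode)
  check_complete_pyramids(ftab)
  if (mode == "sppe") {
    out <- ftab[ftab$level >= 1L, , drop = FALSE]
    rownames(out) <- NULL
    return(out)
  }
  if (mode == "traditional") {
    out <- ftab[ftab$level == 0L, , drop = FALSE]
    rownames(out) <- NULL
    return(out)
  }
  # spp: one wide row per sample
  ids <- unique(ftab$sample_id)
  rows <- lapply(ids, function(s) {
    sub <- ftab[ftab$sample_id == s, , drop = FALSE]
    v <- spp_concat(sub)
    meta <- sub[sub$level == 0L, c("sample_id", "cultivar_id", "label"), drop = FALSE]
    cbind(meta, as.data.frame(t(v)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

check_complete_pyramids <- function(ftab) {
  need <- c("sample_id", "level", "tile_index", "label")
  stopifnot(all(need %in% names(ftab)))
  per <- table(ftab$sample_id)
  bad <- names(per)[per != 21L]
  if (length(bad))
    stop("samples with missing pyramid regions: ", paste(bad, collapse = ","), call. = FALSE)
  invisible(ftab)
}

dataset_features <- function(ds) {
  fn <- if (all(feature_names() %in% names(ds))) feature_names()
        else grep("_L[0-2]_T[0-9]+$", names(ds), value = TRUE)
  as.matrix(ds[, fn, drop = FALSE])
}

#' Kennard-Stone representative train/test split
#'
#' Classic max-min selection: features are z-scored, the two mutually most
#' distant samples seed the training set, and samples are added one at a time
#' by maximising the minimum Euclidean distance to the already-chosen set.
#' Ties break towards the smallest sample index, so the split is
#' deterministic.
#'
#' @param X numeric matrix, one row per sample (the Level-0 descriptors).
#' @param n_train number of training samples to select.
#' @param ids optional sample identifiers (default: row indices).
#' @return list with `train` and `test` id vectors.
#' @export
kennard_stone_split <- function(X, n_train, ids = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (is.null(ids)) ids <- seq_len(n)
  stopifnot(length(ids) == n)
  if (n_train >= n || n_train < 2L)
    stop("n_train must be in [2, n_samples - 1]", call. = FALSE)
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[sdv == 0] <- 1
  Z <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  D <- as.matrix(stats::dist(Z))
  # seed: first (in row-major index order) pair attaining the max distance
  mx <- max(D)
  pair <- which(D == mx, arr.ind = TRUE)
  pair <- pair[order(pair[, 1], pair[, 2]), , drop = FALSE]
  sel <- sort(unique(c(pair[1, 1], pair[1, 2])))[1:2]
  dmin <- pmin(D[, sel[1]], D[, sel[2]])
  while (length(sel) < n_train) {
    dmin[sel] <- -Inf
    nxt <- which.max(dmin)       # first maximiser = smallest index on ties
    sel <- c(sel, nxt)
    dmin <- pmin(dmin, D[, nxt])
  }
  list(train = ids[sort(sel)], test = ids[setdiff(seq_len(n), sel)])
}

#' Train an SPPe (or baseline) model
#'
#' A single base classifier is fitted on all rows of the mode-shaped dataset:
#' every Level-1/2 sub-region row for `"sppe"` (each sub-region inherits its
#' sample's label), the Level-0 rows for `"traditional"`, the concatenated
#' 1155-dimensional rows for `"spp"`. Features are z-scored with training
#' statistics.
#'
#' @param ftab per-region feature table of the training samples.
#' @param classifier an `sppe_classifier` (see [make_classifier()]).
#' @param mode `"sppe"`, `"traditional"` or `"spp"`.
#' @param weights a [vote_weights()] object (used by `"sppe"` prediction).
#' @return an object of class `sppe_model`.
#' @export
sppe_fit <- function(ftab, classifier = make_classifier("tree"),
                     mode = c("sppe", "traditional", "spp"),
                     weights = vote_weights()) {
  mode <- match.arg(mode)
  stopifnot(inherits(classifier, "sppe_classifier"), inherits(weights, "vote_weights"))
  ds <- build_dataset(ftab, mode)
  if (anyNA(ds$label)) stop("training rows must be labelled", call. = FALSE)
  y <- factor(ds$label)
  if (nlevels(y) < 2L) stop("training set contains a single class", call. = FALSE)
  X <- dataset_features(ds)
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0] <- 1
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  meta <- ds[intersect(c("sample_id", "level", "tile_index"), names(ds))]
  state <- classifier$fit(Xs, y, meta)
  tab <- table(y)
  structure(list(classifier = classifier, state = state, center = ctr, scale = scl,
                 weights = weights, classes = levels(y),
                 majority = names(tab)[which.max(tab)], mode = mode),
            class = "sppe_model")
}

#' @export
print.sppe_model <- function(x, ...) {
  cat(sprintf("<sppe_model> mode=%s base=%s classes=%s w1=%.4g w2=%.4g\n",
              x$mode, x$classifier$name, paste(x$classes, collapse = "/"),
              x$weights$w1, x$weights$w2))
  invisible(x)
}

model_predict_rows <- function(model, ds) {
  X <- dataset_features(ds)
  Xs <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
  meta <- ds[intersect(c("sample_id", "level", "tile_index"), names(ds))]
  pred <- model$classifier$predict(model$state, Xs, meta)
  factor(as.character(pred), levels = model$classes)
}

#' Classify one sample by the weighted vote of its 20 sub-regions
#'
#' Each Level-1/2 region is classified by the single base model; the score of
#' a class is the sum of the weights of the members voting for it (`w1` per
#' Level-1 member, `w2` per Level-2 member), so the total score mass is
#' always `4 w1 + 16 w2`. Ties (possible with the default equal-level
#' weights) fall back to the model's own prediction of the Level-0 region;
#' if no Level-0 row is available the training majority class is used.
#'
#' @param model a trained `sppe_model` with `mode = "sppe"`.
#' @param sample_rows the 21 feature-table rows of one sample (a Level-0 row
#'   plus 20 sub-region rows; the Level-0 row is only consulted on ties).
#' @return list with `label` and the named per-class `score` vector.
#' @export
predict_sample <- function(model, sample_rows) {
  stopifnot(inherits(model, "sppe_model"))
  if (model$mode != "sppe")
    stop("predict_sample applies to mode='sppe' models", call. = FALSE)
  sub <- sample_rows[sample_rows$level >= 1L, , drop = FALSE]
  if (nrow(sub) != 20L)
    stop("expected 20 sub-region rows, got ", nrow(sub), call. = FALSE)
  preds <- model_predict_rows(model, sub)
  w <- ifelse(sub$level == 1L, model$weights$w1, model$weights$w2)
  score <- vapply(model$classes, function(cl) sum(w[preds == cl]), numeric(1))
  top <- names(score)[score == max(score)]
  if (length(top) == 1L) {
    label <- top
  } else {
    lvl0 <- sample_rows[sample_rows$level == 0L, , drop = FALSE]
    label <- if (nrow(lvl0) == 1L)
      as.character(model_predict_rows(model, lvl0))
    else model$majority
  }
  list(label = label, score = score)
}

#' Predict a set of samples with a trained model
#'
#' @param object a trained `sppe_model`.
#' @param ftab per-region feature table of the samples to classify (21 rows
#'   per sample).
#' @param ... unused.
#' @return data.frame with one row per sample: `sample_id`, `truth`,
#'   `prediction` and one `score_<class>` column per class (scores are the
#'   weighted votes for `"sppe"`; for the baselines the predicted class
#'   scores 1).
#' @export
predict.sppe_model <- function(object, ftab, ...) {
  check_complete_pyramids(ftab)
  ids <- unique(ftab$sample_id)
  if (object$mode == "sppe") {
    res <- lapply(ids, function(s)
      predict_sample(object, ftab[ftab$sample_id == s, , drop = FALSE]))
    pred <- vapply(res, `[[`, character(1), "label")
    score <- t(vapply(res, `[[`, numeric(length(object$classes)), "score"))
  } else {
    ds <- build_dataset(ftab, object$mode)
    ds <- ds[match(ids, ds$sample_id), , drop = FALSE]
    pred <- as.character(model_predict_rows(object, ds))
    score <- outer(pred, object$classes, `==`) * 1
  }
  colnames(score) <- paste0("score_", object$classes)
  truth <- ftab$label[match(ids, ftab$sample_id)]
  cbind(data.frame(sample_id = ids, truth = truth, prediction = pred,
                   stringsAsFactors = FALSE),
        as.data.frame(score))
}

#' Grouped cross-validation with a hard leakage guard
#'
#' `loso_evaluate` runs Leave-One-Sample-Out: for each held-out sample the
#' model is trained on the rows of all other samples only -- no sub-region of
#' the held-out sample ever enters training -- and the sample is classified
#' with [predict.sppe_model()]. With `k` set, samples are instead partitioned
#' into `k` folds (folds always partition samples, never sub-regions). A
#' sample id found in both a fold's training and test rows aborts with an
#' assertion error.
#'
#' @param ftab per-region feature table (21 rows per sample, labelled).
#' @param classifier an `sppe_classifier`.
#' @param mode,weights see [sppe_fit()].
#' @param k optional fold count for grouped k-fold; default `NULL` = LOSO.
#' @param seed seed for fold shuffling in k-fold mode.
#' @return list with `predictions` (per-sample data.frame), `metrics`
#'   (see [classification_report()]) and `folds`.
#' @export
loso_evaluate <- function(ftab, classifier = make_classifier("tree"),
                          mode = c("sppe", "traditional", "spp"),
                          weights = vote_weights(), k = NULL, seed = 1L) {
  mode <- match.arg(mode)
  check_complete_pyramids(ftab)
  ids <- unique(ftab$sample_id)
  if (length(ids) < 3L) stop("grouped evaluation needs at least 3 samples", call. = FALSE)
  folds <- if (is.null(k)) {
    lapply(ids, function(s) s)
  } else {
    stopifnot(k >= 2L, k <= length(ids))
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(seed)
    split(sample(ids), rep_len(seq_len(k), length(ids)))
  }
  preds <- lapply(folds, function(test_ids) {
    train_tab <- ftab[!ftab$sample_id %in% test_ids, , drop = FALSE]
    test_tab <- ftab[ftab$sample_id %in% test_ids, , drop = FALSE]
    overlap <- intersect(unique(train_tab$sample_id), unique(test_tab$sample_id))
    stopifnot("grouping violation: sample present in both train and test" =
                length(overlap) == 0L)
    model <- sppe_fit(train_tab, classifier, mode, weights)
    predict(model, test_tab)
  })
  predictions <- do.call(rbind, preds)
  rownames(predictions) <- NULL
  list(predictions = predictions,
       metrics = classification_report(predictions$truth, predictions$prediction),
       folds = folds)
}

#' Save / load a trained model archive
#'
#' The archive is a directory holding the base-learner state blob plus a JSON
#' metadata file (mode, weights, class codebook, feature schema hash).
#'
#' @param model a trained `sppe_model`.
#' @param path archive directory.
#' @return `path` / the restored model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "sppe_model"))
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  saveRDS(model, file.path(path, "model.rds"))
  jsonlite::write_json(
    list(mode = model$mode, classifier = model$classifier$name,
         w1 = model$weights$w1, w2 = model$weights$w2, classes = model$classes,
         feature_schema = unname(substr(
           paste(feature_names(), collapse = "|"), 1, 1e6))),
    file.path(path, "meta.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(file.path(path, "model.rds"))
  stopifnot(inherits(m, "sppe_model"))
  m
}
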