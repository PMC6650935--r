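#' Base classifiers behind a fit/predict contract
#'
#' The ensemble treats its base learner as an injected dependency: any list
#' with elements `name`, `fit(X, y, meta)` returning an opaque state, and
#' `predict(state, X, meta)` returning a factor of labels satisfies the
#' contract (`meta` is a data.frame of row provenance -- `sample_id`,
#' `level`, `tile_index` -- that ordinary learners ignore; test spies use
#' it to audit grouping). Four ready-made learners are provided:
#'
#' * `"knn"` -- k-nearest neighbours, Euclidean distance, `k = 5`
#'   (via \pkg{FNN}).
#' * `"tree"` -- a CART-style Gini decision tree with pruning by minimum
#'   node size and depth (implemented in this package; the classic
#'   C4.5/J48 implementation is not available in this environment).
#' * `"forest"` -- bagged ensemble of those trees, `ntree = 100`,
#'   `mtry = 7` features per split.
#' * `"logistic"` -- ridge-regularised logistic regression (via
#'   \pkg{glmnet}); stands in for a polynomial-kernel SVM, which has no
#'   implementation in this environment.
#'
#' @param name one of `"knn"`, `"tree"`, `"forest"`, `"logistic"`.
#' @param ... hyperparameter overrides (`k`; `max_depth`, `min_split`;
#'   `ntree`, `mtry`, `seed`; `lambda`).
#' @return an object of class `sppe_classifier`.
#' @export
make_classifier <- function(name = c("knn", "tree", "forest", "logistic"), ...) {
  name <- match.arg(name)
  opts <- list(...)
  cl <- switch(name,
    knn = classifier_knn(k = opts$k %||% 5L),
    tree = classifier_tree(max_depth = opts$max_depth %||% 20L,
                           min_split = opts$min_split %||% 4L),
    forest = classifier_forest(ntree = opts$ntree %||% 100L,
                               mtry = opts$mtry %||% 7L,
                               seed = opts$seed %||% 1L,
                               max_depth = opts$max_depth %||% 20L,
                               min_split = opts$min_split %||% 4L),
    logistic = classifier_logistic(lambda = opts$lambda %||% 1e-3))
  structure(cl, class = "sppe_classifier")
}

classifier_knn <- function(k = 5L) {
  list(name = "knn",
       fit = function(X, y, meta = NULL) list(X = X, y = y, k = k),
       predict = function(state, X, meta = NULL) {
         k_eff <- min(state$k, nrow(state$X))
         factor(as.character(FNN::knn(state$X, X, state$y, k = k_eff)),
                levels = levels(state$y))
       })
}

classifier_tree <- function(max_depth = 20L, min_split = 4L) {
  list(name = "tree",
       fit = function(X, y, meta = NULL)
         cart_fit(X, y, max_depth = max_depth, min_split = min_split),
       predict = function(state, X, meta = NULL) cart_predict(state, X))
}

classifier_forest <- function(ntree = 100L, mtry = 7L, seed = 1L,
                              max_depth = 20L, min_split = 4L) {
  list(name = "forest",
       fit = function(X, y, meta = NULL) {
         n <- nrow(X)
         old <- .Random.seed_save()
         on.exit(.Random.seed_restore(old))
         set.seed(seed)
         trees <- lapply(seq_len(ntree), function(b) {
           idx <- sample.int(n, n, replace = TRUE)
           cart_fit(X[idx, , drop = FALSE], y[idx], max_depth = max_depth,
                    min_split = min_split, mtry = min(mtry, ncol(X)))
         })
         list(trees = trees, levels = levels(y))
       },
       predict = function(state, X, meta = NULL) {
         votes <- vapply(state$trees, function(tr) as.integer(cart_predict(tr, X)),
                         integer(nrow(X)))
         if (nrow(X) == 1L) votes <- matrix(votes, nrow = 1L)
         win <- apply(votes, 1, function(v) which.max(tabulate(v, length(state$levels))))
         factor(state$levels[win], levels = state$levels)
       })
}

classifier_logistic <- function(lambda = 1e-3) {
  list(name = "logistic",
       fit = function(X, y, meta = NULL) {
         # glmnet warns on tiny classes; small training folds are expected here
         fit <- suppressWarnings(
           glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                          lambda = lambda, standardize = FALSE))
         list(fit = fit, levels = levels(y))
       },
       predict = function(state, X, meta = NULL) {
         pr <- stats::predict(state$fit, X, type = "class")
         factor(as.character(pr), levels = state$levels)
       })
}

# RNG bookkeeping so seeded learners do not disturb the caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

# --- CART decision tree -----------------------------------------------------
# Binary Gini-impurity tree on a numeric feature matrix. Nodes are stored in
# a flat list; splits are `x[, feat] <= cut` (left) vs `>` (right).

cart_fit <- function(X, y, max_depth = 20L, min_split = 4L, mtry = NULL) {
  stopifnot(is.matrix(X), is.factor(y), nrow(X) == length(y))
  K <- nlevels(y)
  yi <- as.integer(y)
  nodes <- list()
  new_node <- function() length(nodes) + 1L

  grow <- function(idx, depth) {
    cnt <- tabulate(yi[idx], K)
    id <- new_node()
    leaf <- list(leaf = TRUE, class = which.max(cnt), n = length(idx))
    if (depth >= max_depth || length(idx) < min_split || sum(cnt > 0L) < 2L) {
      nodes[[id]] <<- leaf
      return(id)
    }
    feats <- if (is.null(mtry)) seq_len(ncol(X)) else sample.int(ncol(X), mtry)
    best <- cart_best_split(X, yi, idx, feats, K)
    if (is.null(best)) {
      nodes[[id]] <<- leaf
      return(id)
    }
    nodes[[id]] <<- list(leaf = FALSE, feat = best$feat, cut = best$cut,
                         class = which.max(cnt), n = length(idx))
    go_left <- X[idx, best$feat] <= best$cut
    left <- grow(idx[go_left], depth + 1L)
    right <- grow(idx[!go_left], depth + 1L)
    nodes[[id]]$left <<- left
    nodes[[id]]$right <<- right
    id
  }
  root <- grow(seq_along(yi), 0L)
  list(nodes = nodes, root = root, levels = levels(y))
}

# vectorised exhaustive search for the Gini-minimising axis-aligned split
cart_best_split <- function(X, yi, idx, feats, K) {
  n <- length(idx)
  cnt <- tabulate(yi[idx], K)
  parent_gini <- 1 - sum((cnt / n)^2)
  best <- NULL; best_gain <- 1e-12
  for (f in feats) {
    x <- X[idx, f]
    ord <- order(x, method = "radix")
    xs <- x[ord]; ys <- yi[idx][ord]
    if (xs[1] == xs[n]) next
    # cumulative class counts at every prefix
    cum <- matrix(0L, n, K)
    for (k in seq_len(K)) cum[, k] <- cumsum(ys == k)
    valid <- which(xs[-n] < xs[-1])        # split between distinct values only
    if (!length(valid)) next
    nl <- valid
    nr <- n - nl
    gl <- 1 - rowSums((cum[valid, , drop = FALSE] / nl)^2)
    cr <- matrix(cnt, length(valid), K, byrow = TRUE) - cum[valid, , drop = FALSE]
    gr <- 1 - rowSums((cr / nr)^2)
    gain <- parent_gini - (nl * gl + nr * gr) / n
    w <- which.max(gain)
    if (gain[w] > best_gain) {
      best_gain <- gain[w]
      best <- list(feat = f, cut = (xs[valid[w]] + xs[valid[w] + 1L]) / 2)
    }
  }
  best
}

cart_predict <- function(tree, X) {
  stopifnot(is.matrix(X))
  out <- integer(nrow(X))
  route <- function(id, idx) {
    nd <- tree$nodes[[id]]
    if (nd$leaf) {
      out[idx] <<- nd$class
      return(invisible())
    }
    go_left <- X[idx, nd$feat] <= nd$cut
    if (any(go_left)) route(nd$left, idx[go_left])
    if (any(!go_left)) route(nd$right, idx[!go_left])
  }
  route(tree$root, seq_len(nrow(X)))
  factor(tree$levels[out], levels = tree$levels)
}
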