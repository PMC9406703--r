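#' Gini impurity of a class-count vector
#'
#' `1 - sum((n_c / n)^2)`; the node-purity criterion used for decision
#' splits. For two classes it lies in `[0, 0.5]`.
#'
#' @param counts nonnegative integer counts per class; total must be > 0.
#' @return Impurity value.
#' @examples
#' gini(c(5, 0))   # pure node
#' gini(c(4, 4))   # maximal two-class impurity
#' @export
gini <- function(counts) {
  n <- sum(counts)
  if (n <= 0) stop("gini: total count must be positive")
  1 - sum((counts / n)^2)
}

#' Forest hyperparameters
#'
#' @param n_trees number of trees in the ensemble.
#' @param m_try features drawn (uniformly, without replacement) at every
#'   split; default `floor(sqrt(37)) = 6`, the standard Random Forest
#'   heuristic for this feature dimensionality.
#' @param min_samples_split smallest node that may still be split.
#' @param max_depth maximum tree depth; `0` means unlimited.
#' @return A list of class `forest_params`.
#' @export
forest_params <- function(n_trees = 1000L, m_try = 6L,
                          min_samples_split = 2L, max_depth = 0L) {
  stopifnot(n_trees >= 1, m_try >= 1, m_try <= 37,
            min_samples_split >= 2, max_depth >= 0)
  structure(list(n_trees = as.integer(n_trees), m_try = as.integer(m_try),
                 min_samples_split = as.integer(min_samples_split),
                 max_depth = as.integer(max_depth)),
            class = "forest_params")
}

#' Best Gini split over candidate features
#'
#' Scans every candidate feature; thresholds are the midpoints between
#' consecutive distinct sorted values. Returns the split maximising the
#' weighted impurity decrease, or `NULL` if no split yields positive gain.
#' Ties are broken by lowest feature index, then lowest threshold, so the
#' result is fully deterministic.
#'
#' @param X numeric matrix (samples x features).
#' @param y class labels (character or factor over [cyst_classes()]).
#' @param candidate_features column indices to consider.
#' @return `list(feature, threshold, gain)` or `NULL`.
#' @export
best_split <- function(X, y, candidate_features = seq_len(ncol(X))) {
  n <- nrow(X)
  stopifnot(n >= 2, length(candidate_features) >= 1)
  y1 <- y == cyst_classes()[1]
  n1 <- sum(y1)
  parent <- gini(c(n1, n - n1))
  if (parent == 0) return(NULL)
  best <- NULL
  for (j in sort(candidate_features)) {
    xf <- X[, j]
    ord <- order(xf)
    xs <- xf[ord]
    cum1 <- cumsum(y1[ord])
    i <- which(xs[-n] < xs[-1])          # valid cut positions
    if (length(i) == 0) next
    nl <- i; nr <- n - i
    l1 <- cum1[i]; r1 <- n1 - l1
    gl <- 1 - ((l1 / nl)^2 + ((nl - l1) / nl)^2)
    gr <- 1 - ((r1 / nr)^2 + ((nr - r1) / nr)^2)
    gain <- parent - (nl / n) * gl - (nr / n) * gr
    k <- which.max(gain)                 # first max -> lowest threshold
    if (gain[k] > 1e-12 &&
        (is.null(best) || gain[k] > best$gain + 1e-12)) {
      best <- list(feature = j,
                   threshold = (xs[i[k]] + xs[i[k] + 1]) / 2,
                   gain = gain[k])
    }
  }
  best
}

# Recursive CART builder. m_try features are redrawn at every split; when
# m_try >= ncol(X) this is exhaustive greedy CART.
build_tree <- function(X, y, params, depth = 0L) {
  classes <- cyst_classes()
  counts <- c(sum(y == classes[1]), sum(y == classes[2]))
  names(counts) <- classes
  leaf <- list(type = "leaf", counts = counts)
  n <- nrow(X)
  if (counts[1] == 0 || counts[2] == 0) return(leaf)
  if (n < params$min_samples_split) return(leaf)
  if (params$max_depth > 0 && depth >= params$max_depth) return(leaf)
  m <- min(params$m_try, ncol(X))
  cand <- if (m < ncol(X)) sample.int(ncol(X), m) else seq_len(ncol(X))
  sp <- best_split(X, y, cand)
  if (is.null(sp)) return(leaf)
  left <- X[, sp$feature] <= sp$threshold
  list(type = "split", feature = sp$feature, threshold = sp$threshold,
       left = build_tree(X[left, , drop = FALSE], y[left], params, depth + 1L),
       right = build_tree(X[!left, , drop = FALSE], y[!left], params, depth + 1L))
}

#' Fit a Random Forest of Gini-split trees
#'
#' Bagging: each tree is grown on a bootstrap resample of size `n` (drawn
#' with replacement), with `m_try` features sampled uniformly without
#' replacement at every split. Fully deterministic under a fixed seed.
#'
#' @param X numeric matrix (samples x features), typically 37 overlap
#'   shares from [feature_matrix()].
#' @param y class labels over [cyst_classes()]; both classes must occur.
#' @param params a [forest_params()].
#' @param seed integer RNG seed.
#' @return A `cyst_forest` model.
#' @export
fit_forest <- function(X, y, params = forest_params(), seed = 1L) {
  X <- as.matrix(X)
  y <- as.character(y)
  stopifnot(nrow(X) >= 2, nrow(X) == length(y))
  if (length(unique(y)) < 2) {
    stop("fit_forest: both classes must be present in y")
  }
  if (!all(y %in% cyst_classes())) {
    stop("fit_forest: labels must be among: ",
         paste(cyst_classes(), collapse = ", "))
  }
  n <- nrow(X)
  trees <- with_seed(seed, {
    lapply(seq_len(params$n_trees), function(t) {
      idx <- sample.int(n, n, replace = TRUE)
      build_tree(X[idx, , drop = FALSE], y[idx], params)
    })
  })
  structure(list(trees = trees, params = params, seed = as.integer(seed),
                 n_features = ncol(X), classes = cyst_classes(),
                 feature_names = colnames(X)),
            class = "cyst_forest")
}

#' @export
print.cyst_forest <- function(x, ...) {
  cat(sprintf("<cyst_forest: %d trees, m_try=%d, %d features, seed=%d>\n",
              length(x$trees), x$params$m_try, x$n_features, x$seed))
  invisible(x)
}

# Vectorised single-tree prediction: returns TRUE where the tree votes the
# first class (odontogenic).
predict_tree <- function(node, X) {
  if (node$type == "leaf") {
    # leaf ties go to the first class (odontogenic)
    vote <- node$counts[1] >= node$counts[2]
    return(rep(vote, nrow(X)))
  }
  out <- logical(nrow(X))
  left <- X[, node$feature] <= node$threshold
  if (any(left)) out[left] <- predict_tree(node$left, X[left, , drop = FALSE])
  if (any(!left)) out[!left] <- predict_tree(node$right, X[!left, , drop = FALSE])
  out
}

#' Predict cyst classes with a fitted forest
#'
#' Majority vote over the trees; an exactly tied vote goes to the
#' odontogenic class (the majority class in clinical samples).
#'
#' @param object a `cyst_forest`.
#' @param X numeric matrix with the model's feature dimensionality.
#' @param ... unused.
#' @return `data.frame(label, vote_odontogenic)` where `vote_odontogenic`
#'   is the fraction of trees voting odontogenic.
#' @export
predict.cyst_forest <- function(object, X, ...) {
  X <- as.matrix(X)
  if (ncol(X) != object$n_features) {
    stop("predict: X has ", ncol(X), " features; model expects ",
         object$n_features)
  }
  votes <- rowMeans(matrix(vapply(object$trees,
                                  function(tr) predict_tree(tr, X),
                                  logical(nrow(X))),
                           nrow = nrow(X)))
  label <- ifelse(votes >= 0.5, object$classes[1], object$classes[2])
  data.frame(label = label, vote_odontogenic = votes,
             stringsAsFactors = FALSE)
}

#' Stratified 80/20 train-test split
#'
#' Splits sample indices into 80% training and 20% test, stratified by
#' class so both partitions keep the class mix; the training size is
#' `round(0.8 n)` overall. Falls back to an unstratified split (with a
#' warning) when some class has fewer than 2 members.
#'
#' @param y class labels.
#' @param seed integer RNG seed.
#' @param train_frac training fraction.
#' @return `list(train, test)` of disjoint, exhaustive index vectors.
#' @export
split_80_20 <- function(y, seed = 1L, train_frac = 0.8) {
  n <- length(y)
  stopifnot(n >= 5)
  with_seed(seed, {
    tab <- table(y)
    if (any(tab < 2)) {
      warning("split_80_20: class with < 2 members; unstratified split")
      train <- sort(sample.int(n, round(train_frac * n)))
      return(list(train = train, test = setdiff(seq_len(n), train)))
    }
    target <- round(train_frac * n)
    per_class <- round(train_frac * tab)
    # reconcile rounding so the overall training size is exact
    drift <- target - sum(per_class)
    if (drift != 0) {
      big <- which.max(tab)
      per_class[big] <- per_class[big] + drift
    }
    train <- integer(0)
    for (cl in names(tab)) {
      idx <- which(y == cl)
      train <- c(train, sample(idx, per_class[[cl]]))
    }
    train <- sort(train)
    list(train = train, test = setdiff(seq_len(n), train))
  })
}

#' Grid search over forest hyperparameters
#'
#' Evaluates every cell of the grid by k-fold cross-validated macro-F1
#' (folds assigned deterministically from the seed and shared across
#' cells). A fold whose training part contains a single class is skipped
#' with a warning. Ties go to the first cell in grid order.
#'
#' @param X,y training data.
#' @param grid list of [forest_params()].
#' @param k number of folds.
#' @param seed integer RNG seed.
#' @return `list(best, scores)` where `scores` is a per-cell data frame.
#' @export
grid_search <- function(X, y, grid = default_forest_grid(), k = 5L, seed = 1L) {
  stopifnot(length(grid) >= 1, k >= 2)
  X <- as.matrix(X)
  y <- as.character(y)
  n <- nrow(X)
  folds <- with_seed(seed, sample(rep_len(seq_len(k), n)))
  cell_seeds <- derive_seeds(seed + 1L, length(grid) * k)
  scores <- numeric(length(grid))
  rows <- list()
  for (g in seq_along(grid)) {
    fold_scores <- rep(NA_real_, k)
    for (f in seq_len(k)) {
      tr <- folds != f
      if (length(unique(y[tr])) < 2 || length(unique(y[!tr])) < 1) {
        warning("grid_search: fold ", f, " skipped (single class)")
        next
      }
      model <- fit_forest(X[tr, , drop = FALSE], y[tr], grid[[g]],
                          seed = cell_seeds[(g - 1L) * k + f])
      pred <- predict(model, X[!tr, , drop = FALSE])$label
      fold_scores[f] <- macro_f1(y[!tr], pred)
    }
    scores[g] <- mean(fold_scores, na.rm = TRUE)
    p <- grid[[g]]
    rows[[g]] <- data.frame(cell = g, n_trees = p$n_trees, m_try = p$m_try,
                            min_samples_split = p$min_samples_split,
                            max_depth = p$max_depth, macro_f1 = scores[g])
  }
  best <- which(scores >= max(scores) - 1e-12)[1]
  list(best = grid[[best]], best_cell = best, scores = do.call(rbind, rows))
}

#' @rdname grid_search
#' @export
default_forest_grid <- function() {
  cells <- expand.grid(n_trees = c(100L, 500L, 1000L),
                       m_try = c(3L, 6L, 12L),
                       min_samples_split = c(2L, 5L))
  lapply(seq_len(nrow(cells)), function(i) {
    forest_params(cells$n_trees[i], cells$m_try[i], cells$min_samples_split[i])
  })
}

# Macro-averaged F1 over the two cyst classes; undefined per-class F1
# (no predictions and no truths of that class) is treated as 0 within CV.
macro_f1 <- function(truth, pred) {
  f1s <- vapply(cyst_classes(), function(cl) {
    tp <- sum(truth == cl & pred == cl)
    fp <- sum(truth != cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    if (2 * tp + fp + fn == 0) return(0)
    2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  mean(f1s)
}

#' Serialize / load a forest model as versioned JSON
#'
#' `load_forest(save_forest(m))` gives a model with identical predictions
#' on any input.
#'
#' @param model a `cyst_forest`.
#' @param path JSON file path.
#' @return `save_forest` returns `path` invisibly; `load_forest` a
#'   `cyst_forest`.
#' @export
save_forest <- function(model, path) {
  obj <- list(format = "cystdx_forest", version = 1L,
              params = unclass(model$params), seed = model$seed,
              n_features = model$n_features, classes = model$classes,
              feature_names = model$feature_names,
              trees = model$trees)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_forest
#' @export
load_forest <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$format, "cystdx_forest")) {
    stop("load_forest: not a cystdx forest file")
  }
  fix_node <- function(nd) {
    if (nd$type == "leaf") {
      counts <- unlist(nd$counts)
      return(list(type = "leaf", counts = counts))
    }
    list(type = "split", feature = as.integer(nd$feature),
         threshold = as.numeric(nd$threshold),
         left = fix_node(nd$left), right = fix_node(nd$right))
  }
  p <- obj$params
  structure(list(trees = lapply(obj$trees, fix_node),
                 params = forest_params(p$n_trees, p$m_try,
                                        p$min_samples_split, p$max_depth),
                 seed = as.integer(obj$seed),
                 n_features = as.integer(obj$n_features),
                 classes = unlist(obj$classes),
                 feature_names = unlist(obj$feature_names)),
            class = "cyst_forest")
}

#' Permutation importance of feature groups
#'
#' Accuracy drop on held-out data when a group of feature columns is
#' jointly permuted (destroying their association with the label while
#' keeping their marginal distribution).
#'
#' @param model a `cyst_forest`.
#' @param X,y held-out data.
#' @param columns indices of the feature group to permute.
#' @param seed integer RNG seed.
#' @return `list(baseline, permuted, drop)` accuracies.
#' @export
permutation_importance <- function(model, X, y, columns, seed = 1L) {
  X <- as.matrix(X)
  y <- as.character(y)
  baseline <- mean(predict(model, X)$label == y)
  Xp <- X
  perm <- with_seed(seed, sample.int(nrow(X)))
  Xp[, columns] <- X[perm, columns]
  permuted <- mean(predict(model, Xp)$label == y)
  list(baseline = baseline, permuted = permuted, drop = baseline - permuted)
}
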