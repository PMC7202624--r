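# Trainable pixel classification: instances from sparse labels, random
# undersampling, correlation-based feature selection (CFS),
# information-gain-ratio ranking, random forest, ROC evaluation.

#' Collect labelled training instances from a feature stack
#'
#' One instance per labelled pixel (1 = elastin, 2 = background);
#' unlabelled pixels (0) are ignored.
#'
#' @param stack a `feature_stack` from [compute_features].
#' @param labels integer label matrix of the same image dimensions.
#' @return a `training_set`: list with `x` (instance x feature matrix),
#'   `y` (factor, levels background/elastin) and `provenance`
#'   (data frame of pixel coordinates).
#' @export
collect_instances <- function(stack, labels) {
  stopifnot(inherits(stack, "feature_stack"))
  if (!identical(dim(labels), stack$dim))
    stop("labels dimensions must match the image")
  idx <- which(labels != 0)
  if (length(idx) == 0) stop("no labelled pixels")
  lab <- labels[idx]
  if (length(unique(lab)) < 2)
    stop("labels must contain both classes (elastin and background)")
  nr <- stack$dim[1]
  structure(
    list(x = stack$values[idx, , drop = FALSE],
         y = factor(ifelse(lab == 1, "elastin", "background"),
                    levels = c("background", "elastin")),
         provenance = data.frame(row = (idx - 1L) %% nr + 1L,
                                 col = (idx - 1L) %/% nr + 1L)),
    class = "training_set")
}

# build a training_set directly from components (used by tests/simulations)
training_set <- function(x, y, provenance = NULL) {
  y <- factor(y, levels = c("background", "elastin"))
  if (is.null(provenance))
    provenance <- data.frame(row = NA_integer_, col = NA_integer_)[rep(1, nrow(x)), ]
  structure(list(x = x, y = y, provenance = provenance),
            class = "training_set")
}

#' Rebalance classes by random undersampling
#'
#' The majority class is randomly subsampled without replacement down to
#' the minority class size; the minority class is untouched.
#'
#' @param ts a `training_set`.
#' @param seed RNG seed.
#' @return a balanced `training_set`.
#' @export
undersample <- function(ts, seed = 1) {
  stopifnot(inherits(ts, "training_set"))
  counts <- table(ts$y)
  if (any(counts == 0)) stop("both classes must be present")
  if (counts[1] == counts[2]) return(ts)
  minority <- names(counts)[which.min(counts)]
  majority <- names(counts)[which.max(counts)]
  keep_min <- which(ts$y == minority)
  idx_maj <- which(ts$y == majority)
  keep_maj <- with_seed(seed, sort(sample(idx_maj, min(counts))))
  keep <- sort(c(keep_min, keep_maj))
  training_set(ts$x[keep, , drop = FALSE], ts$y[keep],
               ts$provenance[keep, , drop = FALSE])
}

# ---- discretization and information measures ---------------------------
# Continuous features are discretized by equal-frequency binning (10 bins
# by default) for both CFS and gain-ratio ranking.

discretize_ef <- function(x, bins = 10) {
  qs <- unique(quantile(x, probs = seq(0, 1, length.out = bins + 1),
                        names = FALSE, type = 7))
  if (length(qs) < 2) return(rep(1L, length(x)))
  cut(x, breaks = qs, include.lowest = TRUE, labels = FALSE)
}

entropy_counts <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p))
}

entropy_disc <- function(x) entropy_counts(tabulate(x))

joint_entropy_disc <- function(x, y) {
  ny <- max(y)
  entropy_counts(tabulate((x - 1L) * ny + y))
}

# symmetrical uncertainty of two discretized variables
symmetrical_uncertainty <- function(x, y) {
  hx <- entropy_disc(x); hy <- entropy_disc(y)
  if (hx + hy == 0) return(0)
  hxy <- joint_entropy_disc(x, y)
  2 * (hx + hy - hxy) / (hx + hy)
}

cfs_merit <- function(k, mean_rcf, mean_rff) {
  denom <- sqrt(k + k * (k - 1) * mean_rff)
  if (denom == 0) return(0)
  k * mean_rcf / denom
}

#' Correlation-based feature selection (CFS)
#'
#' Greedy forward best-first search over feature subsets maximizing the
#' CFS merit \eqn{k \bar r_{cf} / \sqrt{k + k(k-1) \bar r_{ff}}}, where
#' \eqn{\bar r_{cf}} is the mean feature-class correlation and
#' \eqn{\bar r_{ff}} the mean feature-feature correlation, both measured
#' as symmetrical uncertainty on equal-frequency discretized features.
#' Redundant duplicates of informative features are thereby penalized.
#'
#' @param ts a `training_set`.
#' @param bins discretization bins (equal frequency).
#' @return character vector of selected feature names (non-empty), with
#'   the achieved merit as attribute `merit`.
#' @export
select_features_cfs <- function(ts, bins = 10) {
  stopifnot(inherits(ts, "training_set"))
  d <- ncol(ts$x)
  if (d < 2) stop("need at least 2 features")
  nms <- colnames(ts$x) %||% paste0("f", seq_len(d))
  disc <- lapply(seq_len(d), function(j) discretize_ef(ts$x[, j], bins))
  cls <- as.integer(ts$y)
  const <- vapply(disc, function(z) entropy_disc(z) == 0, logical(1))
  if (any(const))
    warning("excluding constant feature(s): ",
            paste(nms[const], collapse = ", "))
  cand <- which(!const)
  if (!length(cand)) stop("all features are constant")
  rcf <- vapply(cand, function(j) symmetrical_uncertainty(disc[[j]], cls),
                numeric(1))
  rff <- matrix(NA_real_, d, d)
  get_rff <- function(a, b) {
    if (is.na(rff[a, b])) {
      v <- symmetrical_uncertainty(disc[[a]], disc[[b]])
      rff[a, b] <<- v; rff[b, a] <<- v
    }
    rff[a, b]
  }
  selected <- integer(0)
  best_merit <- -Inf
  repeat {
    pool <- setdiff(cand, selected)
    if (!length(pool)) break
    merits <- vapply(pool, function(j) {
      sub <- c(selected, j)
      k <- length(sub)
      mrcf <- mean(rcf[match(sub, cand)])
      mrff <- if (k < 2) 0 else {
        pairs <- utils::combn(sub, 2)
        mean(vapply(seq_len(ncol(pairs)),
                    function(t) get_rff(pairs[1, t], pairs[2, t]),
                    numeric(1)))
      }
      cfs_merit(k, mrcf, mrff)
    }, numeric(1))
    j_best <- pool[which.max(merits)]
    if (max(merits) <= best_merit + 1e-10) break
    best_merit <- max(merits)
    selected <- c(selected, j_best)
  }
  structure(nms[selected], merit = best_merit)
}

#' Rank features by information gain ratio
#'
#' Gain ratio = (H(class) - H(class | feature)) / H(feature), with
#' equal-frequency discretization of continuous features. A feature with
#' zero entropy (constant) has gain ratio 0 by convention.
#'
#' @param ts a `training_set`.
#' @param bins discretization bins.
#' @return data frame (`feature`, `gain_ratio`) in descending order.
#' @export
rank_information_gain_ratio <- function(ts, bins = 10) {
  stopifnot(inherits(ts, "training_set"))
  nms <- colnames(ts$x) %||% paste0("f", seq_len(ncol(ts$x)))
  cls <- as.integer(ts$y)
  h_class <- entropy_disc(cls)
  gr <- vapply(seq_len(ncol(ts$x)), function(j) {
    z <- discretize_ef(ts$x[, j], bins)
    hz <- entropy_disc(z)
    if (hz == 0) return(0)
    # H(class | feature) = H(class, feature) - H(feature)
    h_cond <- joint_entropy_disc(z, cls) - hz
    (h_class - h_cond) / hz
  }, numeric(1))
  out <- data.frame(feature = nms, gain_ratio = gr)
  out[order(-out$gain_ratio), , drop = FALSE]
}

#' Train a random forest pixel classifier
#'
#' Bagged CART trees with per-node random feature subsetting
#' (`mtry = floor(sqrt(d))` by default), Gini impurity, grown to purity.
#' 200 trees by default.
#'
#' @param ts a (rebalanced) `training_set`.
#' @param n_trees number of trees, >= 1.
#' @param seed RNG seed; same seed, same forest.
#' @param selected_features optional character vector restricting the
#'   model to a feature subset (e.g. from [select_features_cfs]).
#' @param mtry features tried per node; default `floor(sqrt(d))`.
#' @param min_node minimum node size before splitting stops.
#' @param max_depth depth cap.
#' @param decision_threshold probability cutoff used by [predict_mask].
#' @return an `elastin_classifier` model object.
#' @export
train_forest <- function(ts, n_trees = 200, seed = 1,
                         selected_features = NULL, mtry = NULL,
                         min_node = 1, max_depth = 50,
                         decision_threshold = 0.5) {
  stopifnot(inherits(ts, "training_set"))
  if (!is.numeric(n_trees) || n_trees < 1) stop("n_trees must be >= 1")
  x <- ts$x
  nms <- colnames(x) %||% paste0("f", seq_len(ncol(x)))
  colnames(x) <- nms
  if (!is.null(selected_features)) {
    missing <- setdiff(selected_features, nms)
    if (length(missing))
      stop("unknown selected features: ", paste(missing, collapse = ", "))
    x <- x[, selected_features, drop = FALSE]
  }
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(x))))
  y <- as.integer(ts$y == "elastin")
  trees <- with_seed(seed,
    cpp_rf_train(x, y, as.integer(n_trees), as.integer(mtry),
                 as.integer(min_node), as.integer(max_depth)))
  structure(
    list(trees = trees, feature_names = colnames(x),
         selected_features = selected_features %||% nms,
         n_trees = as.integer(n_trees), training_seed = as.integer(seed),
         decision_threshold = decision_threshold,
         bank_version = 1L),
    class = "elastin_classifier")
}

#' @export
print.elastin_classifier <- function(x, ...) {
  cat(sprintf("elastin_classifier: %d trees, %d features, threshold %.2f\n",
              x$n_trees, length(x$feature_names), x$decision_threshold))
  invisible(x)
}

# predicted elastin probability for a feature matrix or stack
predict_prob <- function(model, newdata) {
  x <- if (inherits(newdata, "feature_stack")) newdata$values else newdata
  missing <- setdiff(model$feature_names, colnames(x))
  if (length(missing))
    stop("feature stack is missing model features: ",
         paste(missing, collapse = ", "))
  cpp_rf_predict(model$trees, x[, model$feature_names, drop = FALSE])
}

#' Segmentation mask container
#'
#' @param mask logical matrix (TRUE = elastin foreground).
#' @param spacing_um micrometres per pixel.
#' @param fov_mask logical FOV matrix; foreground outside it is invalid.
#' @return a `segmentation_mask`.
#' @export
segmentation_mask <- function(mask, spacing_um, fov_mask = NULL) {
  mask <- mask != 0
  if (is.null(fov_mask)) fov_mask <- inscribed_disk_mask(nrow(mask), ncol(mask))
  if (any(mask & !fov_mask))
    stop("foreground must lie inside the FOV")
  if (spacing_um <= 0) stop("spacing_um must be > 0")
  structure(list(mask = mask, spacing_um = spacing_um, fov_mask = fov_mask),
            class = "segmentation_mask")
}

#' @export
print.segmentation_mask <- function(x, ...) {
  cat(sprintf("segmentation_mask: %d x %d px, %.4g um/px, %d fg px\n",
              nrow(x$mask), ncol(x$mask), x$spacing_um, sum(x$mask)))
  invisible(x)
}

#' Predict a binary elastin mask from a feature stack
#'
#' Per-pixel elastin probability thresholded at the model's decision
#' threshold (probability >= threshold is elastin); pixels outside the
#' FOV are forced to background.
#'
#' @param model an `elastin_classifier`.
#' @param stack a `feature_stack` of the image to segment.
#' @param threshold optional override of the model's decision threshold.
#' @return a [segmentation_mask].
#' @export
predict_mask <- function(model, stack, threshold = NULL) {
  stopifnot(inherits(model, "elastin_classifier"),
            inherits(stack, "feature_stack"))
  thr <- threshold %||% model$decision_threshold
  p <- predict_prob(model, stack)
  m <- matrix(p >= thr, stack$dim[1], stack$dim[2])
  m[!matrix(stack$fov, stack$dim[1], stack$dim[2])] <- FALSE
  segmentation_mask(m, stack$spacing_um,
                    fov_mask = matrix(stack$fov, stack$dim[1], stack$dim[2]))
}

#' ROC area under the curve on a held-out test set
#'
#' AUC by the rank statistic over predicted elastin probabilities
#' (midranks for ties); equals the Mann-Whitney U statistic divided by
#' n1 * n2.
#'
#' @param model an `elastin_classifier`.
#' @param test a `training_set` disjoint from the training instances,
#'   containing both classes.
#' @return AUC in [0, 1].
#' @export
evaluate_roc <- function(model, test) {
  stopifnot(inherits(test, "training_set"))
  if (length(unique(test$y)) < 2)
    stop("test set must contain both classes")
  scores <- predict_prob(model, test$x)
  auc_rank(scores, test$y == "elastin")
}

# rank-based AUC (midranks for ties)
auc_rank <- function(scores, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  r <- rank(scores)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Save / load a trained classifier
#'
#' The archive records forest parameters, the selected feature names and
#' the feature-bank version; loading refuses a model built against an
#' incompatible bank.
#'
#' @param model an `elastin_classifier`.
#' @param path file path (`.rds`).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "elastin_classifier"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "elastin_classifier"))
    stop("not an elastin_classifier archive")
  if (!identical(model$bank_version, 1L))
    stop("model was built against an incompatible feature bank version: ",
         model$bank_version)
  model
}
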