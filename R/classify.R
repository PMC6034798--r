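#' Gradient-boosted classifier configuration
#'
#' Hyperparameters and validation design for [cross_validate()]:
#' conventional gradient-boosting defaults for a ~100-subject cohort
#' (200 trees, learning rate 0.05, depth 3, subsample 0.8) and a
#' stratified 5-fold cross-validation repeated 10 times.
#'
#' @param n_trees boosting rounds.
#' @param learning_rate shrinkage (> 0).
#' @param max_depth tree depth.
#' @param subsample row subsample fraction per tree.
#' @param cv_folds folds (>= 2).
#' @param cv_repeats repeats (>= 1).
#' @param threshold_rule `"youden"` (maximize sensitivity + specificity
#'   - 1 on the out-of-fold ROC) or `"fixed"`.
#' @param fixed_threshold operating threshold when `threshold_rule =
#'   "fixed"`.
#' @param seed integer seed controlling fold assignment and tree fitting.
#' @return a list of class `acg_classifier_config`.
#' @export
classifier_config <- function(n_trees = 200, learning_rate = 0.05,
                              max_depth = 3, subsample = 0.8,
                              cv_folds = 5, cv_repeats = 10,
                              threshold_rule = c("youden", "fixed"),
                              fixed_threshold = 0.5, seed = 1L) {
  stopifnot(cv_folds >= 2, cv_repeats >= 1, learning_rate > 0)
  structure(
    list(n_trees = n_trees, learning_rate = learning_rate,
         max_depth = max_depth, subsample = subsample,
         cv_folds = cv_folds, cv_repeats = cv_repeats,
         threshold_rule = match.arg(threshold_rule),
         fixed_threshold = fixed_threshold, seed = as.integer(seed)),
    class = "acg_classifier_config"
  )
}

#' Z-score normalization with externally supplied statistics
#'
#' Standardizes every numeric column. When `center`/`scale` are `NULL`
#' they are computed from `data` itself (the training fold); pass the
#' attributes of a normalized training table to transform a held-out
#' fold with the training statistics only — test-fold statistics never
#' enter the transform. Constant columns (zero SD) are mapped to zeros
#' with a warning.
#'
#' @param data a data frame; non-numeric columns pass through untouched.
#' @param center,scale named numerics from a previous call, or `NULL`.
#' @return the normalized tibble with attributes `center` and `scale`.
#' @export
normalize_features <- function(data, center = NULL, scale = NULL) {
  num <- names(data)[vapply(data, is.numeric, logical(1))]
  if (is.null(center)) {
    center <- vapply(data[num], mean, numeric(1))
    scale <- vapply(data[num], stats::sd, numeric(1))
    if (any(scale == 0 | is.na(scale))) {
      warning("constant feature(s) mapped to zero: ",
              paste(num[scale == 0 | is.na(scale)], collapse = ", "),
              call. = FALSE)
    }
    scale[scale == 0 | is.na(scale)] <- 1
  }
  out <- tibble::as_tibble(data)
  for (v in num) out[[v]] <- (out[[v]] - center[[v]]) / scale[[v]]
  attr(out, "center") <- center
  attr(out, "scale") <- scale
  out
}

#' Empirical ROC curve and AUC from scores
#'
#' Sweeps the unique score values as thresholds, computing (FPR, TPR)
#' from the highest score down; the AUC is the trapezoidal area, which
#' gives tied scores half credit and therefore equals the
#' concordant-pair (Mann-Whitney) definition.
#'
#' @param scores numeric classifier scores, higher = more positive.
#' @param labels 0/1 (or logical/two-level factor) true classes.
#' @return an object of class `acg_roc`: list with `roc` (tibble
#'   `threshold`, `fpr`, `tpr`), `auc`, `scores` tibble.
#' @export
roc_curve <- function(scores, labels) {
  y <- as_binary_labels(labels)
  if (length(unique(y)) < 2) {
    stop("validation error: both classes required", call. = FALSE)
  }
  n_pos <- sum(y == 1)
  n_neg <- sum(y == 0)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  yy <- y[ord]
  # group tied scores into single threshold steps
  grp <- cumsum(!duplicated(s))
  tp <- unname(tapply(yy == 1, grp, sum))
  fp <- unname(tapply(yy == 0, grp, sum))
  tpr <- c(0, cumsum(tp) / n_pos)
  fpr <- c(0, cumsum(fp) / n_neg)
  thr <- c(Inf, unique(s))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(
    list(
      roc = tibble::tibble(threshold = thr, fpr = fpr, tpr = tpr),
      auc = auc,
      scores = tibble::tibble(score = scores, label = y)
    ),
    class = "acg_roc"
  )
}

as_binary_labels <- function(labels) {
  if (is.logical(labels)) return(as.integer(labels))
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) {
    lev <- sort(unique(labels))
    if (length(lev) > 2) stop("labels must have two levels", call. = FALSE)
    # "hypertension" is the positive class in cohort tables
    pos <- if ("hypertension" %in% lev) "hypertension" else lev[length(lev)]
    return(as.integer(labels == pos))
  }
  if (!all(labels %in% c(0, 1))) {
    stop("numeric labels must be 0/1", call. = FALSE)
  }
  as.integer(labels)
}

# stratified fold assignment: shuffles within class, deals into folds
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    idx <- sample(idx)
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Repeated stratified cross-validation of the gradient-boosted classifier
#'
#' Trains a gradient-boosted tree model (xgboost, logistic objective) on
#' z-scored features inside each training fold — held-out folds are
#' transformed with the training fold's statistics only — under
#' stratified k-fold cross-validation repeated `cv_repeats` times.
#' Out-of-fold scores are averaged per subject across repeats; the ROC,
#' AUC and the operating point (Youden's J by default) are computed from
#' those averaged scores.
#'
#' @param features data frame of numeric features, one row per subject
#'   (exam-aggregated; non-numeric columns and `subject_id`/`group` are
#'   dropped with a message).
#' @param labels true classes (see [roc_curve()]).
#' @param config an [classifier_config()].
#' @return an `acg_roc` with additional elements `sensitivity`,
#'   `specificity`, `threshold`, `config`, and per-subject `scores`.
#' @export
cross_validate <- function(features, labels, config = classifier_config()) {
  y <- as_binary_labels(labels)
  if (length(unique(y)) < 2) {
    stop("validation error: both classes required", call. = FALSE)
  }
  if (min(table(y)) < config$cv_folds) {
    stop("each class needs at least `cv_folds` subjects", call. = FALSE)
  }
  drop_cols <- names(features)[!vapply(features, is.numeric, logical(1))]
  drop_cols <- union(drop_cols, intersect(names(features), "subject_id"))
  if (length(drop_cols) > 0) {
    features <- features[setdiff(names(features), drop_cols)]
  }
  x_all <- as.matrix(features)
  n <- nrow(x_all)
  score_sum <- numeric(n)
  withr::with_seed(config$seed, {
    for (rep_i in seq_len(config$cv_repeats)) {
      fold <- stratified_folds(y, config$cv_folds)
      for (f in seq_len(config$cv_folds)) {
        tr <- fold != f
        tr_norm <- normalize_features(as.data.frame(x_all[tr, , drop = FALSE]))
        te_norm <- normalize_features(
          as.data.frame(x_all[!tr, , drop = FALSE]),
          center = attr(tr_norm, "center"),
          scale = attr(tr_norm, "scale")
        )
        booster <- xgboost::xgboost(
          x = as.matrix(tr_norm), y = factor(y[tr], levels = c(0, 1)),
          objective = "binary:logistic",
          nrounds = config$n_trees,
          learning_rate = config$learning_rate,
          max_depth = config$max_depth,
          subsample = config$subsample,
          nthreads = 1,
          seed = config$seed + rep_i,
          verbosity = 0
        )
        score_sum[!tr] <- score_sum[!tr] +
          stats::predict(booster, as.matrix(te_norm))
      }
    }
  })
  scores <- score_sum / config$cv_repeats
  out <- roc_curve(scores, y)
  if (!is.null(rownames(features))) {
    out$scores$subject_id <- rownames(features)
  }
  op <- operating_point(out, config)
  out$sensitivity <- op$sensitivity
  out$specificity <- op$specificity
  out$threshold <- op$threshold
  out$config <- config
  out
}

operating_point <- function(roc_obj, config) {
  roc <- roc_obj$roc
  if (config$threshold_rule == "youden") {
    j <- roc$tpr - roc$fpr
    i <- which.max(j)
    list(threshold = roc$threshold[i], sensitivity = roc$tpr[i],
         specificity = 1 - roc$fpr[i])
  } else {
    s <- roc_obj$scores
    pred <- s$score >= config$fixed_threshold
    list(
      threshold = config$fixed_threshold,
      sensitivity = mean(pred[s$label == 1]),
      specificity = mean(!pred[s$label == 0])
    )
  }
}

#' @export
print.acg_roc <- function(x, ...) {
  cat(sprintf("<acg_roc> AUC = %.3f", x$auc))
  if (!is.null(x$sensitivity)) {
    cat(sprintf(" (sensitivity %.3f, specificity %.3f)",
                x$sensitivity, x$specificity))
  }
  cat("\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the ROC points of a classifier result
#' @param x an `acg_roc`.
#' @param ... unused.
#' @return a tibble with `threshold`, `fpr`, `tpr`.
#' @export
tidy.acg_roc <- function(x, ...) x$roc

#' One-row performance summary of a classifier result
#' @param x an `acg_roc`.
#' @param ... unused.
#' @return a tibble with `auc`, `sensitivity`, `specificity`,
#'   `threshold`, `n`, `n_pos`, `n_neg`.
#' @export
glance.acg_roc <- function(x, ...) {
  tibble::tibble(
    auc = x$auc,
    sensitivity = x$sensitivity %||% NA_real_,
    specificity = x$specificity %||% NA_real_,
    threshold = x$threshold %||% NA_real_,
    n = nrow(x$scores),
    n_pos = sum(x$scores$label == 1),
    n_neg = sum(x$scores$label == 0)
  )
}

#' ROC plot of a classifier result
#' @param object an `acg_roc`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.acg_roc <- function(object, ...) {
  ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("ROC (AUC = %.3f)", object$auc)
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data %||%
NULL
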