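#' Stratified fold assignment
#'
#' Partitions subjects into `n_folds` folds, stratified by class: within each
#' class, members are shuffled and dealt round-robin, so per-fold class counts
#' differ from proportional allocation by less than one.
#'
#' @param classes vector of class labels, one per subject.
#' @param n_folds number of folds.
#' @return integer fold index per subject.
#' @export
stratified_folds <- function(classes, n_folds = 8) {
  counts <- table(classes)
  if (any(counts < n_folds)) {
    stop("every class must have at least n_folds members")
  }
  folds <- integer(length(classes))
  for (cl in names(counts)) {
    idx <- which(classes == cl)
    folds[idx[sample.int(length(idx))]] <- rep_len(seq_len(n_folds), length(idx))
  }
  folds
}

# fit multinomial logistic regression on training rows and return held-out
# class probabilities; features standardized with training-fold statistics
fit_predict_multinom <- function(xtr, ytr, xte, levels) {
  mu <- colMeans(xtr)
  s <- apply(xtr, 2L, stats::sd)
  s[s == 0] <- 1
  ztr <- sweep(sweep(xtr, 2L, mu), 2L, s, "/")
  zte <- sweep(sweep(xte, 2L, mu), 2L, s, "/")
  df_tr <- data.frame(.class = factor(ytr, levels = levels), ztr,
                      check.names = FALSE)
  fit <- nnet::multinom(.class ~ ., data = df_tr, decay = 1e-8,
                        trace = FALSE, maxit = 500)
  pr <- stats::predict(fit, newdata = data.frame(zte, check.names = FALSE),
                       type = "probs")
  if (is.null(dim(pr))) {           # two-class case or single test row
    if (length(levels) == 2) {
      pr <- cbind(1 - pr, pr)
      colnames(pr) <- fit$lev
    } else {
      pr <- matrix(pr, nrow = 1, dimnames = list(NULL, names(pr)))
    }
  }
  full <- matrix(0, nrow(pr), length(levels), dimnames = list(NULL, levels))
  full[, colnames(pr)] <- pr
  full
}

#' Repeated stratified cross-validated multinomial classification
#'
#' For each repeat, a fresh stratified fold split is drawn and a multinomial
#' logistic regression (maximum likelihood with a negligible L2 ridge of 1e-8
#' for numerical stability on separable data) is fitted on the training folds,
#' with features standardized using training-fold statistics only. Held-out
#' class probabilities and argmax labels are recorded for every subject
#' exactly once per repeat and pooled.
#'
#' @param data data.frame with `subject_id`, `class` and numeric feature
#'   columns; every class needs at least `n_folds` members.
#' @param n_folds folds per repeat (default 8).
#' @param n_repeats repeats (default 200).
#' @param seed integer seed.
#' @return data.frame of pooled predictions of class `cv_predictions`:
#'   `repeat_idx`, `fold`, `subject_id`, `true`, `predicted`, one probability
#'   column per class (prefixed `prob.`); class levels kept in attribute
#'   `class_levels`.
#' @export
crossval_predict <- function(data, n_folds = 8, n_repeats = 200, seed = 1) {
  xm <- feature_matrix(data)
  if (!all(is.finite(xm))) stop("features must be finite")
  classes <- as.character(data$class)
  levels <- sort(unique(classes))
  if (length(levels) < 2) stop("need at least 2 classes")
  set.seed(child_seed(seed, "crossval"))
  out <- vector("list", n_repeats * n_folds)
  slot <- 1L
  for (rep_i in seq_len(n_repeats)) {
    folds <- stratified_folds(classes, n_folds)
    for (f in seq_len(n_folds)) {
      te <- folds == f
      pr <- fit_predict_multinom(xm[!te, , drop = FALSE], classes[!te],
                                 xm[te, , drop = FALSE], levels)
      colnames(pr) <- paste0("prob.", levels)
      out[[slot]] <- data.frame(
        repeat_idx = rep_i, fold = f,
        subject_id = data$subject_id[te],
        true = classes[te],
        predicted = levels[max.col(pr, ties.method = "first")],
        pr, stringsAsFactors = FALSE, check.names = FALSE
      )
      slot <- slot + 1L
    }
  }
  preds <- do.call(rbind, out)
  rownames(preds) <- NULL
  attr(preds, "class_levels") <- levels
  class(preds) <- c("cv_predictions", "data.frame")
  preds
}

#' Shuffled-label null predictions
#'
#' Chance-level reference for [crossval_predict()]: class labels are randomly
#' permuted `n_shuffles` times and the cross-validation run with
#' `repeats_per_shuffle` repeats per shuffle, pooling
#' `n_shuffles * repeats_per_shuffle` randomized repeats (50 x 4 = 200 by
#' default). `repeat_idx` runs over all pooled repeats; the shuffle index is
#' recorded in `shuffle`.
#'
#' @inheritParams crossval_predict
#' @param n_shuffles number of label permutations (default 50).
#' @param repeats_per_shuffle CV repeats per permutation (default 4).
#' @return pooled `cv_predictions` with an extra `shuffle` column.
#' @export
shuffle_null <- function(data, n_shuffles = 50, repeats_per_shuffle = 4,
                         n_folds = 8, seed = 1) {
  set.seed(child_seed(seed, "shuffle"))
  shuffle_seeds <- sample.int(2^30, n_shuffles)
  out <- vector("list", n_shuffles)
  for (s in seq_len(n_shuffles)) {
    shuffled <- data
    shuffled$class <- sample(as.character(data$class))
    pr <- crossval_predict(shuffled, n_folds = n_folds,
                           n_repeats = repeats_per_shuffle,
                           seed = shuffle_seeds[s])
    pr$shuffle <- s
    pr$repeat_idx <- pr$repeat_idx + (s - 1L) * repeats_per_shuffle
    out[[s]] <- pr
  }
  preds <- do.call(rbind, out)
  rownames(preds) <- NULL
  attr(preds, "class_levels") <- attr(out[[1]], "class_levels")
  class(preds) <- c("cv_predictions", "data.frame")
  preds
}

#' Row-normalized confusion matrix
#'
#' Counts pooled predictions with rows as the true class and columns as the
#' classified label, then divides each row by its sum, giving the probability
#' of each predicted label conditional on the true class.
#'
#' @param preds a `cv_predictions` data.frame.
#' @return square numeric matrix with rows summing to 1.
#' @export
confusion_matrix <- function(preds) {
  levels <- attr(preds, "class_levels")
  tab <- table(factor(preds$true, levels = levels),
               factor(preds$predicted, levels = levels))
  rs <- rowSums(tab)
  if (any(rs == 0)) stop("no predictions for class: ",
                         paste(levels[rs == 0], collapse = ", "))
  m <- unclass(tab) / rs
  dimnames(m) <- list(true = levels, predicted = levels)
  m
}

#' One-vs-rest ROC curve from pooled probabilities
#'
#' Sweeps every distinct predicted probability of the positive class as a
#' threshold and plots the false-positive rate against the true-positive
#' rate; the area under the curve is computed by the trapezoid rule.
#'
#' @param preds a `cv_predictions` data.frame.
#' @param positive_class the class treated as positive.
#' @return list: `points` (data.frame `threshold`, `fpr`, `tpr` from (0,0) to
#'   (1,1)) and `auc`.
#' @export
roc_curve <- function(preds, positive_class) {
  levels <- attr(preds, "class_levels")
  if (!positive_class %in% levels) stop("unknown class: ", positive_class)
  scores <- preds[[paste0("prob.", positive_class)]]
  pos <- preds$true == positive_class
  if (!any(pos) || all(pos)) stop("need both positive and negative examples")
  ord <- order(scores, decreasing = TRUE)
  sc <- scores[ord]
  tp <- cumsum(pos[ord])
  fp <- cumsum(!pos[ord])
  last <- c(sc[-1] != sc[-length(sc)], TRUE)   # collapse tied thresholds
  pts <- data.frame(
    threshold = c(Inf, sc[last]),
    fpr = c(0, fp[last] / sum(!pos)),
    tpr = c(0, tp[last] / sum(pos))
  )
  list(points = pts, auc = trapezoid(pts$fpr, pts$tpr))
}

#' Per-class precision, recall and F1 with t-based confidence intervals
#'
#' Computes precision = TP / (TP + FP), recall = TP / (TP + FN) and
#' F1 = 2 * precision * recall / (precision + recall) per class within each
#' repeat, then summarizes across repeats: the headline value is the mean and
#' the confidence interval is `mean +/- t(1 - alpha/2, n - 1) * SE` over the
#' per-repeat values. A repeat in which a class's F1 is undefined (no
#' predicted or no true positives for the class) contributes 0 and is counted
#' in `n_undefined`.
#'
#' @param preds a `cv_predictions` data.frame.
#' @param alpha CI significance level (default 0.01, i.e. 99% CI).
#' @return data.frame per class: precision, recall, f1, their CI bounds, and
#'   `n_undefined`.
#' @export
f1_report <- function(preds, alpha = 0.01) {
  levels <- attr(preds, "class_levels")
  reps <- sort(unique(preds$repeat_idx))
  per_rep <- array(0, dim = c(length(reps), length(levels), 3),
                   dimnames = list(NULL, levels, c("precision", "recall", "f1")))
  undef <- stats::setNames(integer(length(levels)), levels)
  for (ri in seq_along(reps)) {
    sub <- preds[preds$repeat_idx == reps[ri], ]
    for (cl in levels) {
      tp <- sum(sub$true == cl & sub$predicted == cl)
      fp <- sum(sub$true != cl & sub$predicted == cl)
      fn <- sum(sub$true == cl & sub$predicted != cl)
      prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
      rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
      f1 <- if (!is.na(prec) && !is.na(rec) && prec + rec > 0) {
        2 * prec * rec / (prec + rec)
      } else NA_real_
      if (is.na(f1)) undef[cl] <- undef[cl] + 1L
      per_rep[ri, cl, ] <- c(ifelse(is.na(prec), 0, prec),
                             ifelse(is.na(rec), 0, rec),
                             ifelse(is.na(f1), 0, f1))
    }
  }
  n <- length(reps)
  tq <- if (n >= 2) stats::qt(1 - alpha / 2, df = n - 1) else NA_real_
  summarize <- function(metric) {
    m <- per_rep[, , metric, drop = FALSE][, , 1]
    if (is.null(dim(m))) m <- matrix(m, nrow = n)
    mu <- colMeans(m)
    se <- if (n >= 2) apply(m, 2L, stats::sd) / sqrt(n) else rep(NA_real_, ncol(m))
    list(mean = mu, lo = mu - tq * se, hi = mu + tq * se)
  }
  p <- summarize("precision"); r <- summarize("recall"); f <- summarize("f1")
  data.frame(
    class = levels,
    precision = p$mean, precision_lo = p$lo, precision_hi = p$hi,
    recall = r$mean, recall_lo = r$lo, recall_hi = r$hi,
    f1 = f$mean, f1_lo = f$lo, f1_hi = f$hi,
    n_undefined = as.integer(undef),
    row.names = NULL, stringsAsFactors = FALSE
  )
}
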