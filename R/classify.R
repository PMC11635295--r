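#' Predefined feature sets
#'
#' The six feature sets compared in the study design: graph-theory AUCs,
#' region-mean correlations, their union, and the restriction of each to
#' the members that separate the groups (Eg, Lp and the left occipital
#' region), plus the hybrid of those.
#'
#' @return Named list of character vectors of feature names, drawn from the
#'   four network AUCs (`Eg`, `Eloc`, `Lp`, `Cp`) and the six region means
#'   (`R_PFC`, `L_PFC`, `R_MC`, `L_MC`, `R_OC`, `L_OC`).
#' @export
default_feature_sets <- function() {
  list(
    gt         = c("Eg", "Eloc", "Lp", "Cp"),
    corr       = c("R_PFC", "L_PFC", "R_MC", "L_MC", "R_OC", "L_OC"),
    gt_corr    = c("Eg", "Eloc", "Lp", "Cp",
                   "R_PFC", "L_PFC", "R_MC", "L_MC", "R_OC", "L_OC"),
    gt_sig     = c("Eg", "Lp"),
    corr_sig   = c("L_OC"),
    hybrid_sig = c("Eg", "Lp", "L_OC")
  )
}

#' Assemble a feature table for classification
#'
#' @param auc_table Data frame of per-subject network AUCs (columns `Eg`,
#'   `Eloc`, `Lp`, `Cp`).
#' @param roi_table Data frame of per-subject region means (columns named
#'   by region).
#' @param members Character vector of feature names to select, in order.
#' @return Numeric matrix subjects x members.
#' @export
build_features <- function(auc_table, roi_table, members) {
  if (anyDuplicated(members)) stop("duplicate feature in set: ",
                                   paste(members[duplicated(members)],
                                         collapse = ", "))
  if (length(members) == 0L) stop("feature set is empty")
  pool <- cbind(as.data.frame(auc_table), as.data.frame(roi_table))
  missing_f <- setdiff(members, names(pool))
  if (length(missing_f))
    stop("feature(s) not available: ", paste(missing_f, collapse = ", "))
  x <- as.matrix(pool[, members, drop = FALSE])
  bad <- which(!is.finite(x), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("missing value for subject %d, feature '%s'",
                 bad[1, 1], members[bad[1, 2]]))
  x
}

#' K-nearest-neighbor prediction
#'
#' Majority vote among the k Euclidean-nearest training rows.  Distance
#' ties are broken by the lower training-row index; vote ties (impossible
#' for k = 3 with two classes) fall back to the single nearest neighbor's
#' label.  Fully deterministic.
#'
#' @param train Numeric matrix of training rows.
#' @param labels Training labels.
#' @param test Numeric vector (one row) or matrix of rows to predict.
#' @param k Neighbor count (default 3).
#' @return Predicted label(s).
#' @export
knn_predict <- function(train, labels, test, k = 3L) {
  train <- as.matrix(train)
  if (nrow(train) == 0L) stop("empty training set")
  stopifnot(length(labels) == nrow(train), k >= 1L, k <= nrow(train))
  if (is.null(dim(test))) test <- matrix(test, nrow = 1L)
  labels <- as.character(labels)
  apply(test, 1L, function(z) {
    d <- sqrt(colSums((t(train) - z)^2))
    nb <- order(d, seq_along(d))[seq_len(k)]   # distance tie -> lower index
    votes <- table(labels[nb])
    top <- names(votes)[votes == max(votes)]
    if (length(top) == 1L) top else labels[nb[1L]]
  })
}

#' Linear discriminant analysis prediction
#'
#' Gaussian equal-covariance discriminant with empirical class priors.
#' When the pooled within-class covariance is singular, a small ridge
#' (`ridge * mean(diag)`) is added to the diagonal; score ties go to the
#' first class level.
#'
#' @param train Numeric training matrix.
#' @param labels Training labels (two or more classes).
#' @param test Vector or matrix of rows to predict.
#' @param ridge Relative ridge used only on singular covariance
#'   (default 1e-8); set to 0 to error instead.
#' @return Predicted label(s).
#' @export
lda_fit_predict <- function(train, labels, test, ridge = 1e-8) {
  train <- as.matrix(train)
  labels <- factor(labels)
  stopifnot(nrow(train) == length(labels), nlevels(labels) >= 2L)
  if (is.null(dim(test))) test <- matrix(test, nrow = 1L)
  p <- ncol(train)
  lv <- levels(labels)
  mu <- do.call(rbind, lapply(lv, function(g)
    colMeans(train[labels == g, , drop = FALSE])))
  sw <- matrix(0, p, p)
  for (g in lv) {
    xg <- train[labels == g, , drop = FALSE]
    xg <- sweep(xg, 2L, colMeans(xg))
    sw <- sw + crossprod(xg)
  }
  sw <- sw / (nrow(train) - length(lv))
  inv <- tryCatch(solve(sw), error = function(e) NULL)
  if (is.null(inv)) {
    if (ridge <= 0)
      stop("pooled within-class covariance is singular; set ridge > 0 to regularize")
    inv <- solve(sw + diag(ridge * mean(diag(sw)) + ridge, p))
  }
  prior <- as.numeric(table(labels)[lv]) / nrow(train)
  scores <- test %*% inv %*% t(mu) -
    matrix(0.5 * rowSums((mu %*% inv) * mu) - log(prior),
           nrow(test), length(lv), byrow = TRUE)
  lv[apply(scores, 1L, which.max)]   # which.max: tie -> first level
}

#' Confusion-matrix performance metrics
#'
#' @param tp,fn,tn,fp Confusion counts with the positive class (MCS by
#'   convention) supplying tp/fn.
#' @return List with `accuracy`, `sensitivity`, `specificity` (`NA` when a
#'   denominator is empty).
#' @export
confusion_metrics <- function(tp, fn, tn, fp) {
  total <- tp + fn + tn + fp
  if (total <= 0) stop("empty confusion matrix")
  list(accuracy = (tp + tn) / total,
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
}

#' Leave-one-out cross-validated classification
#'
#' Each subject is predicted by a model trained on the remaining n - 1;
#' features are z-scored with means/SDs fit inside each training fold and
#' applied to the held-out row, so no information leaks from the held-out
#' subject (constant training columns are centered and left unscaled).  The
#' whole procedure is repeated `n_repeats` times over a seed list and
#' averaged; with the package's deterministic tie rules all repeats
#' coincide and the mean equals a single run.
#'
#' @param features Numeric matrix, subjects x features.
#' @param labels Group label per subject (two classes).
#' @param classifier `"knn"` or `"lda"`.
#' @param k KNN neighbor count (default 3).
#' @param positive Label counted as positive (default `"MCS"`, falling back
#'   to the first level when absent).
#' @param n_repeats Number of repetitions (default 20).
#' @param seeds Optional integer seed per repetition.
#' @return A `class_result`: list with `per_repeat` (data.frame of
#'   accuracy / sensitivity / specificity per repetition), their means,
#'   `confusion` (counts of the first repetition) and `predictions`.
#' @export
loocv <- function(features, labels, classifier = c("knn", "lda"), k = 3L,
                  positive = "MCS", n_repeats = 20L, seeds = NULL) {
  classifier <- match.arg(classifier)
  features <- as.matrix(features)
  labels <- as.character(labels)
  n <- nrow(features)
  stopifnot(length(labels) == n)
  if (min(table(labels)) < 2L) stop("need >= 2 subjects per class")
  if (!positive %in% labels) positive <- sort(unique(labels))[1]
  if (is.null(seeds)) seeds <- seq_len(n_repeats)
  stopifnot(length(seeds) == n_repeats)

  run_once <- function(seed) {
    set.seed(seed)   # governs any stochastic tie-break; rules here are deterministic
    preds <- character(n)
    for (i in seq_len(n)) {
      tr <- features[-i, , drop = FALSE]
      mu <- colMeans(tr)
      sdv <- apply(tr, 2L, stats::sd)
      sdv[sdv == 0] <- 1
      trz <- sweep(sweep(tr, 2L, mu), 2L, sdv, "/")
      tez <- (features[i, ] - mu) / sdv
      preds[i] <- if (classifier == "knn")
        knn_predict(trz, labels[-i], tez, k = k)
      else lda_fit_predict(trz, labels[-i], tez)
    }
    preds
  }

  per_repeat <- vector("list", n_repeats)
  first_conf <- NULL
  first_preds <- NULL
  for (rep_i in seq_len(n_repeats)) {
    preds <- run_once(seeds[rep_i])
    tp <- sum(preds == positive & labels == positive)
    fn <- sum(preds != positive & labels == positive)
    tn <- sum(preds != positive & labels != positive)
    fp <- sum(preds == positive & labels != positive)
    m <- confusion_metrics(tp, fn, tn, fp)
    per_repeat[[rep_i]] <- data.frame(repeat_id = rep_i,
                                      accuracy = m$accuracy,
                                      sensitivity = m$sensitivity,
                                      specificity = m$specificity)
    if (rep_i == 1L) {
      first_conf <- c(tp = tp, fn = fn, tn = tn, fp = fp)
      first_preds <- preds
    }
  }
  per_repeat <- do.call(rbind, per_repeat)
  structure(list(classifier = classifier, k = if (classifier == "knn") k else NA,
                 positive = positive,
                 per_repeat = per_repeat,
                 accuracy = mean(per_repeat$accuracy),
                 sensitivity = mean(per_repeat$sensitivity),
                 specificity = mean(per_repeat$specificity),
                 confusion = first_conf,
                 predictions = first_preds),
            class = "class_result")
}

#' @export
print.class_result <- function(x, ...) {
  cat(sprintf("LOOCV %s%s: accuracy %.3f, sensitivity %.3f, specificity %.3f (positive = %s, %d repeats)\n",
              toupper(x$classifier),
              if (!is.na(x$k)) paste0("(k=", x$k, ")") else "",
              x$accuracy, x$sensitivity, x$specificity, x$positive,
              nrow(x$per_repeat)))
  invisible(x)
}

#' Classification table across feature sets and classifiers
#'
#' Runs LOOCV for every feature set with both KNN and LDA, mirroring the
#' feature-set comparison layout of the study design.
#'
#' @param auc_table,roi_table Per-subject feature sources, see
#'   [build_features()].
#' @param labels Group labels.
#' @param feature_sets Named list of member vectors (default
#'   [default_feature_sets()]).
#' @param k,n_repeats,positive Passed to [loocv()].
#' @param skip_incomplete Skip (with a warning) feature sets with members
#'   missing for some subject instead of erroring; used by the pipeline so
#'   that one quality-control casualty region does not abort the run.
#' @return Data frame: one row per feature set x classifier with accuracy,
#'   sensitivity and specificity.
#' @export
classification_table <- function(auc_table, roi_table, labels,
                                 feature_sets = default_feature_sets(),
                                 k = 3L, n_repeats = 20L, positive = "MCS",
                                 skip_incomplete = FALSE) {
  rows <- list()
  for (fs in names(feature_sets)) {
    x <- if (skip_incomplete) {
      tryCatch(build_features(auc_table, roi_table, feature_sets[[fs]]),
               error = function(e) {
                 warning("feature set '", fs, "' skipped: ",
                         conditionMessage(e), call. = FALSE)
                 NULL
               })
    } else build_features(auc_table, roi_table, feature_sets[[fs]])
    if (is.null(x)) next
    for (clf in c("knn", "lda")) {
      res <- loocv(x, labels, classifier = clf, k = k,
                   n_repeats = n_repeats, positive = positive)
      rows[[length(rows) + 1L]] <-
        data.frame(feature_set = fs,
                   members = paste(feature_sets[[fs]], collapse = "+"),
                   classifier = clf, accuracy = res$accuracy,
                   sensitivity = res$sensitivity,
                   specificity = res$specificity)
    }
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}
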