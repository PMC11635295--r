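#' Two-sample t-test
#'
#' Classical two-sample t-test (pooled-variance Student's by default, Welch
#' optional) with an explicit degenerate-variance contract: when both
#' samples are constant, equal means give `t = 0, p = 1` and unequal means
#' give `t = +/-Inf, p = 0`.
#'
#' @param x,y Numeric samples, each of length >= 2.
#' @param welch Use the Welch (unequal-variance) variant.
#' @return List with `t`, `p` (two-tailed), `df`.
#' @export
two_sample_t <- function(x, y, welch = FALSE) {
  stopifnot(length(x) >= 2L, length(y) >= 2L,
            all(is.finite(x)), all(is.finite(y)))
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    if (mean(x) == mean(y)) return(list(t = 0, p = 1,
                                        df = length(x) + length(y) - 2))
    return(list(t = sign(mean(x) - mean(y)) * Inf, p = 0,
                df = length(x) + length(y) - 2))
  }
  ht <- stats::t.test(x, y, var.equal = !welch)
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter))
}

#' Cohen's d effect size
#'
#' `d = (mean(x) - mean(y)) / s_pooled` with the pooled SD computed over
#' `n1 + n2 - 2` degrees of freedom; its sign follows the mean difference.
#'
#' @param x,y Numeric samples, each of length >= 2.
#' @return d, or `NA` when the pooled SD is zero.
#' @export
cohens_d <- function(x, y) {
  stopifnot(length(x) >= 2L, length(y) >= 2L)
  n1 <- length(x); n2 <- length(y)
  sp <- sqrt(((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) /
               (n1 + n2 - 2))
  if (sp == 0) return(NA_real_)
  (mean(x) - mean(y)) / sp
}

#' Groupwise comparison of every feature
#'
#' Runs a two-sample t-test and Cohen's d for each feature column between
#' the two label groups.  By default no multiple-comparison correction is
#' applied (each feature is reported at its nominal p-value, and a note
#' flags this); an optional Benjamini-Hochberg FDR column can be added.
#'
#' @param features Data frame or matrix, subjects in rows, features in
#'   columns.
#' @param labels Two-level group label per subject; the first level (by
#'   factor order) plays the role of group x in `mean_x - mean_y`.
#' @param alpha Significance level (default 0.05).
#' @param fdr Add a BH-adjusted `p_fdr` column (off by default).
#' @param welch Use Welch tests.
#' @return A `group_comparison` data.frame: one row per feature with group
#'   means/SDs, `t`, `p`, `cohens_d` and `significant`.  Features with
#'   missing values are excluded with a warning.
#' @export
compare_all <- function(features, labels, alpha = 0.05, fdr = FALSE,
                        welch = FALSE) {
  features <- as.data.frame(features)
  labels <- factor(labels)
  stopifnot(nrow(features) == length(labels), nlevels(labels) == 2L)
  lv <- levels(labels)
  if (min(table(labels)) < 2L) stop("need >= 2 subjects per group")
  keep <- vapply(features, function(col) all(is.finite(col)), logical(1))
  if (any(!keep))
    warning("excluding feature(s) with missing values: ",
            paste(names(features)[!keep], collapse = ", "))
  features <- features[, keep, drop = FALSE]
  rows <- lapply(names(features), function(fn) {
    x <- features[labels == lv[1], fn]
    y <- features[labels == lv[2], fn]
    tt <- two_sample_t(x, y, welch = welch)
    data.frame(feature = fn,
               mean_x = mean(x), sd_x = stats::sd(x), n_x = length(x),
               mean_y = mean(y), sd_y = stats::sd(y), n_y = length(y),
               t = tt$t, df = tt$df, p = tt$p,
               cohens_d = cohens_d(x, y))
  })
  out <- do.call(rbind, rows)
  if (fdr) out$p_fdr <- stats::p.adjust(out$p, method = "BH")
  out$significant <- (if (fdr) out$p_fdr else out$p) < alpha
  attr(out, "groups") <- lv
  attr(out, "note") <- if (fdr) "BH-FDR adjusted"
                       else "uncorrected p-values (no multiple-comparison correction)"
  class(out) <- c("group_comparison", "data.frame")
  out
}

#' @export
print.group_comparison <- function(x, ...) {
  gl <- attr(x, "groups")
  cat("Group comparison (", gl[1], " vs ", gl[2], "): ",
      nrow(x), " features, ", sum(x$significant), " significant; ",
      attr(x, "note"), "\n", sep = "")
  print.data.frame(x, digits = 4)
  invisible(x)
}
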