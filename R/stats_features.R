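# Feature discretization, mutual information, mRMR selection, test-retest
# ICC, and chi-squared association.

#' Three-level discretization at mean +/- sd
#'
#' Values at or below `mean - sd` become `low`, values at or above
#' `mean + sd` become `high`, everything else `mid` (boundaries are
#' inclusive). The standard preprocessing for mutual-information-based
#' selection on continuous radiomic features.
#'
#' @param values numeric vector of length >= 2.
#' @return Integer codes (-1, 0, 1 for low/mid/high) with attribute
#'   `constant = TRUE` when the input had zero spread.
#' @export
discretize <- function(values) {
  stopifnot(length(values) >= 2)
  m <- mean(values); s <- sd(values)
  if (!is.finite(s) || s == 0) {
    out <- rep(0L, length(values))
    attr(out, "constant") <- TRUE
    return(out)
  }
  out <- integer(length(values))
  out[values <= m - s] <- -1L
  out[values >= m + s] <- 1L
  out
}

#' Plug-in mutual information of two discrete vectors
#'
#' Computed from the empirical joint frequency table, log base 2.
#'
#' @param x,y equal-length discrete vectors (any atomic codes).
#' @return MI in bits (>= 0).
#' @export
mutual_information <- function(x, y) {
  if (length(x) != length(y)) stopf("mutual_information: length mismatch")
  stopifnot(length(x) >= 2)
  tab <- table(x, y)
  p <- tab / sum(tab)
  px <- rowSums(p); py <- colSums(p)
  ind <- outer(px, py)
  nz <- p > 0
  max(0, sum(p[nz] * log2(p[nz] / ind[nz])))
}

entropy_bits <- function(x) {
  p <- table(x) / length(x)
  -sum(p[p > 0] * log2(p[p > 0]))
}

# Features with more than 3 distinct values go through the mean +/- sd
# discretization; features that are already low-cardinality (binary or
# 3-level, e.g. a label-like plant) are used as categories directly, since
# re-thresholding them at mean +/- sd can collapse a balanced two-valued
# feature into a single level.
code_feature <- function(v) {
  u <- unique(v)
  if (length(u) == 1) {
    out <- rep(0L, length(v))
    attr(out, "constant") <- TRUE
    return(out)
  }
  if (length(u) <= 3) return(match(v, sort(u)))
  discretize(v)
}

#' Greedy mRMR feature selection (MID scheme)
#'
#' Continuous features are discretized with [discretize()] (features with at
#' most 3 distinct values are used as categories directly); the first pick
#' maximizes
#' relevance MI(feature; label); every subsequent pick maximizes
#' `MI(f; label) - mean(MI(f; selected))`. Ties are broken by column order,
#' so the ranking is deterministic.
#'
#' @param table data.frame with `label` and feature columns (a `case_id`
#'   column is ignored).
#' @param k number of features to select (>= 1).
#' @return A list of class `mrmr_result`: `selected` (names, length k),
#'   `relevance` and `redundancy` (per-step values), `score` (their
#'   difference), `constant_features` (flagged zero-spread features).
#' @export
mrmr_select <- function(table, k) {
  stopifnot(is.data.frame(table), "label" %in% names(table), k >= 1)
  feats <- setdiff(names(table), c("case_id", "label"))
  if (k > length(feats)) stopf("mrmr_select: k = %d exceeds %d features", k, length(feats))
  y <- table$label
  disc <- lapply(table[feats], code_feature)
  constant <- feats[vapply(disc, function(d) isTRUE(attr(d, "constant")), logical(1))]
  rel <- vapply(disc, function(d) mutual_information(d, y), numeric(1))

  selected <- character(0)
  rel_out <- red_out <- numeric(0)
  remaining <- feats
  for (step in seq_len(k)) {
    red <- if (length(selected) == 0) {
      setNames(rep(0, length(remaining)), remaining)
    } else {
      vapply(remaining, function(f) {
        mean(vapply(selected, function(s) {
          mutual_information(disc[[f]], disc[[s]])
        }, numeric(1)))
      }, numeric(1))
    }
    score <- rel[remaining] - red
    pick <- remaining[which.max(score)]  # which.max keeps the first tie
    selected <- c(selected, pick)
    rel_out <- c(rel_out, rel[[pick]])
    red_out <- c(red_out, red[[pick]])
    remaining <- setdiff(remaining, pick)
  }
  structure(list(selected = selected, relevance = rel_out,
                 redundancy = red_out, score = rel_out - red_out,
                 constant_features = constant),
            class = "mrmr_result")
}

#' @export
print.mrmr_result <- function(x, ...) {
  cat("<mrmr_result>\n")
  print(data.frame(feature = x$selected, relevance = round(x$relevance, 4),
                   redundancy = round(x$redundancy, 4),
                   score = round(x$score, 4)))
  invisible(x)
}

#' Test-retest stability via the intraclass correlation coefficient
#'
#' Per feature, the two-way random-effects, absolute-agreement,
#' single-measurement ICC -- ICC(2,1) -- computed from the (test, retest)
#' two-column matrix via the mean-squares decomposition, clipped to \[-1, 1\].
#' Stability classes: high when ICC > 0.7, moderate when 0.4 < ICC <= 0.7,
#' unstable otherwise.
#'
#' @param test,retest numeric matrices or data.frames, cases x features, of
#'   identical shape with >= 3 cases.
#' @return A data.frame of class `stability_report`: `feature`, `icc`,
#'   `stability`, `flagged` (TRUE where the ICC was undefined and reported
#'   as 0).
#' @export
icc <- function(test, retest) {
  test <- as.matrix(test); retest <- as.matrix(retest)
  if (!identical(dim(test), dim(retest))) stopf("icc: shape mismatch")
  if (nrow(test) < 3) stopf("icc: need at least 3 cases")
  feats <- colnames(test) %||% paste0("f", seq_len(ncol(test)))
  res <- lapply(seq_len(ncol(test)), function(j) icc21(test[, j], retest[, j]))
  vals <- vapply(res, `[[`, numeric(1), "icc")
  flag <- vapply(res, `[[`, logical(1), "flagged")
  cls <- ifelse(vals > 0.7, "high", ifelse(vals > 0.4, "moderate", "unstable"))
  structure(data.frame(feature = feats, icc = vals, stability = cls,
                       flagged = flag, stringsAsFactors = FALSE),
            class = c("stability_report", "data.frame"))
}

# ICC(2,1) from the two-way mean squares (n subjects, k = 2 raters)
icc21 <- function(x, y) {
  n <- length(x); k <- 2
  dat <- cbind(x, y)
  if (all(dat == dat[1, 1])) return(list(icc = 0, flagged = TRUE))
  row_means <- rowMeans(dat)
  col_means <- colMeans(dat)
  grand <- mean(dat)
  msr <- k * sum((row_means - grand)^2) / (n - 1)
  msc <- n * sum((col_means - grand)^2) / (k - 1)
  sse <- sum((dat - outer(row_means, rep(1, k)) -
                outer(rep(1, n), col_means) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k * (msc - mse) / n
  if (denom == 0) return(list(icc = 0, flagged = TRUE))
  list(icc = max(-1, min(1, (msr - mse) / denom)), flagged = FALSE)
}

#' Pearson chi-squared test of association
#'
#' @param labels_a,labels_b equal-length categorical vectors with >= 2
#'   categories each.
#' @return A list with `statistic`, `p_value`, `df` and the contingency
#'   `table`.
#' @export
chi2_association <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) stopf("chi2_association: length mismatch")
  tab <- table(labels_a, labels_b)
  if (nrow(tab) < 2 || ncol(tab) < 2) {
    stopf("chi2_association: need at least 2 categories per vector")
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected == 0)) {
    bad <- which(expected == 0, arr.ind = TRUE)[1, ]
    stopf("chi2_association: expected count 0 in cell (%s, %s)",
          rownames(tab)[bad[1]], colnames(tab)[bad[2]])
  }
  stat <- sum((tab - expected)^2 / expected)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  list(statistic = as.numeric(stat), p_value = pchisq(stat, df, lower.tail = FALSE),
       df = df, table = tab)
}
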