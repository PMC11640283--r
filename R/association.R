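#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact two-sided p-value under the minimum-likelihood rule: the sum of
#' hypergeometric probabilities, over all tables with the observed margins,
#' of tables no more probable than the observed one. Thin wrapper around
#' [stats::fisher.test()], which implements exactly this convention.
#'
#' @param table 2x2 matrix (or coercible) of non-negative integer counts
#'   `[[both, a_only], [b_only, neither]]`.
#' @return the two-sided p-value.
#' @export
fisher_exact_2x2 <- function(table) {
  tab <- .check_2x2(table)
  if (sum(tab) == 0) return(1)
  # fisher.test can overshoot 1 by floating-point error
  min(1, stats::fisher.test(tab, alternative = "two.sided")$p.value)
}

#' Odds ratio of a 2x2 table
#'
#' Sample odds ratio `ad/bc`; when any cell is zero the Haldane-Anscombe
#' correction (adding 0.5 to every cell) is applied so the estimate stays
#' finite, and typical tables are left unbiased.
#'
#' @inheritParams fisher_exact_2x2
#' @return a positive number (possibly `NaN` for the all-zero table).
#' @export
odds_ratio <- function(table) {
  tab <- .check_2x2(table)
  if (any(tab == 0)) tab <- tab + 0.5
  (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
}

.check_2x2 <- function(table) {
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(2L, 2L))) stop("need a 2x2 table", call. = FALSE)
  if (any(is.na(tab)) || any(tab < 0) || any(tab != round(tab)))
    stop("table cells must be non-negative integers", call. = FALSE)
  storage.mode(tab) <- "double"
  tab
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment,
#' `q_(i) = min_(j >= i) p_(j) * m / j` capped at 1, returned in input order.
#' Wrapper around [stats::p.adjust()].
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return adjusted q-values in the input order.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p_values, method = "BH")
}

#' Pairwise co-occurrence / mutual-exclusivity testing
#'
#' Tests every unordered pair of features with the two-sided Fisher exact
#' test, controls the false discovery rate across all pairs in one
#' Benjamini-Hochberg family, and labels each pair by effect direction:
#' `co-occurring` when `q < alpha` and the odds ratio exceeds 1, `exclusive`
#' when `q < alpha` and the odds ratio is below 1, `none` otherwise.
#'
#' @param fm an `mn_feature_matrix` with at least two features.
#' @param alpha FDR significance level (default 0.05).
#' @return data.frame with one row per pair: `feature_a`, `feature_b`,
#'   `n11`, `n10`, `n01`, `n00`, `odds_ratio`, `p`, `q`, `relation`.
#' @export
classify_pairs <- function(fm, alpha = 0.05) {
  stopifnot(inherits(fm, "mn_feature_matrix"))
  d <- ncol(fm$x)
  if (d < 2L) stop("need at least two features", call. = FALSE)
  x <- fm$x
  n <- nrow(x)
  cross <- crossprod(x)                    # n11 for every pair
  colsum <- colSums(x)
  idx <- which(upper.tri(cross), arr.ind = TRUE)
  res <- data.frame(
    feature_a = colnames(x)[idx[, 1]],
    feature_b = colnames(x)[idx[, 2]],
    n11 = cross[idx], stringsAsFactors = FALSE)
  res$n10 <- colsum[idx[, 1]] - res$n11
  res$n01 <- colsum[idx[, 2]] - res$n11
  res$n00 <- n - res$n11 - res$n10 - res$n01
  stats <- mapply(function(a, b, c, d) {
    tab <- matrix(c(a, c, b, d), 2, 2)
    c(odds_ratio(tab), fisher_exact_2x2(tab))
  }, res$n11, res$n10, res$n01, res$n00)
  res$odds_ratio <- stats[1, ]
  res$p <- stats[2, ]
  res$q <- bh_adjust(res$p)
  res$relation <- ifelse(res$q < alpha & res$odds_ratio > 1, "co-occurring",
                  ifelse(res$q < alpha & res$odds_ratio < 1, "exclusive",
                         "none"))
  res
}
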