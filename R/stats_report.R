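## Statistics layer: paired Wilcoxon signed-rank on household-pair
## differences, Spearman rank correlation, Fisher's exact test and
## Benjamini-Hochberg FDR, all returned in a uniform TestResult shape.
## The computations delegate to the standard stats:: implementations; the
## test suite cross-checks them against independent enumeration oracles.

test_result <- function(statistic, p, method, estimate = NA_real_) {
  structure(list(statistic = unname(statistic), p = unname(p),
                 estimate = unname(estimate), q = NA_real_,
                 significant = NA, method = method),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g", x$method, x$statistic,
              x$p))
  if (!is.na(x$estimate)) cat(sprintf(", estimate = %.4g", x$estimate))
  if (!is.na(x$q)) cat(sprintf(", q = %.4g (%s)", x$q,
                               if (isTRUE(x$significant)) "significant"
                               else "n.s."))
  cat("\n")
  invisible(x)
}

#' Paired Wilcoxon signed-rank test on household pairs
#'
#' Two-sided signed-rank test on per-pair differences. Zero differences
#' are dropped (the signed-rank convention); if every difference is zero
#' the test is degenerate and `p = 1` is returned with a message. The
#' exact null distribution is used for up to 25 informative pairs without
#' ties; the tie-corrected normal approximation (with continuity
#' correction) otherwise.
#'
#' @param x,y paired numeric vectors (e.g. IgA+ and IgA- values per
#'   household pair, in pair order).
#' @return a `test_result` (statistic V, two-sided p).
#' @export
paired_wilcoxon <- function(x, y) {
  if (length(x) != length(y))
    stop("paired series have different lengths (", length(x), " vs ",
         length(y), ")")
  d <- x - y
  d <- d[!is.na(d)]
  if (all(d == 0)) {
    message("all paired differences are zero; p = 1 by convention")
    return(test_result(NA_real_, 1, "paired Wilcoxon signed-rank"))
  }
  nz <- d[d != 0]
  exact <- length(nz) <= 25 && !any(duplicated(abs(nz)))
  # zeroes are dropped here so the exact distribution stays available
  wt <- suppressWarnings(stats::wilcox.test(nz, mu = 0, exact = exact,
                                            correct = TRUE))
  test_result(wt$statistic, wt$p.value, "paired Wilcoxon signed-rank")
}

#' Spearman rank correlation with two-sided p
#'
#' Exact permutation p for n <= 10 without ties, t approximation above
#' (and whenever ties make the exact distribution unavailable). Constant
#' input leaves the coefficient undefined and returns NA.
#'
#' @param x,y numeric vectors of equal length (n >= 3).
#' @return a `test_result` with `estimate` = SCC.
#' @export
spearman <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("spearman needs n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant input; Spearman coefficient undefined")
    return(test_result(NA_real_, NA_real_, "Spearman rank correlation"))
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = length(x) <= 10))
  test_result(ct$statistic, ct$p.value, "Spearman rank correlation",
              estimate = ct$estimate)
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p by summation of hypergeometric point probabilities no
#' larger than that of the observed table.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return a `test_result` with `estimate` = conditional odds ratio.
#' @export
fisher_exact <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2, 2)), all(table >= 0),
            all(table == round(table)))
  ft <- stats::fisher.test(table)
  test_result(NA_real_, ft$p.value, "Fisher exact",
              estimate = ft$estimate)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @return q-values in the original order.
#' @export
fdr_adjust <- function(pvals) {
  stopifnot(all(pvals >= 0 & pvals <= 1, na.rm = TRUE))
  stats::p.adjust(pvals, method = "BH")
}

#' Apply FDR within declared test families and flag significance
#'
#' Adds `q` (BH within each family) and the study's significance call
#' `p < 0.05 & q < 0.1` to a list of test results.
#'
#' @param results list of `test_result` objects.
#' @param family character vector assigning each result to an adjustment
#'   family (e.g. one family per figure panel). Default: one family.
#' @return the list, with `q` and `significant` filled in.
#' @export
adjust_results <- function(results, family = rep("all", length(results))) {
  stopifnot(length(family) == length(results))
  p <- vapply(results, `[[`, numeric(1), "p")
  q <- rep(NA_real_, length(p))
  for (f in unique(family)) {
    sel <- family == f
    q[sel] <- fdr_adjust(p[sel])
  }
  for (i in seq_along(results)) {
    results[[i]]$q <- q[i]
    results[[i]]$significant <- !is.na(p[i]) && p[i] < 0.05 && q[i] < 0.1
  }
  results
}

#' Tidy a list of test results
#'
#' @param results (possibly adjusted) list of `test_result`s.
#' @param labels optional names for the rows.
#' @return data.frame with statistic, estimate, p, q, significance.
#' @export
results_table <- function(results, labels = names(results)) {
  data.frame(
    label = labels %||% paste0("test", seq_along(results)),
    method = vapply(results, `[[`, character(1), "method"),
    statistic = vapply(results, `[[`, numeric(1), "statistic"),
    estimate = vapply(results, `[[`, numeric(1), "estimate"),
    p = vapply(results, `[[`, numeric(1), "p"),
    q = vapply(results, `[[`, numeric(1), "q"),
    significant = vapply(results, function(r) isTRUE(r$significant),
                         logical(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}
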