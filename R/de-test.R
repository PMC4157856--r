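#' Audic-Claverie conditional probability of a tag count pair
#'
#' For a gene with \code{x} tags in library 1 (total \code{n1} clean tags)
#' and \code{y} tags in library 2 (total \code{n2}), the probability of
#' observing \code{y} given \code{x} under equal expression is
#' \deqn{p(y|x) = \left(\frac{N_2}{N_1}\right)^y
#'   \frac{(x+y)!}{x!\,y!\,(1+N_2/N_1)^{x+y+1}},}
#' the conditional distribution obtained by integrating the Poisson rate
#' out of two independent Poisson counts. Equivalently \code{y | x} is
#' negative binomial with size \code{x+1} and success probability
#' \code{n1/(n1+n2)}. Computed in log space; vectorised over \code{x},
#' \code{y}.
#'
#' @param x,y Non-negative integer tag counts in library 1 and 2.
#' @param n1,n2 Positive clean-tag totals of library 1 and 2.
#' @return Probabilities in [0, 1], same length as \code{x}/\code{y}.
#' @seealso [ac_pvalue()] for the two-sided test built on this
#'   distribution.
#' @examples
#' ac_probability(1, 1, 1e6, 1e6)  # 0.25
#' @export
ac_probability <- function(x, y, n1, n2) {
  assert_counts(x, "x"); assert_counts(y, "y")
  assert_scalar_number(n1, "n1"); assert_scalar_number(n2, "n2")
  if (n1 <= 0 || n2 <= 0) stop_input("'n1' and 'n2' must be positive")
  q <- n2 / (n1 + n2)
  exp(lchoose(x + y, y) + y * log(q) + (x + 1) * log1p(-q))
}

# Log pmf of the conditional distribution at counts k (vectorised over k).
ac_log_pmf <- function(k, x, lq, l1q) {
  lgamma(x + k + 1) - lgamma(k + 1) - lgamma(x + 1) + k * lq + (x + 1) * l1q
}

# One pair's two-sided p-value. Sums the smaller tail directly (numerically
# exact for tiny tails); the larger tail is obtained by complement, where
# absolute error ~1e-16 is irrelevant.
ac_pvalue_one <- function(x, y, q) {
  lq <- log(q); l1q <- log1p(-q)
  mu <- (x + 1) * q / (1 - q)  # conditional mean of y given x
  if (y <= mu) {
    lower <- sum(exp(ac_log_pmf(0:y, x, lq, l1q)))
    upper <- 1 - lower + exp(ac_log_pmf(y, x, lq, l1q))
  } else {
    # sum the upper tail upward from y; above the mode terms decay and the
    # term ratio tends to q < 1, so truncation error is geometrically bounded
    acc <- 0
    k0 <- y
    chunk <- 512L
    repeat {
      ks <- k0:(k0 + chunk - 1L)
      terms <- exp(ac_log_pmf(ks, x, lq, l1q))
      acc <- acc + sum(terms)
      last <- terms[chunk]
      ratio <- q * (x + ks[chunk] + 1) / (ks[chunk] + 1)
      if (ratio < 1 && last * ratio / (1 - ratio) < max(acc, 1e-300) * 1e-16)
        break
      k0 <- k0 + chunk
      chunk <- min(2L * chunk, 65536L)
    }
    upper <- acc
    lower <- 1 - upper + exp(ac_log_pmf(y, x, lq, l1q))
  }
  min(1, 2 * min(lower, upper))
}

#' Two-sided Audic-Claverie p-value for differential expression
#'
#' Tests whether a gene is expressed equally in two tag libraries given its
#' counts \code{x}, \code{y} and the library clean-tag totals \code{n1},
#' \code{n2}. The p-value is the doubled smaller tail of the conditional
#' distribution of \code{y} given \code{x} (see [ac_probability()]),
#' including the observed point and capped at 1. Numerically stable for
#' counts up to the million range: the smaller tail is always accumulated
#' by direct summation, never by complement.
#'
#' @inheritParams ac_probability
#' @return p-values in [0, 1], vectorised over \code{x}, \code{y}.
#' @examples
#' ac_pvalue(200, 100, 1e6, 1e6)
#' ac_pvalue(0, 100, 1e6, 1e6)   # overwhelming evidence, ~1e-30
#' @export
ac_pvalue <- function(x, y, n1, n2) {
  assert_counts(x, "x"); assert_counts(y, "y")
  assert_scalar_number(n1, "n1"); assert_scalar_number(n2, "n2")
  if (n1 <= 0 || n2 <= 0) stop_input("'n1' and 'n2' must be positive")
  if (length(x) != length(y)) {
    n <- max(length(x), length(y))
    x <- rep_len(x, n); y <- rep_len(y, n)
  }
  q <- n2 / (n1 + n2)
  vapply(seq_along(x), function(i) ac_pvalue_one(x[i], y[i], q), numeric(1))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment; a thin validating wrapper over
#' \code{stats::p.adjust(method = "BH")}.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return Adjusted values (q-values), order-aligned with the input.
#' @export
bh_fdr <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1))
    stop_input("'p' must be p-values in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Log2 expression ratio between two libraries
#'
#' \code{log2(TPM1 / TPM2)} where \code{TPM_i = count / N_i * 1e6}. A zero
#' count is floored to 1 before normalisation so the ratio stays finite
#' (how tag pipelines report, e.g., a gene absent from one library at a
#' finite fold such as |log2| ~ 12). The untestable case \code{x = y = 0}
#' returns 0 by convention.
#'
#' @inheritParams ac_probability
#' @return Finite log2 ratios (library 1 over library 2), vectorised.
#' @examples
#' log2_ratio(200, 100, 1e6, 1e6)  # +1
#' @export
log2_ratio <- function(x, y, n1, n2) {
  assert_counts(x, "x"); assert_counts(y, "y")
  if (n1 <= 0 || n2 <= 0) stop_input("'n1' and 'n2' must be positive")
  out <- log2((pmax(x, 1) / n1) / (pmax(y, 1) / n2))
  out[x == 0 & y == 0] <- 0
  out
}

#' Call differentially expressed genes between two tag libraries
#'
#' Runs the Audic-Claverie test on per-gene unambiguous tag counts and
#' applies the joint decision rule: a gene is differentially expressed iff
#' \code{p < p_threshold} AND \code{fdr < fdr_threshold} AND
#' \code{|log2_ratio| >= log2_threshold}; the direction (up/down, library 1
#' relative to library 2) follows the sign of the log2 ratio. Genes with
#' \code{x + y = 0} are untestable: they are excluded from the test and
#' from the BH family (their p and fdr are NA, call \code{ns}).
#'
#' @param counts data.frame with columns \code{gene_id}, \code{x}, \code{y}
#'   (tag counts in library 1 and 2).
#' @param n1,n2 Clean-tag totals of the two libraries.
#' @param p_threshold,fdr_threshold P-value and FDR gates (defaults 0.005
#'   and 0.001).
#' @param log2_threshold Minimum absolute log2 ratio (default 1, i.e.
#'   2-fold; the gate is inclusive, \code{>=}).
#' @return A list of class \code{DEResult}:
#'   \describe{
#'     \item{table}{data.frame \code{gene_id, x, y, tpm1, tpm2,
#'       log2_ratio, p_value, fdr, call} sorted by p-value.}
#'     \item{summary}{list \code{n_total, n_up, n_down, pct_up, pct_down}
#'       (percentages of the DEG total, 1 decimal).}
#'   }
#' @export
call_degs <- function(counts, n1, n2, p_threshold = 0.005,
                      fdr_threshold = 0.001, log2_threshold = 1) {
  if (!is.data.frame(counts) ||
      !all(c("gene_id", "x", "y") %in% names(counts)))
    stop_input("'counts' must have columns gene_id, x, y")
  assert_scalar_number(p_threshold, "p_threshold", 0, 1)
  assert_scalar_number(fdr_threshold, "fdr_threshold", 0, 1)
  assert_scalar_number(log2_threshold, "log2_threshold", 0)
  x <- counts$x; y <- counts$y
  assert_counts(x, "x"); assert_counts(y, "y")

  tab <- data.frame(gene_id = counts$gene_id, x = x, y = y,
                    tpm1 = x / n1 * 1e6, tpm2 = y / n2 * 1e6,
                    log2_ratio = log2_ratio(x, y, n1, n2),
                    p_value = rep(NA_real_, length(x)),
                    fdr = rep(NA_real_, length(x)),
                    call = rep("ns", length(x)),
                    stringsAsFactors = FALSE)
  testable <- x + y > 0
  if (any(testable)) {
    p <- ac_pvalue(x[testable], y[testable], n1, n2)
    tab$p_value[testable] <- p
    tab$fdr[testable] <- bh_fdr(p)
  }
  de <- testable & !is.na(tab$p_value) &
    tab$p_value < p_threshold & tab$fdr < fdr_threshold &
    abs(tab$log2_ratio) >= log2_threshold
  tab$call[de] <- ifelse(tab$log2_ratio[de] > 0, "up", "down")
  tab <- tab[order(tab$p_value), , drop = FALSE]
  rownames(tab) <- NULL

  n_up <- sum(tab$call == "up"); n_down <- sum(tab$call == "down")
  n_total <- n_up + n_down
  res <- list(table = tab,
              summary = list(
                n_total = n_total, n_up = n_up, n_down = n_down,
                pct_up = if (n_total > 0) round(n_up / n_total * 100, 1) else 0,
                pct_down = if (n_total > 0) round(n_down / n_total * 100, 1) else 0))
  class(res) <- "DEResult"
  res
}

#' @export
print.DEResult <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "DEResult: %d genes tested, %d DEGs (%d up [%.1f%%], %d down [%.1f%%])\n",
    sum(!is.na(x$table$p_value)), s$n_total, s$n_up, s$pct_up,
    s$n_down, s$pct_down))
  invisible(x)
}

#' Histogram of absolute fold changes between two libraries
#'
#' Bins absolute log2 ratios at configurable edges and reports the
#' fraction of entries whose linear ratio is within 5-fold, the headline
#' concordance statistic of two-library tag comparisons.
#'
#' @param results A \code{DEResult} or a data.frame with a
#'   \code{log2_ratio} column.
#' @param edges Increasing numeric vector of |log2 ratio| bin edges.
#' @return List with \code{bins} (data.frame \code{bin}, \code{count}) and
#'   \code{pct_within_5fold} (percentage, 2 decimals).
#' @export
fold_change_histogram <- function(results,
                                  edges = c(0, 1, log2(5), 3, 5, 9, Inf)) {
  tab <- if (inherits(results, "DEResult")) results$table else results
  if (!is.data.frame(tab) || !"log2_ratio" %in% names(tab) || nrow(tab) == 0L)
    stop_input("'results' must be non-empty with a log2_ratio column")
  if (is.unsorted(edges, strictly = TRUE))
    stop_input("'edges' must be strictly increasing")
  a <- abs(tab$log2_ratio)
  cuts <- cut(a, breaks = edges, include.lowest = TRUE, right = FALSE)
  list(bins = data.frame(bin = levels(cuts), count = as.integer(table(cuts)),
                         stringsAsFactors = FALSE),
       pct_within_5fold = round(mean(a <= log2(5)) * 100, 2))
}
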