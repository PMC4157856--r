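#' Relative expression by the comparative Ct method
#'
#' Computes the 2^-ddCt fold change of a target gene between two samples.
#' Replicate Ct values are averaged on the Ct scale; dCt = mean Ct(target)
#' - mean Ct(reference) within each sample; ddCt = dCt(test) - dCt(control)
#' and the fold change is 2^-ddCt. A global Ct shift of a sample (e.g. a
#' loading difference) cancels in dCt.
#'
#' @param ct data.frame with columns \code{sample}, \code{gene},
#'   \code{ct}; extra columns (\code{group}, \code{replicate}) are
#'   ignored here.
#' @param target Target gene id.
#' @param test_sample,control_sample Sample ids to compare (e.g. the
#'   deformed and the normal individual of a pair).
#' @param reference Endogenous control gene id (e.g. beta-actin).
#' @return The linear fold change (test over control).
#' @examples
#' ct <- data.frame(sample = rep(c("s1", "s2"), each = 2),
#'                  gene = rep(c("tgt", "actb"), 2),
#'                  ct = c(20, 18, 22, 18))
#' ddct_fold_change(ct, "tgt", "s1", "s2", "actb")  # 2^-(2-4) = 4
#' @export
ddct_fold_change <- function(ct, target, test_sample, control_sample,
                             reference) {
  if (!is.data.frame(ct) ||
      !all(c("sample", "gene", "ct") %in% names(ct)))
    stop_input("'ct' must have columns sample, gene, ct")
  if (any(ct$ct <= 0)) stop_input("Ct values must be positive")
  dct <- function(smp) {
    sub <- ct[ct$sample == smp, , drop = FALSE]
    t_ct <- sub$ct[sub$gene == target]
    r_ct <- sub$ct[sub$gene == reference]
    if (length(t_ct) == 0L)
      stop_input("sample '%s' has no Ct for target '%s'", smp, target)
    if (length(r_ct) == 0L)
      stop_input("sample '%s' has no Ct for reference gene '%s'", smp,
                 reference)
    mean(t_ct) - mean(r_ct)
  }
  ddct <- dct(test_sample) - dct(control_sample)
  2^(-ddct)
}

#' Compare qPCR expression between two groups of samples
#'
#' Per-gene two-sample Student's t-test on dCt values (target minus
#' reference, averaged over replicates within each sample) between a test
#' group and a control group, plus the mean fold change. Direction is
#' reported as the sign of the log2 fold change so concordance with a DGE
#' up/down call can be checked. With fewer than two samples per group, or
#' degenerate variance, the test is flagged and p is NA (descriptive
#' output only).
#'
#' @param ct data.frame with columns \code{sample}, \code{group},
#'   \code{gene}, \code{ct}; \code{group} must have exactly two levels.
#' @param reference Endogenous control gene id.
#' @param test_group Which group level is the test condition (default:
#'   first level alphabetically is control, the other is test — pass
#'   explicitly to be safe).
#' @return data.frame, one row per non-reference gene: \code{gene},
#'   \code{log2_fold}, \code{fold}, \code{direction}, \code{t},
#'   \code{p_value}, \code{tested}; attribute \code{method} records that
#'   the test is on dCt values.
#' @export
compare_groups <- function(ct, reference, test_group = NULL) {
  if (!is.data.frame(ct) ||
      !all(c("sample", "group", "gene", "ct") %in% names(ct)))
    stop_input("'ct' must have columns sample, group, gene, ct")
  groups <- sort(unique(as.character(ct$group)))
  if (length(groups) != 2L)
    stop_input("'group' must have exactly two levels, got %d",
               length(groups))
  if (is.null(test_group)) test_group <- groups[2L]
  if (!test_group %in% groups)
    stop_input("test_group '%s' not among groups", test_group)
  control_group <- setdiff(groups, test_group)

  genes <- setdiff(unique(ct$gene), reference)
  rows <- lapply(genes, function(g) {
    dct_of <- function(grp) {
      samples <- unique(ct$sample[ct$group == grp])
      vapply(samples, function(s) {
        t_ct <- ct$ct[ct$sample == s & ct$gene == g]
        r_ct <- ct$ct[ct$sample == s & ct$gene == reference]
        if (length(t_ct) == 0L || length(r_ct) == 0L) return(NA_real_)
        mean(t_ct) - mean(r_ct)
      }, numeric(1))
    }
    d_test <- dct_of(test_group)[!is.na(dct_of(test_group))]
    d_ctrl <- dct_of(control_group)[!is.na(dct_of(control_group))]
    l2f <- -(mean(d_test) - mean(d_ctrl))  # -ddCt = log2 fold change
    tested <- length(d_test) >= 2L && length(d_ctrl) >= 2L
    tval <- NA_real_; pval <- NA_real_
    if (tested) {
      if (stats::sd(c(d_test, d_ctrl)) == 0) {
        if (mean(d_test) == mean(d_ctrl)) { tval <- 0; pval <- 1 }
        # else degenerate variance with a shift: flagged, p undefined
        else tested <- FALSE
      } else {
        tt <- stats::t.test(d_test, d_ctrl, var.equal = TRUE)
        tval <- unname(tt$statistic); pval <- tt$p.value
      }
    }
    data.frame(gene = g, log2_fold = l2f, fold = 2^l2f,
               direction = if (l2f > 0) "up" else if (l2f < 0) "down"
               else "none",
               t = tval, p_value = pval, tested = tested,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "method") <- "two-sample t on dCt (test vs control)"
  out
}
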