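#' Upper-tail hypergeometric enrichment probability
#'
#' Probability of observing at least \code{m} members of a term among
#' \code{n} differentially expressed genes drawn from \code{N} annotated
#' background genes of which \code{M} carry the term:
#' \deqn{P = 1 - \sum_{i=0}^{m-1} \frac{\binom{M}{i}\binom{N-M}{n-i}}
#'   {\binom{N}{n}}.}
#' Accumulated as a log-space sum over the upper tail, which is exact for
#' small P where it matters.
#'
#' @param N Annotated background genes.
#' @param n Annotated differentially expressed genes.
#' @param M Background genes carrying the term.
#' @param m DE genes carrying the term.
#' @return The enrichment probability in [0, 1]; \code{m = 0} gives 1.
#' @examples
#' hypergeom_enrich_p(N = 10, n = 5, M = 5, m = 5)  # 1/252
#' @export
hypergeom_enrich_p <- function(N, n, M, m) {
  for (v in c(N, n, M, m))
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 ||
        v != floor(v))
      stop_input("N, n, M, m must be single non-negative integers")
  if (M > N) stop_input("M (%d) exceeds N (%d)", M, N)
  if (n > N) stop_input("n (%d) exceeds N (%d)", n, N)
  if (m > min(n, M))
    stop_input("m (%d) exceeds min(n, M) = %d", m, min(n, M))
  if (m == 0) return(1)
  i <- m:min(n, M)
  i <- i[(n - i) <= (N - M)]  # terms with infeasible complement vanish
  if (length(i) == 0L) return(0)
  min(1, exp(logsumexp(lchoose(M, i) + lchoose(N - M, n - i) -
                         lchoose(N, n))))
}

#' Term enrichment of a differentially expressed gene set
#'
#' Tests every annotation term for over-representation in a DEG set with
#' the upper-tail hypergeometric probability. \code{N} and \code{n} are
#' computed over annotated genes only: background genes without any term
#' (and DEGs outside the background) do not enter the calculation.
#' Significance is called on the raw p-value (\code{p <= alpha}); an
#' optional BH adjustment column can be added but the significance flag
#' deliberately stays raw.
#'
#' @param deg_ids Character vector of differentially expressed gene ids.
#' @param annotations data.frame with columns \code{gene_id}, \code{term};
#'   optional \code{namespace} and \code{label} are carried through.
#' @param background_ids Character vector of background gene ids
#'   (typically all annotated genes detected in either library).
#' @param alpha Significance threshold on the raw p-value (default 0.05).
#' @param adjust If TRUE, add a BH-adjusted \code{fdr} column (does not
#'   change the \code{significant} flag).
#' @return data.frame of class \code{EnrichmentResult}, one row per term
#'   with >= 1 annotated background gene: \code{term}, \code{namespace},
#'   \code{label}, \code{N}, \code{n}, \code{M}, \code{m}, \code{p_value},
#'   \code{significant}, \code{deg_members} (comma-separated), sorted by
#'   ascending p (ties broken by term id).
#' @export
enrich_terms <- function(deg_ids, annotations, background_ids,
                         alpha = 0.05, adjust = FALSE) {
  if (!is.data.frame(annotations) ||
      !all(c("gene_id", "term") %in% names(annotations)))
    stop_input("'annotations' must have columns gene_id and term")
  assert_scalar_number(alpha, "alpha", 0, 1)
  empty <- data.frame(term = character(), namespace = character(),
                      label = character(), N = integer(), n = integer(),
                      M = integer(), m = integer(), p_value = numeric(),
                      significant = logical(), deg_members = character(),
                      stringsAsFactors = FALSE)
  class(empty) <- c("EnrichmentResult", "data.frame")
  if (nrow(annotations) == 0L) return(empty)

  ann <- annotations[annotations$gene_id %in% background_ids, , drop = FALSE]
  if (nrow(ann) == 0L) return(empty)
  annotated <- unique(ann$gene_id)
  deg <- intersect(unique(deg_ids), annotated)
  N <- length(annotated)
  n <- length(deg)

  terms <- unique(ann$term)
  rows <- lapply(terms, function(tm) {
    sub <- ann[ann$term == tm, , drop = FALSE]
    members <- unique(sub$gene_id)
    hit <- intersect(members, deg)
    data.frame(term = tm,
               namespace = if ("namespace" %in% names(sub))
                 sub$namespace[1L] else NA_character_,
               label = if ("label" %in% names(sub))
                 sub$label[1L] else NA_character_,
               N = N, n = n, M = length(members), m = length(hit),
               p_value = hypergeom_enrich_p(N, n, length(members),
                                            length(hit)),
               deg_members = paste(sort(hit), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$significant <- out$p_value <= alpha
  if (adjust) out$fdr <- bh_fdr(out$p_value)
  out <- out[order(out$p_value, out$term), , drop = FALSE]
  rownames(out) <- NULL
  cols <- c("term", "namespace", "label", "N", "n", "M", "m", "p_value",
            "significant", if (adjust) "fdr", "deg_members")
  out <- out[, cols, drop = FALSE]
  class(out) <- c("EnrichmentResult", "data.frame")
  out
}

#' Top-k enriched terms
#'
#' The k most enriched terms of an [enrich_terms()] result, in the
#' "term (gene count), p" style of top-10 enrichment panels. Ties at the
#' cut are resolved by term id so the report is deterministic.
#'
#' @param results An \code{EnrichmentResult}.
#' @param k Number of terms to keep (default 10); if larger than the
#'   result, everything is returned.
#' @return data.frame \code{term}, \code{label}, \code{gene_count},
#'   \code{p_value}, \code{display} (e.g. \code{"term (12)"}).
#' @export
top_k_report <- function(results, k = 10L) {
  if (!is.numeric(k) || length(k) != 1L || k <= 0 || k != floor(k))
    stop_input("'k' must be a positive integer")
  if (!is.data.frame(results))
    stop_input("'results' must be an EnrichmentResult data.frame")
  ord <- order(results$p_value, results$term)
  top <- results[ord, , drop = FALSE][seq_len(min(k, nrow(results))), ,
                                      drop = FALSE]
  rownames(top) <- NULL
  data.frame(term = top$term, label = top$label, gene_count = top$m,
             p_value = top$p_value,
             display = sprintf("%s (%d)", top$term, top$m),
             stringsAsFactors = FALSE)
}
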